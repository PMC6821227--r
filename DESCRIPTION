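Package: gtahunter
Title: Discrimination of Gene-Transfer-Agent Genes from Phage Homologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies protein-coding genes as gene-transfer-agent (GTA)
    or bona fide phage using a weighted soft-margin support vector machine
    on amino-acid compositional features (k-mer counts, pseudo-amino-acid
    composition, and physicochemical class frequencies). Includes
    training-set curation (exact-duplicate removal, interquartile-fence
    outlier filtering on phylogenetic distances, taxonomic-bias weighting
    by complete-linkage clustering), repeated stratified cross-validation
    with grid search and a tie-break cascade for parameter selection,
    chaining of predicted GTA genes into head-tail clusters along the
    genome, and OTU-corrected abundance estimates from average nucleotide
    identity. A seeded synthetic-data generator emulates the compositional
    and genomic structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    kernlab,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
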