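# gtahunter

Gene transfer agents (GTAs) are domesticated phage-like elements encoded in
bacterial genomes: they build virus-like particles but package random host
DNA instead of their own genome. The best-studied GTA, RcGTA of
*Rhodobacter capsulatus*, is encoded by a 17-gene "head–tail cluster" that
looks so much like a prophage that prophage-prediction tools routinely
misannotate it. Distinguishing genuine GTA loci from real prophages
otherwise requires manual phylogenetics.

`gtahunter` automates that call. It exploits the observation that GTA
proteins have a distinct amino-acid composition (notably enriched in
alanine and glycine) relative to their viral homologs, and classifies each
homologous gene with a **weighted soft-margin support vector machine** over
compositional features. Around the classifier it provides the full
workflow: training-set curation, cross-validated parameter selection,
genomic clustering of predictions into head–tail cluster calls, and
taxonomically corrected abundance estimates. It is intended for
microbiologists and comparative genomicists screening (alphaproteobacterial)
genomes for GTA-like elements.

## The model

For a gene family *g*, training sequences T₁…T_m with labels
yᵢ ∈ {−1 (GTA), +1 (virus)} are encoded as feature vectors xᵢ and the
classifier solves

min ½‖w‖² + Σᵢ Cᵢᵢ ξᵢ  subject to yᵢ(w·xᵢ + b) ≥ 1 − ξᵢ, ξᵢ ≥ 0,

where the per-sample cost Cᵢᵢ = C·dᵢ carries a *taxonomic-bias weight*
dᵢ = 1/(size of the sequence's clade group): clades of near-identical
sequences, grouped by complete-linkage clustering of phylogenetic distances
at threshold *t*, count as a single sequence in the misclassification
budget. Training solves the dual

max_α Σᵢ αᵢ − ½ ΣᵢΣⱼ αᵢαⱼyᵢyⱼK(xᵢ,xⱼ),  0 ≤ αᵢ ≤ C·dᵢ,  Σᵢ αᵢyᵢ = 0,

by an interior-point quadratic program refined with an exact active-set
polish. A query u is called "GTA" when f(u) = Σᵢ αᵢyᵢK(xᵢ,u) + b < 0.

Three compositional encoders can be combined: overlapping k-mer counts
(k = 1–6), pseudo-amino-acid composition (20 residue frequencies plus λ
sequence-order correlation factors from standardized hydrophobicity,
hydrophilicity, and side-chain mass; ω = 0.05), and the frequencies of 19
overlapping physicochemical residue classes. Parameters (features, C, t)
are selected by stratified 5-fold cross-validation repeated 10 times over a
1,435-point grid, scored by the Weighted Accuracy Score
WAS = 100·(½·AAS_GTA + ½·AAS_virus) and the Matthews correlation
coefficient, with a documented tie-break cascade.

Predicted GTA genes are chained along each replicon (adjacent genes at
most 8,000 bp apart, at least 6 genes) into head–tail cluster calls, and
cluster abundance is corrected for taxon oversampling by grouping genomes
into OTUs at 95% average nucleotide identity and weighting each
cluster-bearing genome by 1/(OTU size).

## Worked example

Everything below runs offline on seeded synthetic data; the generator
plants the compositional contrast the method assumes (Ala+Gly enrichment
in the GTA class).

```r
library(gtahunter)
set.seed(42)
fx <- synthetic_training_fixture(skew = 1)   # 60 GTA + 60 virus sequences

spec <- feature_spec(kmer_k = 3)
X <- encode_features(fx$set, spec)
w <- assign_weights(fx$dist, t = 0.03, ids = fx$set$id)$weights
fit <- gta_svm(X, fx$set$y, weights = as.numeric(w), C = 100)
fit
#> Weighted soft-margin SVM (linear kernel)
#>   training points: 120 (GTA 60, virus 60)
#>   support vectors: 113  C: 100
#>   bias b: 0.359453

queries <- rbind(sample_sequences(fx$profiles$gta, 3, prefix = "qg"),
                 sample_sequences(fx$profiles$virus, 3, prefix = "qv"))
round(predict(fit, queries), 3)
#>    qg1    qg2    qg3    qv1    qv2    qv3
#> -0.243 -0.868 -0.028  0.375  0.491  0.590
predict(fit, queries, type = "class")
#>     qg1     qg2     qg3     qv1     qv2     qv3
#>   "GTA"   "GTA"   "GTA" "virus" "virus" "virus"
```

Negative decision values fall on the GTA side of the hyperplane; all six
held-out queries are recovered. Cross-validating the same configuration:

```r
cross_validate(fx$set, fx$dist,
               list(kmer_k = 3L, pseaac_lambda = NA_integer_,
                    physchem = FALSE, C = 100, t = 0.03),
               repeats = 3, seed = 1)
#> 5-fold x 3 CV  [k=3 lambda=- physchem=- C=100 t=0.03]
#>   WAS 98.33  MCC 0.967  (AAS GTA 0.983, virus 0.983)
```

A WAS of 98.3 means the two class accuracies average 98.3% with each class
weighted equally regardless of size.

The same workflow is scriptable from a shell via
`inst/scripts/gta-hunter.R` with subcommands `make-fixtures`, `xval`,
`train`, `classify`, and `scan`; every run writes a JSON manifest (inputs,
checksums, seed, configuration) for exact replay.

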