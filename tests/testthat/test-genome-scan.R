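mk_loci <- function(starts, lens, replicon = "chr", genome = "g1",
                    prefix = "L") {
  data.frame(id = paste0(prefix, seq_along(starts)), genome = genome,
             replicon = replicon, start = as.integer(starts),
             end = as.integer(starts + lens - 1), stringsAsFactors = FALSE)
}

test_that("gene chaining applies the gap and size thresholds", {
  # six genes, 1 kb each, exact 4000 bp gaps
  starts <- 1 + (0:5) * 5000
  loci <- mk_loci(starts, rep(1000, 6))
  got <- chain_cluster(loci, eps = 8000, min_size = 6)
  expect_equal(nrow(got), 1)
  expect_equal(got$n_members, 6)
  expect_equal(got$start, 1L)
  expect_equal(got$end, tail(starts, 1) + 999L)

  # one 9 kb gap splits the chain below min_size
  starts2 <- c(starts[1:3], starts[4:6] + 5001)
  got2 <- chain_cluster(mk_loci(starts2, rep(1000, 6)), 8000, 6)
  expect_equal(nrow(got2), 0)
  # but both halves qualify at min_size 3
  got3 <- chain_cluster(mk_loci(starts2, rep(1000, 6)), 8000, 3)
  expect_equal(got3$n_members, c(3L, 3L))

  # a gap of exactly eps still chains
  b <- mk_loci(c(1, 1000 + 8000 + 1), c(1000, 1000))
  expect_equal(chain_cluster(b, 8000, 2)$n_members, 2L)
  b2 <- mk_loci(c(1, 1000 + 8001 + 1), c(1000, 1000))
  expect_equal(nrow(chain_cluster(b2, 8000, 2)), 0)

  expect_error(chain_cluster(data.frame(id = "x", replicon = "c",
                                        start = NA_integer_, end = 5L),
                             8000, 6), "without coordinates")
})

test_that("chaining matches brute-force maximal-chain enumeration", {
  set.seed(60)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    starts <- sort(sample.int(2e5, n))
    lens <- sample(200:2000, n, replace = TRUE)
    loci <- mk_loci(starts, lens)
    for (par in list(c(5000, 9), c(8000, 6))) {
      got <- chain_cluster(loci, par[1], par[2])
      want <- oracle_chains(loci, par[1], par[2])
      expect_equal(nrow(got), length(want))
      if (length(want))
        expect_equal(strsplit(got$members, ","),
                     want[order(vapply(want, function(m)
                       min(loci$start[loci$id %in% m]), 0))])
    }
  }
})

test_that("chaining is invariant to input locus order and splits replicons", {
  set.seed(61)
  loci <- rbind(mk_loci(1 + (0:6) * 3000, rep(1000, 7), replicon = "c1"),
                mk_loci(1 + (0:6) * 3000, rep(1000, 7), replicon = "c2",
                        prefix = "M"))
  base <- chain_cluster(loci, 8000, 6)
  expect_equal(nrow(base), 2)
  for (i in 1:5) {
    p <- sample(nrow(loci))
    expect_equal(chain_cluster(loci[p, ], 8000, 6), base)
  }
})

test_that("cluster calls use only GTA-classified loci", {
  set.seed(62)
  pg <- plant_genome(n_background = 8, cluster_sizes = 7L)
  in_cluster <- pg$loci$id %in% pg$truth[[1]]
  preds <- data.frame(id = pg$loci$id,
                      score = ifelse(in_cluster, -0.8, 0.9))
  got <- call_gta_clusters(preds, pg$loci)
  expect_equal(nrow(got), 1)
  expect_equal(strsplit(got$members, ",")[[1]], pg$truth[[1]])

  # all virus: nothing called
  preds$score <- 1
  expect_equal(nrow(call_gta_clusters(preds, pg$loci)), 0)

  # planted cluster of 5 stays below min_size
  pg5 <- plant_genome(n_background = 8, cluster_sizes = 5L)
  preds5 <- data.frame(id = pg5$loci$id, score = -1)
  expect_equal(nrow(call_gta_clusters(preds5, pg5$loci, min_size = 6)), 0)

  expect_error(call_gta_clusters(data.frame(id = c("a", "a"),
                                            score = c(-1, -1)),
                                 pg$loci), "duplicated")
})

test_that("OTU grouping is the single-linkage closure of the ANI graph", {
  ani <- data.frame(genome_a = c("a", "b"), genome_b = c("b", "c"),
                    ani = c(96, 96))
  otus <- otu_group(ani)
  expect_equal(otus, list(c("a", "b", "c")))  # transitive closure

  ani2 <- rbind(ani, data.frame(genome_a = "a", genome_b = "c", ani = 80))
  expect_equal(otu_group(ani2), list(c("a", "b", "c")))

  # three genomes all >= 95 pairwise
  ani3 <- data.frame(genome_a = c("x", "x", "y"),
                     genome_b = c("y", "z", "z"), ani = 96)
  expect_equal(otu_group(ani3), list(c("x", "y", "z")))

  # genomes without qualifying pairs become singletons
  otus4 <- otu_group(ani, genomes = c("a", "b", "c", "d"))
  expect_equal(otus4, list(c("a", "b", "c"), "d"))

  expect_error(otu_group(data.frame(genome_a = "a", genome_b = "b",
                                    ani = 101)), "\\[0, 100\\]")
})

test_that("OTU components match a union-find oracle on random block tables", {
  set.seed(63)
  for (i in 1:30) {
    n_blocks <- sample(2:6, 1)
    sizes <- sample(1:5, n_blocks, replace = TRUE)
    genomes <- sprintf("g%d_%d", rep(seq_len(n_blocks), sizes),
                       unlist(lapply(sizes, seq_len)))
    block <- rep(seq_len(n_blocks), sizes)
    pairs <- t(combn(seq_along(genomes), 2))
    same <- block[pairs[, 1]] == block[pairs[, 2]]
    ani <- data.frame(genome_a = genomes[pairs[, 1]],
                      genome_b = genomes[pairs[, 2]],
                      ani = ifelse(same, runif(nrow(pairs), 95, 100),
                                   runif(nrow(pairs), 70, 94.9)))
    # drop some within-block pairs to exercise transitivity
    keep <- ifelse(same, runif(nrow(pairs)) < 0.7, TRUE)
    ani <- ani[keep, ]
    got <- otu_group(ani, genomes = genomes)
    want <- oracle_otus(ani, sort(genomes))
    expect_equal(got, want)
  }
})

test_that("corrected abundance down-weights multi-genome OTUs", {
  otus <- list(c("g1", "g2", "g3", "g4"), "g5")
  # OTU of 4 with 2 cluster-bearing genomes contributes 0.5
  ab <- corrected_abundance(otus, c("g1", "g2"))
  expect_equal(ab$corrected, 0.5)
  expect_equal(ab$raw, 2L)

  # all singleton OTUs: corrected equals raw
  singles <- as.list(paste0("s", 1:6))
  ab2 <- corrected_abundance(singles, c("s1", "s4", "s5"))
  expect_equal(ab2$corrected, 3)
  expect_equal(ab2$raw, 3L)

  # per-group aggregation
  grp <- c(g1 = "Rhodobacterales", g2 = "Rhodobacterales",
           g5 = "Rhizobiales")
  ab3 <- corrected_abundance(otus, c("g1", "g2", "g5"), grp)
  expect_equal(ab3$corrected[ab3$group == "Rhodobacterales"], 0.5)
  expect_equal(ab3$corrected[ab3$group == "Rhizobiales"], 1)

  expect_error(corrected_abundance(otus, "nope"), "not assigned")
  expect_equal(nrow(corrected_abundance(otus, character())), 0)
})

test_that("corrected abundance equals direct weighted summation on random fixtures", {
  set.seed(64)
  for (i in 1:30) {
    n_otus <- sample(2:8, 1)
    sizes <- sample(1:6, n_otus, replace = TRUE)
    genomes <- sprintf("G%d_%d", rep(seq_len(n_otus), sizes),
                       unlist(lapply(sizes, seq_len)))
    otus <- split(genomes, rep(seq_len(n_otus), sizes))
    otus <- unname(lapply(otus, sort))
    withcl <- sample(genomes, sample(seq_along(genomes), 1))
    got <- corrected_abundance(otus, withcl)
    want <- sum(sapply(unique(withcl), function(g)
      1 / sizes[rep(seq_len(n_otus), sizes)[match(g, genomes)]]))
    expect_equal(got$corrected, want)
    # corrected never exceeds the raw count
    expect_lte(got$corrected, got$raw)
  }
})
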