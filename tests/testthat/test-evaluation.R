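test_that("stratified folds partition the samples with balanced sizes", {
  y <- rep(c(-1, 1), each = 5)
  set.seed(50)
  fold <- kfold_split(y, 5)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 2))
  # each fold holds one member of each class here
  expect_true(all(table(fold, y) == 1))
  expect_error(kfold_split(y[1:3], 5), "fewer")

  set.seed(51)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    y <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.3, 0.7))
    if (length(unique(y)) < 2) next
    fold <- kfold_split(y, 5)
    expect_length(fold, n)
    expect_lte(diff(range(table(factor(fold, levels = 1:5)))), 2)
    # folds contain both classes whenever the minority class allows it
    if (min(table(y)) >= 5)
      expect_true(all(table(fold, y) > 0))
  }
})

test_that("identical seeds give identical folds", {
  y <- rep(c(-1, 1), c(20, 30))
  set.seed(7); f1 <- kfold_split(y, 5)
  set.seed(7); f2 <- kfold_split(y, 5)
  expect_identical(f1, f2)
})

test_that("Matthews correlation coefficient follows its closed form", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(5, 5, 5, 5), 0)
  expect_equal(mcc(8, 6, 2, 4),
               (8 * 6 - 2 * 4) / sqrt((8 + 2) * (8 + 4) * (6 + 2) * (6 + 4)))
  expect_equal(mcc(5, 0, 0, 5), 0)  # zero denominator convention
  expect_error(mcc(-1, 0, 0, 2), "negative")
  expect_error(mcc(0, 0, 0, 0), "empty")

  set.seed(52)
  for (i in 1:1000) {
    cc <- sample(0:20, 4, replace = TRUE)
    if (sum(cc) == 0) next
    v <- mcc(cc[1], cc[2], cc[3], cc[4])
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("the default parameter grid holds 1435 points over 41 feature sets", {
  g <- enumerate_grid()
  expect_equal(nrow(g), 1435)
  feats <- unique(g[, c("kmer_k", "pseaac_lambda", "physchem")])
  expect_equal(nrow(feats), 41)
  expect_equal(sort(unique(g$C)), c(0.01, 0.1, 1, 100, 10000))
  expect_equal(sort(unique(g$t)), c(0, 0.01, 0.02, 0.03, 0.04, 0.05, 0.1))
  # no empty feature combination, parameters within the declared grids
  expect_false(any(is.na(g$kmer_k) & is.na(g$pseaac_lambda) & !g$physchem))
  expect_true(all(g$kmer_k %in% c(NA, 1:6)))
  expect_true(all(g$pseaac_lambda %in% c(NA, 3, 6)))
})

test_that("weighted accuracy combines the class accuracies with equal weight", {
  # WAS arithmetic on a constructed result
  expect_equal(100 * (0.5 * 0.9 + 0.5 * 0.8), 85)
  set.seed(53)
  fx <- synthetic_training_fixture(n_gta = 12, n_virus = 12, skew = 1)
  cv <- cross_validate(fx$set, fx$dist,
                       list(kmer_k = 2L, pseaac_lambda = NA_integer_,
                            physchem = FALSE, C = 100, t = 0),
                       repeats = 2, seed = 1)
  expect_equal(cv$WAS, 100 * (0.5 * cv$AAS_GTA + 0.5 * cv$AAS_virus))
  expect_gte(cv$WAS, 0); expect_lte(cv$WAS, 100)
  expect_gte(cv$MCC, -1); expect_lte(cv$MCC, 1)
})

test_that("cross-validation is deterministic given the seed", {
  set.seed(54)
  fx <- synthetic_training_fixture(n_gta = 12, n_virus = 12, skew = 1)
  gp <- list(kmer_k = 2L, pseaac_lambda = NA_integer_, physchem = FALSE,
             C = 100, t = 0.03)
  cv1 <- cross_validate(fx$set, fx$dist, gp, repeats = 2, seed = 9)
  cv2 <- cross_validate(fx$set, fx$dist, gp, repeats = 2, seed = 9)
  expect_identical(cv1$WAS, cv2$WAS)
  expect_identical(cv1$confusion, cv2$confusion)
})

test_that("strongly skewed classes cross-validate to near-perfect accuracy", {
  # separability regime: Ala+Gly mass tripled in the GTA class
  set.seed(55)
  fx <- synthetic_training_fixture(skew = 1)
  for (kk in c(2L, 3L)) {
    cv <- cross_validate(fx$set, fx$dist,
                         list(kmer_k = kk, pseaac_lambda = NA_integer_,
                              physchem = FALSE, C = 100, t = 0),
                         repeats = 3, seed = 2)
    expect_gte(cv$WAS, 95)
    expect_gte(cv$MCC, 0.9)
  }
})

test_that("shuffled labels score at chance level", {
  set.seed(56)
  fx <- synthetic_training_fixture(skew = 1, n_gta = 30, n_virus = 30)
  fx$set$y <- sample(fx$set$y)
  cv <- cross_validate(fx$set, fx$dist,
                       list(kmer_k = 2L, pseaac_lambda = NA_integer_,
                            physchem = FALSE, C = 100, t = 0),
                       repeats = 3, seed = 3)
  # 3 sigma of the binomial null around 50 for 30-per-class validation sets
  expect_gt(cv$WAS, 30)
  expect_lt(cv$WAS, 70)
  expect_lt(abs(cv$MCC), 0.4)
})

test_that("the selection cascade prefers plain k-mer sets and resolves ties", {
  base <- expand.grid(kmer_k = c(2L, 3L), pseaac_lambda = c(NA, 3L),
                      physchem = FALSE, C = c(1, 100), t = c(0, 0.02))
  base$WAS <- 80
  base$MCC <- 0.5

  # single maximum returned unchanged
  r1 <- base; r1$WAS[5] <- 99
  expect_equal(select_best(r1)[, 1:5], r1[5, 1:5], ignore_attr = TRUE)

  # k-mer-only beats k-mer + PseAAC at equal WAS and equal k-mer means
  r2 <- base
  tie <- (r2$kmer_k == 2 & r2$C == 1 & r2$t == 0)
  r2$WAS[tie] <- 99   # one with lambda = NA, one with lambda = 3
  best <- select_best(r2)
  expect_true(is.na(best$pseaac_lambda))
  expect_equal(best$kmer_k, 2L)

  # k-mer size with the higher average WAS wins the first criterion
  r3 <- base
  r3$WAS[r3$kmer_k == 3] <- r3$WAS[r3$kmer_k == 3] + 5
  r3$WAS[c(1, 2)] <- 99  # tie between one k=2 and one k=3 point
  expect_equal(select_best(r3)$kmer_k, 3L)

  expect_error(select_best(base[0, ]), "empty")
})

test_that("the cascade agrees with an independent replay on constructed ties", {
  set.seed(57)
  for (i in 1:20) {
    n <- 12
    rep_grid <- data.frame(
      kmer_k = sample(c(NA, 1:6), n, replace = TRUE),
      pseaac_lambda = sample(c(NA, 3L, 6L), n, replace = TRUE),
      physchem = sample(c(TRUE, FALSE), n, replace = TRUE),
      C = sample(c(0.1, 1, 100), n, replace = TRUE),
      t = sample(c(0, 0.02, 0.1), n, replace = TRUE))
    drop <- is.na(rep_grid$kmer_k) & is.na(rep_grid$pseaac_lambda) &
      !rep_grid$physchem
    rep_grid <- rep_grid[!drop, ]
    rep_grid <- rep_grid[!duplicated(rep_grid), ]
    # few distinct WAS values force multi-way ties
    rep_grid$WAS <- sample(c(90, 95, 99), nrow(rep_grid), replace = TRUE)
    got <- select_best(rep_grid)
    want <- oracle_select(rep_grid)
    expect_equal(got[, c("kmer_k", "pseaac_lambda", "physchem", "C", "t")],
                 want[, c("kmer_k", "pseaac_lambda", "physchem", "C", "t")],
                 ignore_attr = TRUE)
  }
})

test_that("grid search reports one scored row per grid point", {
  set.seed(58)
  fx <- synthetic_training_fixture(n_gta = 10, n_virus = 10, skew = 1)
  grid <- enumerate_grid(C_values = c(1, 100), t_values = c(0, 0.03),
                         k_values = 2:3, lambda_values = integer(0),
                         physchem_values = FALSE)
  expect_equal(nrow(grid), 8)  # 2 k x 2 C x 2 t
  rep_out <- grid_search(fx$set, fx$dist, grid, repeats = 1, seed = 4)
  expect_equal(nrow(rep_out), 8)
  expect_true(all(c("AAS_GTA", "AAS_virus", "WAS", "MCC") %in%
                  names(rep_out)))
  expect_true(all(rep_out$WAS >= 0 & rep_out$WAS <= 100))
})
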