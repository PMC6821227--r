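#' Stratified k-fold split
#'
#' Randomly partitions sample indices into \code{k} folds of near-equal
#' size (differing by at most one), stratified by class so that every fold
#' contains both classes whenever the class counts allow it. Stratification
#' matters here because viral training sets can be as small as a dozen
#' sequences; an unstratified split would regularly produce folds with an
#' empty class, leaving a per-class accuracy undefined.
#'
#' @param y Label vector (-1 / +1).
#' @param k Number of folds; must not exceed the number of samples.
#' @return Integer vector of fold assignments in 1..k, aligned with
#'   \code{y}. Deterministic given the RNG state.
#' @export
kfold_split <- function(y, k = 5L) {
  n <- length(y)
  if (n < k) stop("fewer samples (", n, ") than folds (", k, ")")
  fold <- integer(n)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    # continue fold numbering across classes so fold sizes stay balanced
    fold[idx] <- (seq_along(idx) - 1L) %% k + 1L
  }
  fold
}

#' Matthews correlation coefficient
#'
#' @param tp,tn,fp,fn Confusion counts (non-negative).
#' @return \code{(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))}; if
#'   any denominator factor is zero the coefficient is defined as 0 (the
#'   standard convention for degenerate tables).
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion counts")
  if (tp + tn + fp + fn == 0) stop("empty confusion table")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' The parameter grid of the classifier
#'
#' Enumerates every feature combination - at most one k-mer size (1..6), at
#' most one PseAAC rank (3 or 6), physicochemical classes on or off,
#' excluding the empty combination - crossed with the regularization values
#' C in \{0.01, 0.1, 1, 100, 10000\} and weighting thresholds t in
#' \{0, 0.01, 0.02, 0.03, 0.04, 0.05, 0.1\}. That is
#' (7 x 3 x 2 - 1) = 41 feature combinations and 41 x 5 x 7 = 1435 grid
#' points in total.
#'
#' @param C_values,t_values,k_values,lambda_values Optional restrictions of
#'   the default grids.
#' @param physchem_values Logical values to consider for the
#'   physicochemical block.
#' @return Data frame with one row per grid point: \code{kmer_k},
#'   \code{pseaac_lambda} (NA = encoder off), \code{physchem}, \code{C},
#'   \code{t}.
#' @export
enumerate_grid <- function(C_values = c(0.01, 0.1, 1, 100, 10000),
                           t_values = c(0, 0.01, 0.02, 0.03, 0.04, 0.05, 0.1),
                           k_values = 1:6, lambda_values = c(3L, 6L),
                           physchem_values = c(FALSE, TRUE)) {
  feats <- expand.grid(kmer_k = c(NA_integer_, k_values),
                       pseaac_lambda = c(NA_integer_, lambda_values),
                       physchem = physchem_values)
  feats <- feats[!(is.na(feats$kmer_k) & is.na(feats$pseaac_lambda) &
                   !feats$physchem), , drop = FALSE]
  grid <- merge(feats, expand.grid(C = C_values, t = t_values))
  grid <- grid[order(grid$kmer_k, grid$pseaac_lambda, grid$physchem,
                     grid$C, grid$t, na.last = TRUE), ]
  rownames(grid) <- NULL
  grid[, c("kmer_k", "pseaac_lambda", "physchem", "C", "t")]
}

grid_spec <- function(gp) {
  feature_spec(kmer_k = gp$kmer_k, pseaac_lambda = gp$pseaac_lambda,
               physchem = gp$physchem)
}

#' Repeated stratified cross-validation of one grid point
#'
#' Evaluates one feature/parameter combination by 5-fold cross-validation
#' repeated \code{repeats} times. Within every fold, taxonomic-bias weights
#' are recomputed by complete-linkage clustering at threshold \code{t}
#' restricted to the training four-fifths (weights must not look at held-out
#' sequences), the SVM is trained at regularization \code{C} on features
#' encoded with a vocabulary frozen from the training members, and the
#' held-out fifth is classified.
#'
#' Per class, the accuracy is averaged over folds and repeats (AAS); the
#' weighted accuracy score gives each class weight 0.5 regardless of size:
#' \code{WAS = 100 (0.5 AAS_GTA + 0.5 AAS_virus)}. The Matthews correlation
#' coefficient is computed from the confusion counts pooled over all folds
#' and repeats (pooling is stabler than averaging when a class holds only a
#' handful of sequences), with "GTA" as the positive class.
#'
#' @param set Labeled training set (\code{\link{training_set}}, typically
#'   after \code{\link{deduplicate}} and outlier filtering).
#' @param dist Distance matrix covering all ids in \code{set}.
#' @param grid_point One-row data frame from \code{\link{enumerate_grid}}
#'   (or a list with the same fields).
#' @param repeats Number of random re-partitions; default 10.
#' @param k Number of folds; default 5.
#' @param seed Integer seed making the partitioning reproducible.
#' @param scales,classes Property tables (loaded once for speed).
#' @return An object of class \code{gta_cv}: list with \code{AAS_GTA},
#'   \code{AAS_virus}, \code{WAS}, \code{MCC}, the pooled \code{confusion}
#'   counts, \code{per_repeat} accuracies, and the grid point.
#' @export
cross_validate <- function(set, dist, grid_point, repeats = 10L, k = 5L,
                           seed = 1L,
                           scales = load_aa_scales(),
                           classes = load_physchem_classes()) {
  gp <- as.list(grid_point)
  spec <- grid_spec(gp)
  y <- set$y
  if (!all(set$id %in% rownames(dist)))
    stop("distance matrix does not cover all training ids")
  set.seed(seed)
  acc_g <- acc_v <- matrix(NA_real_, repeats, k)
  conf <- c(tp = 0, tn = 0, fp = 0, fn = 0)   # positive class: GTA (-1)
  for (r in seq_len(repeats)) {
    fold <- kfold_split(y, k)
    for (f in seq_len(k)) {
      tr <- fold != f
      X_tr <- encode_features(set[tr, ], spec, scales = scales,
                              classes = classes)
      X_te <- encode_features(set[!tr, ], spec,
                              vocabulary = attr(X_tr, "vocabulary"),
                              scales = scales, classes = classes)
      w <- if (gp$t > 0)
        assign_weights(dist, t = gp$t, ids = set$id[tr])$weights
      else rep(1, sum(tr))
      fit <- gta_svm(X_tr, y[tr], weights = as.numeric(w), C = gp$C)
      f_te <- predict(fit, X_te)
      pred <- ifelse(f_te < 0, -1, 1)
      truth <- y[!tr]
      acc_g[r, f] <- if (any(truth == -1))
        mean(pred[truth == -1] == -1) else NA_real_
      acc_v[r, f] <- if (any(truth == 1))
        mean(pred[truth == 1] == 1) else NA_real_
      conf["tp"] <- conf["tp"] + sum(truth == -1 & pred == -1)
      conf["tn"] <- conf["tn"] + sum(truth == 1 & pred == 1)
      conf["fp"] <- conf["fp"] + sum(truth == 1 & pred == -1)
      conf["fn"] <- conf["fn"] + sum(truth == -1 & pred == 1)
    }
  }
  AAS_GTA <- mean(acc_g, na.rm = TRUE)
  AAS_virus <- mean(acc_v, na.rm = TRUE)
  out <- list(AAS_GTA = AAS_GTA, AAS_virus = AAS_virus,
              WAS = 100 * (0.5 * AAS_GTA + 0.5 * AAS_virus),
              MCC = mcc(conf["tp"], conf["tn"], conf["fp"], conf["fn"]),
              confusion = conf,
              per_repeat = list(GTA = rowMeans(acc_g, na.rm = TRUE),
                                virus = rowMeans(acc_v, na.rm = TRUE)),
              grid_point = gp, repeats = repeats, k = k, seed = seed)
  class(out) <- "gta_cv"
  out
}

#' @export
print.gta_cv <- function(x, ...) {
  gp <- x$grid_point
  cat(sprintf("5-fold x %d CV  [k=%s lambda=%s physchem=%s C=%g t=%g]\n",
              x$repeats, ifelse(is.na(gp$kmer_k), "-", gp$kmer_k),
              ifelse(is.na(gp$pseaac_lambda), "-", gp$pseaac_lambda),
              ifelse(gp$physchem, "+", "-"), gp$C, gp$t))
  cat(sprintf("  WAS %.2f  MCC %.3f  (AAS GTA %.3f, virus %.3f)\n",
              x$WAS, x$MCC, x$AAS_GTA, x$AAS_virus))
  invisible(x)
}

#' Grid search over feature/parameter combinations
#'
#' Runs \code{\link{cross_validate}} for every row of \code{grid} and
#' returns the report table used by \code{\link{select_best}}.
#'
#' @inheritParams cross_validate
#' @param grid Data frame of grid points (\code{\link{enumerate_grid}}).
#' @param verbose Print one line per grid point.
#' @return Data frame: the grid columns plus \code{AAS_GTA},
#'   \code{AAS_virus}, \code{WAS}, \code{MCC}.
#' @export
grid_search <- function(set, dist, grid = enumerate_grid(), repeats = 10L,
                        k = 5L, seed = 1L, verbose = FALSE,
                        scales = load_aa_scales(),
                        classes = load_physchem_classes()) {
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cv <- cross_validate(set, dist, grid[i, ], repeats = repeats, k = k,
                         seed = seed, scales = scales, classes = classes)
    if (verbose) print(cv)
    c(AAS_GTA = cv$AAS_GTA, AAS_virus = cv$AAS_virus,
      WAS = cv$WAS, MCC = unname(cv$MCC))
  })
  cbind(grid, do.call(rbind, res))
}

#' Select the optimal grid point from a grid-search report
#'
#' Restricts to the grid points achieving the maximal WAS, then applies a
#' tie-break cascade in priority order: (1) keep the point(s) whose k-mer
#' size has the highest mean WAS over all evaluated grid points sharing
#' that k-mer size; (2) drop points that use PseAAC or physicochemical
#' features, unless that would empty the candidate set; (3) keep the
#' regularization C with the highest mean WAS among the remaining
#' candidates; (4) keep the threshold t with the highest WAS among the
#' remaining candidates. Any residual tie is resolved deterministically by
#' the smallest (k, C, t), with an absent k-mer encoder ordered last.
#'
#' @param report Data frame from \code{\link{grid_search}}.
#' @return One-row data frame: the selected grid point with its scores.
#' @export
select_best <- function(report) {
  if (nrow(report) == 0L) stop("empty grid report")
  cand <- report[report$WAS == max(report$WAS), , drop = FALSE]

  # (1) mean WAS per k-mer size over the full report
  if (nrow(cand) > 1L) {
    key <- function(k) ifelse(is.na(k), "none", as.character(k))
    mean_by_k <- tapply(report$WAS, key(report$kmer_k), mean)
    kw <- mean_by_k[key(cand$kmer_k)]
    cand <- cand[kw == max(kw), , drop = FALSE]
  }
  # (2) avoid PseAAC / physchem add-ons
  if (nrow(cand) > 1L) {
    plain <- is.na(cand$pseaac_lambda) & !cand$physchem
    if (any(plain)) cand <- cand[plain, , drop = FALSE]
  }
  # (3) C with the highest mean WAS among remaining candidates
  if (nrow(cand) > 1L) {
    mean_by_C <- tapply(cand$WAS, cand$C, mean)
    cand <- cand[cand$C %in%
                 as.numeric(names(mean_by_C)[mean_by_C == max(mean_by_C)]),
                 , drop = FALSE]
  }
  # (4) t with the highest WAS among remaining candidates
  if (nrow(cand) > 1L) {
    best_t <- tapply(cand$WAS, cand$t, max)
    cand <- cand[cand$t %in%
                 as.numeric(names(best_t)[best_t == max(best_t)]),
                 , drop = FALSE]
  }
  if (nrow(cand) > 1L) {
    k_ord <- ifelse(is.na(cand$kmer_k), Inf, cand$kmer_k)
    cand <- cand[order(k_ord, cand$C, cand$t), , drop = FALSE]
    cand <- cand[1L, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}
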