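# Independent oracle routines used across tests. These deliberately take
# different computational routes from the package code they check.

# Step-by-step evaluation of the pseudo-amino-acid composition, written as a
# literal transcription of the defining equations (explicit loops, no sharing
# with the package implementation).
oracle_pseaac <- function(seq, lambda, omega, scales_raw) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  std <- matrix(NA_real_, 20, 3)
  for (p in 1:3) {
    v <- scales_raw[, p]
    mu <- sum(v) / 20
    std[, p] <- (v - mu) / sqrt(sum((v - mu)^2) / 20)
  }
  rownames(std) <- aa
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  r <- numeric(20)
  for (i in 1:20) r[i] <- sum(res == aa[i])
  s <- numeric(lambda)
  for (k in 1:lambda) {
    total <- 0
    for (i in 1:(L - k)) {
      J <- 0
      for (p in 1:3) J <- J + (std[res[i + k], p] - std[res[i], p])^2
      total <- total + J / 3
    }
    s[k] <- total / (L - k)
  }
  den <- sum(r) + omega * sum(s)
  c(r / den, omega * s / den)
}

# Tukey-fence outlier evaluation straight from the rule text, using R's
# quantile() as the independent quartile routine.
oracle_filter_outliers <- function(dist, bact, vir) {
  o <- sapply(bact, function(b) mean(dist[b, setdiff(bact, b)]))
  q <- quantile(o, c(0.25, 0.75), type = 7)
  flagged <- o > q[2] + 1.5 * (q[2] - q[1])
  nearest <- sapply(bact, function(b) min(dist[b, vir]))
  removed <- flagged & o > nearest
  bact[!removed]
}

# Maximal-chain enumeration by exhaustive window checking: every [i, j]
# window of the start-sorted loci is tested for validity (all adjacent gaps
# <= eps) and maximality (cannot extend left or right).
oracle_chains <- function(loci, eps, min_size) {
  out <- list()
  for (rep_id in unique(loci$replicon)) {
    sub <- loci[loci$replicon == rep_id, ]
    sub <- sub[order(sub$start, sub$end, sub$id), ]
    n <- nrow(sub)
    gap_ok <- function(i) sub$start[i + 1] - sub$end[i] - 1 <= eps
    for (i in 1:n) for (j in i:n) {
      valid <- j == i || all(sapply(i:(j - 1), gap_ok))
      if (!valid) next
      maximal <- (i == 1 || !gap_ok(i - 1)) && (j == n || !gap_ok(j))
      if (maximal && (j - i + 1) >= min_size)
        out[[length(out) + 1]] <- sub$id[i:j]
    }
  }
  out
}

# Union-find connected components over ANI edges.
oracle_otus <- function(ani, genomes, threshold = 95) {
  parent <- stats::setNames(genomes, genomes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  hits <- ani[ani$ani >= threshold, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    ra <- find(hits$genome_a[i]); rb <- find(hits$genome_b[i])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(genomes, find, "")
  comps <- unname(lapply(split(genomes, roots), sort))
  comps[order(vapply(comps, `[`, "", 1))]
}

# Independent replay of the parameter-selection cascade, coded from its
# statement rather than shared with select_best().
oracle_select <- function(report) {
  cand <- report[report$WAS == max(report$WAS), ]
  kkey <- ifelse(is.na(report$kmer_k), "none", as.character(report$kmer_k))
  if (nrow(cand) > 1) {
    mk <- sapply(split(report$WAS, kkey), mean)
    ck <- ifelse(is.na(cand$kmer_k), "none", as.character(cand$kmer_k))
    cand <- cand[mk[ck] == max(mk[ck]), ]
  }
  if (nrow(cand) > 1) {
    plain <- is.na(cand$pseaac_lambda) & !cand$physchem
    if (any(plain)) cand <- cand[plain, ]
  }
  if (nrow(cand) > 1) {
    mC <- sapply(split(cand$WAS, cand$C), mean)
    cand <- cand[cand$C %in% as.numeric(names(mC)[mC == max(mC)]), ]
  }
  if (nrow(cand) > 1) {
    mt <- sapply(split(cand$WAS, cand$t), max)
    cand <- cand[cand$t %in% as.numeric(names(mt)[mt == max(mt)]), ]
  }
  cand <- cand[order(ifelse(is.na(cand$kmer_k), Inf, cand$kmer_k),
                     cand$C, cand$t), ]
  cand[1, ]
}

# Decision-value deviation between a gta_svm fit and the libsvm reference
# on the same data, with per-sample weights realized in the reference by
# point replication. When the fit has no margin support vector the bias is
# not unique (any value in the KKT interval is optimal); in that case the
# unique linear parts are compared and both biases are required to lie in
# the KKT-feasible interval.
oracle_svm_deviation <- function(fit, X, y, d, C) {
  m <- e1071::svm(X[rep(seq_along(y), d), , drop = FALSE],
                  factor(rep(y, d), levels = c(-1, 1)), scale = FALSE,
                  kernel = "linear", cost = C, tolerance = 1e-10)
  dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")
  sgn <- if (colnames(dv)[1] == "-1/1") -1 else 1
  f_ref <- sgn * dv[, 1]
  f_me <- unname(predict(fit, X))
  u <- C * d
  margin <- fit$alpha > 1e-6 * u & fit$alpha < u - 1e-6 * u
  if (any(margin)) return(max(abs(f_me - f_ref)))
  b_ref <- -sgn * m$rho
  g <- f_me - fit$b
  lo <- max((y - g)[(y > 0 & fit$alpha <= 1e-6 * u) |
                    (y < 0 & fit$alpha >= u - 1e-6 * u)])
  hi <- min((y - g)[(y < 0 & fit$alpha <= 1e-6 * u) |
                    (y > 0 & fit$alpha >= u - 1e-6 * u)])
  both_feasible <- fit$b >= lo - 1e-6 && fit$b <= hi + 1e-6 &&
    b_ref >= lo - 1e-6 && b_ref <= hi + 1e-6
  if (!both_feasible) return(Inf)
  max(abs((f_me - fit$b) - (f_ref - b_ref)))
}

# Random distance matrix with labeled ids.
random_dist <- function(n, prefix = "s", scale = 1) {
  m <- matrix(runif(n * n, 0, scale), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  ids <- paste0(prefix, seq_len(n))
  dimnames(m) <- list(ids, ids)
  m
}
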