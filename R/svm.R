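#' Kernel evaluation
#'
#' @param kernel \code{"linear"} (dot product) or \code{"gaussian"}
#'   (\code{exp(-gamma * ||xi - xj||^2)}).
#' @param X,Y Row matrices of feature vectors with equal width; \code{Y}
#'   defaults to \code{X}.
#' @param gamma Gaussian width parameter (required for the Gaussian kernel).
#' @return The |X| x |Y| Gram matrix.
#' @export
kernel_matrix <- function(kernel, X, Y = X, gamma = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("feature width mismatch: ", ncol(X), " vs ", ncol(Y))
  switch(kernel,
    linear = X %*% t(Y),
    gaussian = {
      if (is.null(gamma)) stop("gaussian kernel requires gamma")
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      exp(-gamma * pmax(d2, 0))
    },
    stop("unknown kernel: ", kernel))
}

#' Weighted soft-margin support vector machine
#'
#' Fits a binary soft-margin SVM in which each training point carries its
#' own misclassification budget: the box constraint on the dual coefficient
#' of point i is \code{0 <= alpha_i <= C * d_i}, where \code{d_i} is a
#' per-sample weight (here, the reciprocal taxonomic group size from
#' \code{\link{assign_weights}}). With all \code{d_i = 1} this is the
#' ordinary C-SVM. The dual problem
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'   y_i y_j K(x_i, x_j)}
#' subject to \eqn{\sum_i \alpha_i y_i = 0} and the per-sample box bounds is
#' solved by an interior-point quadratic program (\code{kernlab::ipop})
#' followed by an exact Newton polish on the identified active set, giving a
#' deterministic solution with KKT residuals near machine precision.
#'
#' The bias is the mean over margin support vectors (those with
#' \code{0 < alpha_i < C d_i}, up to tolerance) of
#' \code{y_i - sum_j alpha_j y_j K(x_j, x_i)}; if no margin support vector
#' exists, the midpoint of the interval permitted by the KKT conditions is
#' used.
#'
#' Class convention: \code{y = -1} is "GTA", \code{y = +1} is "virus"; the
#' decision value \code{f(x) = sum_i alpha_i y_i K(x_i, x) + b} is negative
#' on the GTA side. No feature scaling is applied before the optimization.
#'
#' @param x Numeric feature matrix, one row per training sequence (as from
#'   \code{\link{encode_features}}).
#' @param y Labels in \{-1, +1\}; both classes must be present.
#' @param weights Per-sample weights \code{d_i > 0}; default all 1.
#' @param C Regularization scalar (> 0); larger values harden the margin.
#' @param kernel \code{"linear"} (default) or \code{"gaussian"}.
#' @param gamma Gaussian kernel width, ignored for the linear kernel.
#' @param sv_tol Support-vector identification tolerance, relative to each
#'   sample's bound \code{C d_i}.
#' @return An object of class \code{gta_svm} with components \code{alpha},
#'   \code{sv_index}, \code{sv_x}, \code{sv_y}, \code{sv_alpha}, \code{b},
#'   \code{C}, \code{weights}, \code{kernel}, \code{gamma},
#'   \code{vocabulary}, \code{spec}, \code{fitted} (training decision
#'   values), and \code{kkt} (feasibility residuals).
#' @seealso \code{\link{predict.gta_svm}}, \code{\link{cross_validate}}
#' @examples
#' x <- matrix(c(0, 2), ncol = 1)
#' fit <- gta_svm(x, c(-1, 1), C = 100)
#' predict(fit, matrix(c(0, 1, 2), ncol = 1))  # -1, 0, 1
#' @export
gta_svm <- function(x, y, weights = NULL, C = 1, kernel = "linear",
                    gamma = NULL, sv_tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  m <- nrow(x)
  if (length(y) != m) stop("x and y sizes differ")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 (GTA) or +1 (virus)")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights <= 0))
    stop("weights must be positive and one per sample")
  if (C <= 0) stop("C must be positive")
  if (kernel == "gaussian" && is.null(gamma)) gamma <- 1 / ncol(x)

  K <- kernel_matrix(kernel, x, gamma = gamma)
  K <- (K + t(K)) / 2
  u <- C * weights                         # per-sample box bounds C d_i
  H <- (y %o% y) * K

  alpha <- solve_svm_dual(H, y, u)
  ub_tol <- sv_tol * u
  sv <- alpha > ub_tol
  if (!any(sv)) sv <- alpha == max(alpha)  # degenerate: keep argmax

  g <- as.numeric(K %*% (alpha * y))       # sum_j alpha_j y_j K(x_j, .)
  margin_tol <- pmax(1e-6 * u, 1e-10)
  margin_sv <- alpha > margin_tol & alpha < u - margin_tol
  if (any(margin_sv)) {
    b <- mean(y[margin_sv] - g[margin_sv])
  } else {
    # KKT: y_i(g_i + b) >= 1 where alpha_i = 0, <= 1 where alpha_i = u_i,
    # so b is bounded below by y_i - g_i at (alpha = 0, y = +1) and
    # (alpha = u, y = -1), and above at the two opposite corners
    lo <- suppressWarnings(max(c(-Inf, (y - g)[(y > 0 & alpha <= margin_tol) |
                                               (y < 0 & alpha >= u - margin_tol)])))
    hi <- suppressWarnings(min(c(Inf, (y - g)[(y < 0 & alpha <= margin_tol) |
                                              (y > 0 & alpha >= u - margin_tol)])))
    b <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
         else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
  }

  fit <- structure(list(
    alpha = alpha, sv_index = which(sv),
    sv_x = x[sv, , drop = FALSE], sv_y = y[sv], sv_alpha = alpha[sv],
    b = b, C = C, weights = weights, kernel = kernel, gamma = gamma,
    vocabulary = attr(x, "vocabulary"), spec = attr(x, "spec"),
    y = y, fitted = g + b,
    kkt = c(eq = abs(sum(alpha * y)),
            box = max(c(0, -alpha, alpha - u))),
    call = match.call()), class = "gta_svm")
  fit
}

# Solve max 1'a - a'Ha/2 s.t. y'a = 0, 0 <= a <= u.
# ipop supplies a near-optimal interior point; an active-set refinement then
# solves the KKT system exactly on the working set, moving bound violators
# until the optimality conditions hold to near machine precision.
solve_svm_dual <- function(H, y, u) {
  m <- length(y)
  res <- tryCatch(
    kernlab::ipop(c = matrix(-1, m, 1), H = H, A = matrix(y, 1, m), b = 0,
                  l = rep(0, m), u = u, r = 0, sigf = 8, maxiter = 80,
                  margin = 0.05, bound = 10),
    error = function(e) NULL)
  alpha <- if (!is.null(res))
    pmin(pmax(as.numeric(kernlab::primal(res)), 0), u)
  else
    rep(0, m)  # cold start: the active-set loop solves from scratch

  refined <- refine_active_set(alpha, H, y, u,
                               max_iter = if (is.null(res)) 20L * m + 50L
                                          else 60L)
  if (!is.null(refined)) alpha <- refined
  else if (is.null(res))
    stop("QP solver failed: interior point did not converge and ",
         "active-set refinement found no solution")
  alpha
}

# Active-set refinement of the dual solution. The working set is seeded from
# the interior-point iterate; each round solves the equality-constrained QP
# over the free variables exactly, clamps the worst free-variable bound
# violation, and frees the worst KKT violator among the bounded variables.
# Returns NULL if no clean solution is reached (the caller keeps the
# interior-point iterate).
refine_active_set <- function(alpha, H, y, u, act_tol = 1e-5,
                              kkt_tol = 1e-10, max_iter = 60L) {
  m <- length(y)
  state <- integer(m)                      # 0 free, -1 at zero, +1 at upper
  state[alpha <= act_tol * u] <- -1L
  state[alpha >= (1 - act_tol) * u] <- 1L
  scale <- max(1, max(abs(H)), max(u[is.finite(u)]))
  best <- NULL
  for (iter in seq_len(max_iter)) {
    free <- state == 0L
    a <- ifelse(state == 1L, u, 0)
    if (any(free)) {
      n_f <- sum(free)
      Hf <- H[free, free, drop = FALSE]
      yf <- y[free]
      rhs <- c(1 - as.numeric(H[free, !free, drop = FALSE] %*% a[!free]),
               -sum(a[!free] * y[!free]))
      M <- rbind(cbind(Hf, yf), c(yf, 0))
      # exact solve; fall back to a least-squares solve, then to a tiny
      # ridge, when the working-set system is singular (duplicate points)
      sol <- tryCatch(solve(M, rhs), error = function(e)
        tryCatch(qr.solve(M, rhs, tol = 1e-12), error = function(e2)
          tryCatch(solve(M + diag(1e-10 * scale, n_f + 1L), rhs),
                   error = function(e3) NULL)))
      if (is.null(sol)) return(best)
      a[free] <- sol[seq_len(n_f)]
      beta <- sol[n_f + 1L]
      # clamp the worst bound violation among free variables, if any
      lo_v <- pmax(0 - a, 0) * free
      hi_v <- pmax(a - u, 0) * free
      if (max(lo_v, hi_v) > kkt_tol * scale) {
        w <- which.max(pmax(lo_v, hi_v))
        state[w] <- if (lo_v[w] >= hi_v[w]) -1L else 1L
        next
      }
      a <- pmin(pmax(a, 0), u)
    } else {
      if (abs(sum(a * y)) > 1e-8 * scale) return(best)
      beta <- {
        # any beta satisfying all bound conditions; take the midpoint of
        # the feasible interval when it exists
        q <- as.numeric(H %*% a)
        lo <- max(-Inf, ((1 - q) / y)[(state == -1L & y > 0) |
                                      (state == 1L & y < 0)])
        hi <- min(Inf, ((1 - q) / y)[(state == -1L & y < 0) |
                                     (state == 1L & y > 0)])
        if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
        else if (is.finite(lo)) lo else if (is.finite(hi)) hi else 0
      }
    }
    # KKT check for the bounded variables:
    #   at zero: (Ha)_i + beta y_i >= 1;  at upper: <= 1
    q <- as.numeric(H %*% a) + beta * y
    viol <- rep(0, m)
    viol[state == -1L] <- pmax(1 - q[state == -1L], 0)
    viol[state == 1L] <- pmax(q[state == 1L] - 1, 0)
    best <- a
    if (max(viol) <= 1e-8) return(a)
    state[which.max(viol)] <- 0L
  }
  best
}

#' Predict with a fitted weighted SVM
#'
#' @param object A \code{gta_svm} fit.
#' @param newdata Feature matrix with the width the model was trained on, or
#'   a sequence data frame / character vector to be encoded with the model's
#'   frozen feature spec and vocabulary.
#' @param type \code{"decision"} (default) for the raw decision values
#'   f(x), or \code{"class"} for the labels: \code{"GTA"} when f(x) < 0,
#'   \code{"virus"} otherwise (ties at exactly 0 go to "virus").
#' @param ... Unused.
#' @return Numeric vector of decision values or character vector of class
#'   calls, in row order of \code{newdata}.
#' @export
predict.gta_svm <- function(object, newdata,
                            type = c("decision", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) {
    if (is.null(object$spec))
      stop("model carries no feature spec; supply an encoded matrix")
    newdata <- encode_features(newdata, object$spec,
                               vocabulary = object$vocabulary)
  }
  if (ncol(newdata) != ncol(object$sv_x))
    stop("feature width mismatch: model ", ncol(object$sv_x),
         ", newdata ", ncol(newdata))
  Kq <- kernel_matrix(object$kernel, newdata, object$sv_x,
                      gamma = object$gamma)
  f <- as.numeric(Kq %*% (object$sv_alpha * object$sv_y) + object$b)
  names(f) <- rownames(newdata)
  if (type == "decision") f else ifelse(f < 0, "GTA", "virus")
}

#' @export
print.gta_svm <- function(x, ...) {
  cat("Weighted soft-margin SVM (", x$kernel, " kernel)\n", sep = "")
  cat("  training points:", length(x$y),
      sprintf("(GTA %d, virus %d)", sum(x$y < 0), sum(x$y > 0)), "\n")
  cat("  support vectors:", length(x$sv_alpha), " C:", x$C, "\n")
  cat("  bias b:", format(x$b, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.gta_svm <- function(object, ...) {
  pred <- ifelse(object$fitted < 0, -1, 1)
  acc <- mean(pred == object$y)
  xi <- pmax(0, 1 - object$y * object$fitted)
  out <- list(model = object, training_accuracy = acc,
              n_margin_violations = sum(xi > 1e-8), total_slack = sum(xi),
              kkt = object$kkt)
  class(out) <- "summary.gta_svm"
  out
}

#' @export
print.summary.gta_svm <- function(x, ...) {
  print(x$model)
  cat("  training accuracy:", format(x$training_accuracy, digits = 4), "\n")
  cat("  margin violations:", x$n_margin_violations,
      " total slack:", format(x$total_slack, digits = 4), "\n")
  cat("  KKT residuals: |sum(alpha*y)| =", format(x$kkt["eq"], digits = 3),
      ", box =", format(x$kkt["box"], digits = 3), "\n")
  invisible(x)
}

#' Primal weight vector of a linear-kernel fit
#' @param object A \code{gta_svm} fit with linear kernel.
#' @param ... Unused.
#' @return Named numeric vector w such that f(x) = w.x + b.
#' @export
coef.gta_svm <- function(object, ...) {
  if (object$kernel != "linear")
    stop("primal coefficients are only defined for the linear kernel")
  w <- as.numeric(t(object$sv_x) %*% (object$sv_alpha * object$sv_y))
  names(w) <- colnames(object$sv_x)
  w
}

#' @export
fitted.gta_svm <- function(object, ...) object$fitted

#' Hinge slack of the training points
#' @param object A \code{gta_svm} fit.
#' @param ... Unused.
#' @return Per-point slack xi = max(0, 1 - y f(x)); zero for points on the
#'   correct side of their margin.
#' @export
residuals.gta_svm <- function(object, ...)
  pmax(0, 1 - object$y * object$fitted)

#' Decision-value plot of a fitted SVM
#'
#' Strip chart of the training decision values by class with the decision
#' boundary (f = 0, solid) and the margins (f = +/-1, dashed).
#'
#' @param x A \code{gta_svm} fit.
#' @param ... Passed to \code{stripchart}.
#' @export
plot.gta_svm <- function(x, ...) {
  cls <- factor(ifelse(x$y < 0, "GTA", "virus"), c("GTA", "virus"))
  graphics::stripchart(split(x$fitted, cls), method = "jitter",
                       vertical = FALSE, pch = 1,
                       xlab = "decision value f(x)", ...)
  graphics::abline(v = 0, lty = 1)
  graphics::abline(v = c(-1, 1), lty = 2)
  invisible(x)
}

#' Serialize / restore a fitted model as versioned JSON text
#'
#' The file carries everything needed for bit-reproducible reload: dual
#' coefficients, support vectors, labels, bias, kernel, C, the feature
#' spec, the frozen k-mer vocabulary, and checksums of the property tables
#' in use.
#'
#' @param object A \code{gta_svm} fit.
#' @param path Output path.
#' @return \code{path} invisibly (\code{write_gta_svm}); a \code{gta_svm}
#'   object (\code{read_gta_svm}).
#' @export
write_gta_svm <- function(object, path) {
  stopifnot(inherits(object, "gta_svm"))
  payload <- list(
    format = "gtahunter-svm", version = 1L,
    kernel = object$kernel, gamma = object$gamma, C = object$C, b = object$b,
    sv_alpha = object$sv_alpha, sv_y = object$sv_y,
    sv_x = apply(object$sv_x, 1, as.numeric, simplify = FALSE),
    feature_names = colnames(object$sv_x),
    vocabulary = object$vocabulary,
    spec = if (!is.null(object$spec)) unclass(object$spec),
    table_md5 = c(
      scales = unname(tools::md5sum(system.file(
        "extdata", "pseaac_scales.tsv", package = "gtahunter"))),
      classes = unname(tools::md5sum(system.file(
        "extdata", "physchem_classes_synthetic.tsv", package = "gtahunter")))))
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null", na = "null"), path)
  invisible(path)
}

#' @rdname write_gta_svm
#' @export
read_gta_svm <- function(path) {
  p <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  if (!identical(p$format, "gtahunter-svm"))
    stop("not a gtahunter model file: ", path)
  sv_x <- do.call(rbind, p$sv_x)
  colnames(sv_x) <- p$feature_names
  opt_int <- function(v) if (is.null(v) || is.na(v)) NA_integer_ else as.integer(v)
  spec <- if (!is.null(p$spec))
    feature_spec(kmer_k = opt_int(p$spec$kmer_k),
                 pseaac_lambda = opt_int(p$spec$pseaac_lambda),
                 pseaac_omega = p$spec$pseaac_omega,
                 physchem = isTRUE(p$spec$physchem),
                 kmer_normalize = isTRUE(p$spec$kmer_normalize))
  structure(list(
    alpha = p$sv_alpha, sv_index = seq_along(p$sv_y), sv_x = sv_x,
    sv_y = p$sv_y, sv_alpha = p$sv_alpha, b = p$b, C = p$C,
    weights = rep(1, length(p$sv_y)), kernel = p$kernel,
    gamma = if (is.null(p$gamma)) NULL else p$gamma,
    vocabulary = p$vocabulary, spec = spec, y = p$sv_y,
    fitted = NULL, kkt = NULL, call = NULL), class = "gta_svm")
}
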