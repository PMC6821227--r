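#' Feature specification for sequence encoding
#'
#' Selects which of the three compositional encoders are active and their
#' parameters. At least one encoder must be active.
#'
#' @param kmer_k k-mer size in 1..6, or \code{NA} to disable the k-mer block.
#' @param pseaac_lambda Pseudo-amino-acid composition rank (number of
#'   sequence-order correlation factors), 3 or 6, or \code{NA} to disable.
#' @param pseaac_omega Weight of the order-correlation terms relative to the
#'   residue frequencies; default 0.05.
#' @param physchem Logical; include the 19 physicochemical class frequencies.
#' @param kmer_normalize Logical; divide k-mer counts by the number of
#'   windows (L - k + 1). Off by default: raw counts are used, which keeps
#'   absolute compositional load visible to the margin; normalization only
#'   rescales features shared by train and query.
#' @return An object of class \code{feature_spec}.
#' @export
feature_spec <- function(kmer_k = NA, pseaac_lambda = NA, pseaac_omega = 0.05,
                         physchem = FALSE, kmer_normalize = FALSE) {
  kmer_k <- if (is.na(kmer_k)) NA_integer_ else as.integer(kmer_k)
  pseaac_lambda <- if (is.na(pseaac_lambda)) NA_integer_ else as.integer(pseaac_lambda)
  if (!is.na(kmer_k) && (kmer_k < 1L || kmer_k > 6L))
    stop("kmer_k must be in 1..6")
  if (!is.na(pseaac_lambda) && pseaac_lambda < 1L)
    stop("pseaac_lambda must be a positive integer")
  if (pseaac_omega < 0) stop("pseaac_omega must be >= 0")
  if (is.na(kmer_k) && is.na(pseaac_lambda) && !physchem)
    stop("at least one encoder must be active")
  structure(list(kmer_k = kmer_k, pseaac_lambda = pseaac_lambda,
                 pseaac_omega = pseaac_omega, physchem = isTRUE(physchem),
                 kmer_normalize = isTRUE(kmer_normalize)),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  parts <- c(
    if (!is.na(x$kmer_k))
      paste0("k-mer (k=", x$kmer_k, if (x$kmer_normalize) ", normalized", ")"),
    if (!is.na(x$pseaac_lambda))
      paste0("PseAAC (lambda=", x$pseaac_lambda, ", omega=", x$pseaac_omega, ")"),
    if (x$physchem) "physicochemical classes (19)")
  cat("Feature spec:", paste(parts, collapse = " + "), "\n")
  invisible(x)
}

#' Amino-acid property scales for PseAAC
#'
#' Loads the raw hydrophobicity, hydrophilicity, and side-chain mass values
#' of the 20 amino acids from a tab-separated table and standardizes each
#' scale to zero mean and unit root-mean-square over the 20 residues (see
#' \code{\link{standardize_scales}}). The shipped table carries the scales
#' classically used for pseudo-amino-acid composition (Hopp-Woods
#' hydrophilicity, consensus hydrophobicity, side-chain masses in Da); users
#' may substitute their own table with the same schema
#' (columns \code{aa}, \code{hydrophobicity}, \code{hydrophilicity},
#' \code{sidechain_mass}).
#'
#' @param path Path to a scale table; default is the packaged table.
#' @return List with matrices \code{raw} and \code{std} (20 x 3, rownames
#'   the amino acids in alphabet order).
#' @export
load_aa_scales <- function(path = system.file("extdata", "pseaac_scales.tsv",
                                              package = "gtahunter")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("aa", "hydrophobicity", "hydrophilicity", "sidechain_mass")
  if (!all(need %in% names(tab))) stop("scale table missing columns: ",
                                       paste(setdiff(need, names(tab)), collapse = ", "))
  if (!setequal(tab$aa, AA_ALPHABET)) stop("scale table must cover exactly the 20 canonical amino acids")
  tab <- tab[match(AA_ALPHABET, tab$aa), ]
  raw <- as.matrix(tab[, need[-1]])
  rownames(raw) <- AA_ALPHABET
  list(raw = raw, std = apply(raw, 2, standardize_scale))
}

#' Standardize one amino-acid property scale
#'
#' Centers the 20 raw values by their mean and divides by the root of the
#' mean squared deviation, so the standardized scale has mean 0 and
#' root-mean-square 1 across the 20 amino acids. Standardizing an already
#' standardized scale is a fixed point.
#'
#' @param raw Numeric vector of 20 raw property values.
#' @return Standardized numeric vector of length 20.
#' @export
standardize_scale <- function(raw) {
  if (length(raw) != 20L) stop("a scale has exactly 20 values")
  centered <- raw - mean(raw)
  denom <- sqrt(mean(centered^2))
  if (denom == 0) stop("constant scale cannot be standardized")
  centered / denom
}

#' @rdname standardize_scale
#' @param raw_mat 20 x p matrix of raw scales (one column per property).
#' @export
standardize_scales <- function(raw_mat) apply(raw_mat, 2, standardize_scale)

#' Count overlapping k-mers in a protein sequence
#'
#' @param seq Character scalar, a cleaned amino-acid sequence.
#' @param k Word size; must not exceed the sequence length.
#' @return Named integer vector of counts over the k-mers observed in
#'   \code{seq}. The counts sum to L - k + 1.
#' @examples
#' kmer_counts("AAG", 2)  # AA = 1, AG = 1
#' @export
kmer_counts <- function(seq, k) {
  L <- nchar(seq)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > L) stop("k (", k, ") exceeds sequence length (", L, ")")
  words <- substring(seq, 1:(L - k + 1L), k:L)
  tab <- table(words)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Pseudo-amino-acid composition of a protein sequence
#'
#' Encodes a sequence as its 20 residue frequencies augmented with
#' \code{lambda} sequence-order correlation factors built from standardized
#' hydrophobicity, hydrophilicity, and side-chain mass. Correlation factor
#' \code{s_k} is the mean, over residue pairs \code{k} positions apart, of
#' the mean squared difference of the three standardized properties. All
#' components share the denominator \code{sum(r) + omega * sum(s)}, so the
#' vector is non-negative and sums to exactly 1; the order terms enter with
#' weight \code{omega}.
#'
#' Residue tallies \code{r} are raw counts; because the shared denominator
#' normalizes the vector regardless, using counts rather than frequencies
#' only rescales the relative influence of \code{omega}.
#'
#' @param seq Character scalar amino-acid sequence of length L > lambda.
#' @param lambda Number of correlation factors (the sequence must be longer
#'   than lambda).
#' @param omega Order-effect weight, default 0.05.
#' @param scales Output of \code{\link{load_aa_scales}}.
#' @return Numeric vector of length 20 + lambda, named
#'   \code{A..Y, pse1..pse<lambda>}.
#' @export
pseaac <- function(seq, lambda, omega = 0.05,
                   scales = load_aa_scales()) {
  L <- nchar(seq)
  lambda <- as.integer(lambda)
  if (L <= lambda)
    stop("sequence length (", L, ") must exceed lambda (", lambda, ")")
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("non-canonical residue in sequence")
  r <- tabulate(idx, nbins = 20L)

  P <- scales$std[idx, , drop = FALSE]   # L x 3 standardized properties
  s <- vapply(seq_len(lambda), function(k) {
    d <- P[(1L + k):L, , drop = FALSE] - P[1:(L - k), , drop = FALSE]
    mean(rowMeans(d^2))                   # mean over pairs of J(i, i+k)
  }, 0)

  denom <- sum(r) + omega * sum(s)
  x <- c(r / denom, omega * s / denom)
  names(x) <- c(AA_ALPHABET, paste0("pse", seq_len(lambda)))
  x
}

#' Physicochemical class table
#'
#' Loads the table of 19 overlapping amino-acid classes used by the
#' physicochemical encoder. The shipped table
#' (\code{physchem_classes_synthetic.tsv}) is a constructed set of standard
#' physicochemical groupings (hydrophobicity, charge, size, chemistry, and
#' secondary-structure propensity); it is a stand-in assembled from common
#' literature definitions, labeled synthetic, and users may substitute a
#' table with the same schema (columns \code{class}, \code{residues}).
#'
#' @param path Path to the class table.
#' @return Named list of 19 character vectors of residues.
#' @export
load_physchem_classes <- function(path = system.file(
  "extdata", "physchem_classes_synthetic.tsv", package = "gtahunter")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("class", "residues") %in% names(tab)))
    stop("class table needs columns 'class' and 'residues'")
  classes <- lapply(strsplit(tab$residues, ""), intersect, x = AA_ALPHABET)
  names(classes) <- tab$class
  if (length(classes) != 19L)
    stop("expected exactly 19 classes, got ", length(classes))
  if (any(lengths(classes) == 0L)) stop("empty class in table")
  classes
}

#' Physicochemical class frequencies of a sequence
#'
#' For each of the 19 (overlapping) classes, the fraction of residues in the
#' sequence belonging to that class.
#'
#' @param seq Character scalar amino-acid sequence.
#' @param classes Output of \code{\link{load_physchem_classes}}.
#' @return Named numeric vector of length 19, each entry in [0, 1].
#' @export
physchem_freqs <- function(seq, classes = load_physchem_classes()) {
  L <- nchar(seq)
  if (L < 1L) stop("empty sequence")
  res <- strsplit(seq, "")[[1]]
  vapply(classes, function(cl) sum(res %in% cl) / L, 0)
}

#' Encode sequences into a feature matrix
#'
#' Applies the encoders activated in \code{spec} to each sequence and
#' concatenates their blocks in fixed order: k-mer counts, PseAAC,
#' physicochemical classes. In training mode (no \code{vocabulary} given)
#' the k-mer vocabulary is the lexicographically sorted union of k-mers over
#' the input sequences, and is returned so it can be frozen into a model. In
#' prediction mode (a \code{vocabulary} is supplied) k-mers outside the
#' vocabulary are ignored and vocabulary k-mers absent from a query count 0,
#' so encoding never depends on the composition of the query batch.
#'
#' @param records Sequence data frame (\code{\link{read_protein_fasta}}) or
#'   character vector of sequences.
#' @param spec A \code{\link{feature_spec}}.
#' @param vocabulary Optional character vector: frozen k-mer vocabulary.
#' @param scales,classes Property tables; defaults load the packaged ones.
#' @return Numeric matrix (rows = sequences, named by id when available)
#'   with attributes \code{vocabulary} (the k-mer vocabulary used, possibly
#'   \code{NULL}) and \code{spec}.
#' @export
encode_features <- function(records, spec, vocabulary = NULL,
                            scales = load_aa_scales(),
                            classes = load_physchem_classes()) {
  stopifnot(inherits(spec, "feature_spec"))
  seqs <- if (is.data.frame(records)) records$seq else as.character(records)
  ids <- if (is.data.frame(records)) records$id else names(records)
  n <- length(seqs)

  blocks <- list()
  if (!is.na(spec$kmer_k)) {
    counts <- lapply(seqs, kmer_counts, k = spec$kmer_k)
    if (is.null(vocabulary))
      vocabulary <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
    km <- matrix(0, n, length(vocabulary),
                 dimnames = list(NULL, vocabulary))
    for (i in seq_len(n)) {
      hit <- counts[[i]][names(counts[[i]]) %in% vocabulary]
      km[i, names(hit)] <- as.numeric(hit)
      if (spec$kmer_normalize)
        km[i, ] <- km[i, ] / (nchar(seqs[i]) - spec$kmer_k + 1L)
    }
    blocks$kmer <- km
  }
  if (!is.na(spec$pseaac_lambda)) {
    blocks$pseaac <- t(vapply(
      seqs, pseaac, numeric(20L + spec$pseaac_lambda),
      lambda = spec$pseaac_lambda, omega = spec$pseaac_omega,
      scales = scales))
    rownames(blocks$pseaac) <- NULL
  }
  if (spec$physchem) {
    blocks$physchem <- t(vapply(seqs, physchem_freqs, numeric(19L),
                                classes = classes))
    rownames(blocks$physchem) <- NULL
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- ids
  attr(X, "vocabulary") <- vocabulary
  attr(X, "spec") <- spec
  X
}
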