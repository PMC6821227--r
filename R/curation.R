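#' Assemble a labeled training set from GTA and virus records
#'
#' @param gta,virus Sequence data frames (\code{\link{read_protein_fasta}}).
#' @return A data frame with the union of records, a label column \code{y}
#'   (-1 for GTA, +1 for virus) and a unit \code{weight} column.
#' @export
training_set <- function(gta, virus) {
  if (nrow(gta) == 0L || nrow(virus) == 0L)
    stop("both classes must be non-empty")
  both <- rbind(cbind(gta, y = -1), cbind(virus, y = 1))
  both$weight <- 1
  clash <- intersect(gta$id, virus$id)
  if (length(clash))
    stop("id(s) present in both classes: ", paste(clash, collapse = ", "))
  rownames(both) <- NULL
  both
}

#' Remove exact duplicate sequences within each class
#'
#' Sequences with identical amino-acid strings carry no extra information
#' and would inflate the cost of misclassifying their neighborhood; within
#' each class only the first occurrence is kept. A sequence occurring in
#' both classes is kept in both (the duplicate rule is within-class); such
#' cross-class conflicts are reported in the \code{conflicts} attribute
#' because they make the classes non-separable at those points.
#'
#' @param set Labeled training set (\code{\link{training_set}}).
#' @return The deduplicated set; attributes \code{n_removed} and
#'   \code{conflicts} (character vector of sequences seen in both classes).
#' @export
deduplicate <- function(set) {
  keep <- !duplicated(paste(set$y, set$seq, sep = "\r"))
  out <- set[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "conflicts") <-
    intersect(out$seq[out$y == -1], out$seq[out$y == 1])
  out
}

#' Filter phylogenetically outlying bacterial homologs
#'
#' For each bacterial (GTA-class) sequence, its outlier distance \code{o}
#' is the mean phylogenetic distance to all other bacterial sequences. A
#' sequence is flagged when \code{o} exceeds the Tukey fence
#' \code{Q3 + 1.5 (Q3 - Q1)} over the bacterial \code{o} distribution
#' (type-7 quartiles, i.e. linear interpolation), and removed only when it
#' is also closer to the viral class than to its own: removal requires
#' \code{o} greater than the shortest distance from that sequence to any
#' viral homolog. Flagged-but-kept sequences are divergent yet still
#' nearer their own class, and stay in the training set.
#'
#' @param dist Distance matrix covering all ids (see
#'   \code{\link{read_distance_matrix}}).
#' @param bacterial_ids,viral_ids Character vectors partitioning the ids of
#'   interest into the two classes.
#' @return List with \code{kept} (bacterial ids retained) and \code{report},
#'   a data frame with per-bacterial-id \code{o}, the fence quartiles,
#'   \code{flagged}, \code{nearest_viral}, and \code{removed}.
#' @export
filter_outliers <- function(dist, bacterial_ids, viral_ids) {
  missing <- setdiff(c(bacterial_ids, viral_ids), rownames(dist))
  if (length(missing))
    stop("ids absent from distance matrix: ", paste(missing, collapse = ", "))
  if (length(bacterial_ids) < 3L)
    stop("need at least 3 bacterial sequences to define quartiles")
  B <- dist[bacterial_ids, bacterial_ids, drop = FALSE]
  nb <- length(bacterial_ids)
  o <- (rowSums(B)) / (nb - 1)              # diagonal is zero
  qs <- stats::quantile(o, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- qs[2] + 1.5 * (qs[2] - qs[1])
  flagged <- o > fence
  nearest_viral <- if (length(viral_ids))
    apply(dist[bacterial_ids, viral_ids, drop = FALSE], 1, min)
  else rep(Inf, nb)
  removed <- flagged & (o > nearest_viral)
  report <- data.frame(
    id = bacterial_ids, o = unname(o), Q1 = qs[1], Q3 = qs[2],
    fence = fence, flagged = unname(flagged),
    nearest_viral = unname(nearest_viral), removed = unname(removed),
    stringsAsFactors = FALSE)
  list(kept = bacterial_ids[!removed], report = report)
}

#' Taxonomic-bias weights by complete-linkage clustering
#'
#' Groups sequences whose phylogenetic distances fall below the threshold
#' \code{t} by farthest-neighbor (complete-linkage) agglomeration: clusters
#' are merged while some pair of clusters has complete-linkage distance
#' strictly below \code{t}. Each sequence then receives weight
#' \code{1 / (group size)}, so a clade of near-identical sequences counts
#' as one sequence in the soft-margin cost and overrepresented taxa do not
#' dominate the hyperplane.
#'
#' Merging always picks the globally closest pair; exact ties are broken by
#' the lexicographically smallest pair of cluster representatives, making
#' the output invariant to the input ordering.
#'
#' @param dist Distance matrix (or submatrix) over the sequences to weight.
#' @param t Non-negative distance threshold; \code{t = 0} leaves every
#'   sequence in its own group (all weights 1).
#' @param ids Optional subset of ids to weight (defaults to all).
#' @return List with \code{groups} (list of character vectors partitioning
#'   the ids) and \code{weights} (named numeric vector, one entry per id).
#' @export
assign_weights <- function(dist, t, ids = rownames(dist)) {
  if (t < 0) stop("threshold t must be non-negative")
  missing <- setdiff(ids, rownames(dist))
  if (length(missing))
    stop("ids absent from distance matrix: ", paste(missing, collapse = ", "))
  n <- length(ids)
  if (n == 0L) stop("no ids to weight")
  D <- dist[ids, ids, drop = FALSE]

  # clusters keyed by their lexicographically smallest member id
  clusters <- as.list(ids)
  names(clusters) <- ids
  cd <- D                                  # complete-linkage distances
  repeat {
    if (length(clusters) < 2L) break
    m <- cd
    diag(m) <- Inf
    best <- min(m)
    if (!(best < t)) break
    cand <- which(m == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairs <- cbind(rownames(cd)[cand[, 1]], colnames(cd)[cand[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    ord <- order(pairs[, 1], pairs[, 2])
    a <- pairs[ord[1], 1]; b <- pairs[ord[1], 2]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
    merged <- pmax(cd[a, ], cd[b, ])       # farthest-neighbor update
    cd[a, ] <- merged; cd[, a] <- merged
    keep <- rownames(cd) != b
    cd <- cd[keep, keep, drop = FALSE]
    cd[a, a] <- 0
  }
  groups <- unname(lapply(clusters, sort))
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  weights <- unlist(lapply(groups, function(g)
    stats::setNames(rep(1 / length(g), length(g)), g)))
  list(groups = groups, weights = weights[ids])
}
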