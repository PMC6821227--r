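#' Chain co-located genes into head-tail cluster candidates
#'
#' One-dimensional density-based clustering of gene coordinates: within each
#' replicon, genes are sorted by start and adjacent genes are linked when
#' the intergenic gap (\code{next start - previous end - 1}, 1-based
#' inclusive coordinates, strand-agnostic) does not exceed \code{eps}.
#' Maximal chains with at least \code{min_size} members are reported. The
#' thresholds in use are \code{eps = 5000, min_size = 9} when curating
#' training regions and \code{eps = 8000, min_size = 6} when calling
#' clusters on predictions (looser because only 11 of the 17 head-tail
#' genes are classified, so observed gaps can be larger). Replicons are
#' treated as linear; a cluster spanning the origin of a circular replicon
#' would be split.
#'
#' @param loci Data frame with columns \code{id}, \code{genome},
#'   \code{replicon}, \code{start}, \code{end} (1-based inclusive).
#' @param eps Maximum intergenic gap in bp between adjacent cluster members.
#' @param min_size Minimum number of genes in a reported cluster.
#' @return Data frame with one row per cluster: \code{genome},
#'   \code{replicon}, \code{start}, \code{end} (span), \code{n_members},
#'   \code{members} (comma-separated gene ids in coordinate order).
#' @export
chain_cluster <- function(loci, eps, min_size) {
  if (eps < 0 || min_size < 1) stop("eps must be >= 0 and min_size >= 1")
  need <- c("id", "replicon", "start", "end")
  if (!all(need %in% names(loci))) stop("loci need columns id, replicon, start, end")
  if (any(is.na(loci$start) | is.na(loci$end) | is.na(loci$replicon)))
    stop("locus without coordinates: ",
         paste(loci$id[is.na(loci$start) | is.na(loci$end) |
                       is.na(loci$replicon)], collapse = ", "))
  if (anyDuplicated(loci$id)) stop("duplicated locus ids")
  if (is.null(loci$genome)) loci$genome <- loci$replicon

  out <- list()
  for (key in unique(paste(loci$genome, loci$replicon, sep = "\r"))) {
    sub <- loci[paste(loci$genome, loci$replicon, sep = "\r") == key, ,
                drop = FALSE]
    sub <- sub[order(sub$start, sub$end, sub$id), , drop = FALSE]
    n <- nrow(sub)
    gaps <- if (n > 1L) sub$start[-1L] - sub$end[-n] - 1L else integer()
    brk <- c(0L, which(gaps > eps), n)
    for (i in seq_len(length(brk) - 1L)) {
      mem <- (brk[i] + 1L):brk[i + 1L]
      if (length(mem) >= min_size)
        out[[length(out) + 1L]] <- data.frame(
          genome = sub$genome[1L], replicon = sub$replicon[1L],
          start = min(sub$start[mem]), end = max(sub$end[mem]),
          n_members = length(mem),
          members = paste(sub$id[mem], collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(genome = character(), replicon = character(),
                      start = integer(), end = integer(),
                      n_members = integer(), members = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$genome, res$replicon, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call GTA head-tail clusters from per-gene classifications
#'
#' Only loci classified "GTA" (decision value < 0) enter the chaining; a
#' genomic region is called a putative GTA head-tail cluster when at least
#' \code{min_size} GTA-classified genes lie with no more than \code{eps} bp
#' between any two adjacent members. All homologs in a chain count toward
#' \code{min_size}, including multiple homologs of the same gene family
#' (the per-cluster member list lets users tighten this).
#'
#' @param predictions Data frame with columns \code{id} and \code{score}
#'   (decision values; \code{class} is recomputed as score < 0) referencing
#'   \code{loci$id}.
#' @param loci Coordinate data frame (see \code{\link{chain_cluster}}).
#' @param eps,min_size Chaining thresholds; defaults 8000 bp and 6 genes.
#' @return As \code{\link{chain_cluster}}, restricted to GTA-classified
#'   loci.
#' @export
call_gta_clusters <- function(predictions, loci, eps = 8000, min_size = 6) {
  if (anyDuplicated(predictions$id)) stop("duplicated prediction ids")
  missing <- setdiff(predictions$id, loci$id)
  if (length(missing))
    stop("prediction id(s) without loci: ", paste(missing, collapse = ", "))
  gta_ids <- predictions$id[predictions$score < 0]
  sub <- loci[loci$id %in% gta_ids, , drop = FALSE]
  if (nrow(sub) == 0L) return(chain_cluster(loci[0, , drop = FALSE],
                                            eps, min_size))
  chain_cluster(sub, eps, min_size)
}

#' Group genomes into OTUs at an ANI threshold
#'
#' Operational taxonomic units are the connected components of the graph
#' whose edges join genome pairs with average nucleotide identity at or
#' above the threshold (single-linkage closure: if a~b and b~c then a, b, c
#' share an OTU even when ANI(a, c) falls below the threshold). Pairs
#' absent from a sparse table are treated as below threshold.
#'
#' @param ani Data frame with columns \code{genome_a}, \code{genome_b},
#'   \code{ani} (percent, in [0, 100]); may be sparse.
#' @param genomes Optional character vector of all genomes (singleton OTUs
#'   are emitted for genomes without qualifying pairs); defaults to the
#'   genomes mentioned in \code{ani}.
#' @param threshold ANI percent cutoff; default 95.
#' @return List of character vectors (sorted members), ordered by first
#'   member; each vector is one OTU.
#' @export
otu_group <- function(ani, genomes = NULL, threshold = 95) {
  if (nrow(ani) > 0 && (any(ani$ani < 0) || any(ani$ani > 100)))
    stop("ANI values must lie in [0, 100]")
  genomes <- sort(unique(c(genomes, ani$genome_a, ani$genome_b)))
  if (length(genomes) == 0L) return(list())
  edges <- ani[ani$ani >= threshold, c("genome_a", "genome_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genomes)
  comp <- igraph::components(g)$membership
  otus <- split(names(comp), comp)
  otus <- unname(lapply(otus, sort))
  otus[order(vapply(otus, `[`, "", 1))]
}

#' OTU-corrected cluster abundance per taxonomic group
#'
#' Corrects raw head-tail cluster counts for taxon overrepresentation: each
#' genome that carries at least one cluster contributes
#' \code{1 / (size of its OTU)} to its group's total, so an OTU of
#' near-identical genomes counts at most once however many of its members
#' were sequenced.
#'
#' @param otus List of OTUs (\code{\link{otu_group}}).
#' @param cluster_genomes Character vector of genomes carrying at least one
#'   called cluster (repeats are collapsed).
#' @param groups Named character vector mapping genome -> taxonomic group
#'   (e.g. order); genomes absent from it are grouped as
#'   \code{"unclassified"}.
#' @return Data frame with \code{group}, \code{corrected} (weighted cluster
#'   count) and \code{raw} (unweighted genome count), one row per group
#'   present.
#' @export
corrected_abundance <- function(otus, cluster_genomes, groups = NULL) {
  cluster_genomes <- unique(cluster_genomes)
  if (length(cluster_genomes) == 0L)
    return(data.frame(group = character(), corrected = numeric(),
                      raw = integer(), stringsAsFactors = FALSE))
  otu_of <- stats::setNames(
    rep(seq_along(otus), lengths(otus)), unlist(otus))
  missing <- setdiff(cluster_genomes, names(otu_of))
  if (length(missing))
    stop("genome(s) not assigned to any OTU: ",
         paste(missing, collapse = ", "))
  w <- 1 / lengths(otus)[otu_of[cluster_genomes]]
  grp <- if (is.null(groups)) rep("all", length(cluster_genomes))
         else {
           g <- groups[cluster_genomes]
           ifelse(is.na(g), "unclassified", g)
         }
  agg <- stats::aggregate(
    list(corrected = w, raw = rep(1L, length(w))),
    by = list(group = grp), FUN = sum)
  agg[order(agg$group), , drop = FALSE]
}
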