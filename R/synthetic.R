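#' Synthetic amino-acid composition profiles for the two classes
#'
#' Emulates the compositional contrast the classifier exploits: GTA
#' proteins are enriched in alanine and glycine relative to their viral
#' homologs. The virus profile is a mildly varying Dirichlet draw around
#' uniform; the GTA profile is the same profile with the combined
#' alanine+glycine mass inflated by the factor \code{1 + 2 * skew} and
#' renormalized, so \code{skew = 0} gives identical classes (the null) and
#' \code{skew = 1} triples the Ala+Gly mass before renormalization.
#'
#' @param skew Enrichment strength in [0, 1].
#' @param concentration Dirichlet concentration per residue for the virus
#'   profile (larger = closer to uniform); default 50.
#' @return List with \code{gta} and \code{virus}, each a named probability
#'   vector over the 20 amino acids summing to 1.
#' @export
make_profiles <- function(skew, concentration = 50) {
  if (skew < 0 || skew > 1) stop("skew must lie in [0, 1]")
  g <- stats::rgamma(20L, shape = concentration)
  virus <- g / sum(g)
  names(virus) <- AA_ALPHABET
  gta <- virus
  gta[c("A", "G")] <- gta[c("A", "G")] * (1 + 2 * skew)
  gta <- gta / sum(gta)
  list(gta = gta, virus = virus)
}

#' Sample i.i.d. protein sequences from a composition profile
#'
#' Residues are drawn independently from the profile and lengths uniformly
#' from \code{len_range}. Independence between positions is a deliberate
#' simplification: every feature the classifier uses is compositional, and
#' under i.i.d. sampling k-mer frequencies are products of marginals, which
#' still separate classes whose marginals differ.
#'
#' @param profile Named probability vector over the 20 amino acids.
#' @param n Number of sequences.
#' @param len_range Integer length range, inclusive.
#' @param prefix Id prefix.
#' @return Sequence data frame compatible with
#'   \code{\link{read_protein_fasta}} output.
#' @export
sample_sequences <- function(profile, n, len_range = c(200L, 400L),
                             prefix = "seq") {
  if (n < 1L) stop("n must be >= 1")
  if (length(len_range) != 2L || len_range[1] < 1L ||
      len_range[1] > len_range[2]) stop("invalid length range")
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  if (len_range[1] == len_range[2]) lens <- rep(len_range[1], n)
  seqs <- vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = profile),
          collapse = ""), "")
  data.frame(id = paste0(prefix, seq_len(n)), seq = seqs,
             genome = NA_character_, replicon = NA_character_,
             start = NA_integer_, end = NA_integer_,
             strand = NA_character_, n_removed = 0L,
             stringsAsFactors = FALSE)
}

#' Plant gene clusters on a synthetic replicon
#'
#' Lays out background genes separated by gaps strictly larger than
#' \code{background_gap} and inserts clusters whose internal gaps are drawn
#' from \code{cluster_gap}, providing ground truth for the chain-clustering
#' step.
#'
#' @param n_background Number of scattered background genes.
#' @param cluster_sizes Integer vector: one planted cluster per entry.
#' @param cluster_gap Range of intra-cluster intergenic gaps (bp).
#' @param background_gap Range of gaps around/between background genes (bp);
#'   the lower bound must exceed the chaining \code{eps} in use.
#' @param gene_len Range of gene lengths (bp).
#' @param genome,replicon Identifiers stamped on the loci.
#' @return List with \code{loci} (coordinate data frame) and \code{truth}
#'   (list of character vectors: the planted cluster memberships).
#' @export
plant_genome <- function(n_background, cluster_sizes = integer(),
                         cluster_gap = c(100L, 4000L),
                         background_gap = c(10000L, 30000L),
                         gene_len = c(300L, 1500L),
                         genome = "synth_genome", replicon = "chr") {
  if (background_gap[1] <= cluster_gap[2])
    stop("background gaps must exceed the largest intra-cluster gap")
  draw <- function(rng) if (rng[1] == rng[2]) rng[1] else
    sample(seq(rng[1], rng[2]), 1L)
  units <- c(rep(list(1L), n_background), as.list(cluster_sizes))
  if (!length(units)) stop("nothing to place")
  units <- sample(units)                  # shuffle cluster positions
  pos <- 1L
  rows <- list(); truth <- list(); gi <- 0L
  for (u in units) {
    member_ids <- character(u)
    for (j in seq_len(u)) {
      gi <- gi + 1L
      len <- draw(gene_len)
      id <- sprintf("gene%03d", gi)
      rows[[gi]] <- data.frame(id = id, genome = genome,
                               replicon = replicon, start = pos,
                               end = pos + len - 1L,
                               strand = sample(c("+", "-"), 1L),
                               stringsAsFactors = FALSE)
      member_ids[j] <- id
      gap <- if (j < u) draw(cluster_gap) else draw(background_gap)
      pos <- pos + len + gap
    }
    if (u > 1L) truth[[length(truth) + 1L]] <- member_ids
  }
  list(loci = do.call(rbind, rows), truth = truth)
}

#' Block-structured synthetic distance matrix
#'
#' Builds a symmetric, zero-diagonal matrix in which sequences within a
#' block sit at distance about \code{intra} and sequences across blocks at
#' about \code{inter}, plus bounded uniform noise. This is the structure
#' complete-linkage weighting and outlier filtering assume: tight clades
#' inside a class, larger distances across clades.
#'
#' @param sizes Integer vector of block sizes.
#' @param intra,inter Baseline within- and between-block distances
#'   (\code{intra < inter}).
#' @param noise Half-width of the uniform perturbation; must be smaller
#'   than \code{(inter - intra) / 2} so blocks stay separated.
#' @param prefix Id prefix; ids are \code{<prefix><block>_<index>}.
#' @return Distance matrix with ids in dimnames, plus attribute
#'   \code{blocks} (list of id vectors).
#' @export
block_distance_matrix <- function(sizes, intra = 0.01, inter = 1,
                                  noise = 0, prefix = "s") {
  if (intra >= inter) stop("intra must be smaller than inter")
  if (noise < 0 || (noise > 0 && noise >= (inter - intra) / 2))
    stop("noise must be below (inter - intra) / 2")
  block <- rep(seq_along(sizes), sizes)
  ids <- sprintf("%s%d_%d", prefix, block,
                 unlist(lapply(sizes, seq_len)))
  n <- length(ids)
  base <- ifelse(outer(block, block, "=="), intra, inter)
  pert <- matrix(0, n, n)
  up <- upper.tri(base)
  pert[up] <- stats::runif(sum(up), -noise, noise)
  m <- base + pert + t(pert)
  m <- pmax(m, 0)
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  attr(m, "blocks") <- split(ids, block)
  m
}

#' Generate a full synthetic two-class training fixture
#'
#' Convenience wrapper tying the generators together: composition profiles
#' at the requested skew, sequence sets for both classes, and a
#' block-structured distance matrix over all ids (one block per simulated
#' clade within each class, inter-class distances largest).
#'
#' @param n_gta,n_virus Class sizes; defaults 60 and 60.
#' @param skew Ala/Gly enrichment of the GTA class; default 0.5.
#' @param len_range Sequence length range; default 200..400.
#' @param blocks_per_class Simulated clades per class (for the distance
#'   matrix); default 3.
#' @return List with \code{set} (labeled training set), \code{dist}
#'   (distance matrix), and \code{profiles}.
#' @export
synthetic_training_fixture <- function(n_gta = 60L, n_virus = 60L,
                                       skew = 0.5,
                                       len_range = c(200L, 400L),
                                       blocks_per_class = 3L) {
  prof <- make_profiles(skew)
  gta <- sample_sequences(prof$gta, n_gta, len_range, prefix = "gta")
  virus <- sample_sequences(prof$virus, n_virus, len_range, prefix = "vir")
  set <- training_set(gta, virus)
  split_sizes <- function(n, b) {
    s <- rep(n %/% b, b); s[seq_len(n %% b)] <- s[seq_len(n %% b)] + 1L; s
  }
  sizes <- c(split_sizes(n_gta, blocks_per_class),
             split_sizes(n_virus, blocks_per_class))
  m <- block_distance_matrix(sizes, intra = 0.02, inter = 0.6,
                             noise = 0.005)
  # relabel block ids with the real sequence ids (GTA blocks first),
  # and push the two classes further apart than any within-class pair
  ids <- c(gta$id, virus$id)
  dimnames(m) <- list(ids, ids)
  is_gta <- seq_along(ids) <= n_gta
  cross <- outer(is_gta, is_gta, "!=")
  m[cross] <- m[cross] + 0.8
  attr(m, "blocks") <- NULL
  list(set = set, dist = m, profiles = prof)
}
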