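# Amino-acid alphabet used throughout: the 20 canonical residues, fixed order.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' Reads amino-acid sequences and cleans them to the 20-letter canonical
#' alphabet. Characters outside the alphabet (ambiguity codes \code{X B Z J},
#' the rare residues \code{U O}, stop \code{*}, and gap characters) are
#' removed, not recoded, because every downstream compositional feature is
#' defined only over the 20 canonical amino acids; the number of removed
#' characters is recorded per record.
#'
#' Genomic coordinates may be carried in the header using the convention
#' \code{id|genome|replicon|start|end|strand} with 1-based inclusive
#' coordinates (GenBank convention), or supplied separately as a BED sidecar
#' via \code{\link{read_bed_coords}}.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A data frame with one row per record and columns \code{id},
#'   \code{seq}, \code{genome}, \code{replicon}, \code{start}, \code{end},
#'   \code{strand}, and \code{n_removed} (count of non-canonical characters
#'   stripped from the sequence).
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">q1|gnm1|chr1|100|400|+", "MKXLA"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  raw <- toupper(as.character(set))

  parsed <- lapply(headers, parse_fasta_header)
  ids <- vapply(parsed, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))

  cleaned <- clean_sequences(raw)
  empty <- nchar(cleaned$seq) == 0L
  if (any(empty))
    stop("sequence(s) empty after removing non-canonical characters: ",
         paste(ids[empty], collapse = ", "))

  out <- data.frame(
    id = ids,
    seq = cleaned$seq,
    genome = vapply(parsed, `[[`, "", "genome"),
    replicon = vapply(parsed, `[[`, "", "replicon"),
    start = vapply(parsed, `[[`, NA_integer_, "start"),
    end = vapply(parsed, `[[`, NA_integer_, "end"),
    strand = vapply(parsed, `[[`, NA_character_, "strand"),
    n_removed = cleaned$n_removed,
    stringsAsFactors = FALSE
  )
  bad <- !is.na(out$start) & !is.na(out$end) & out$start > out$end
  if (any(bad))
    stop("start > end for record(s): ", paste(out$id[bad], collapse = ", "))
  rownames(out) <- NULL
  out
}

parse_fasta_header <- function(h) {
  # first whitespace-delimited token carries the pipe-separated fields
  tok <- strsplit(trimws(h), "[ \t]")[[1]][1]
  parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
  if (length(parts) == 0L || !nzchar(parts[1])) stop("empty id in header: ", h)
  res <- list(id = parts[1], genome = NA_character_, replicon = NA_character_,
              start = NA_integer_, end = NA_integer_, strand = NA_character_)
  if (length(parts) >= 2L && nzchar(parts[2])) res$genome <- parts[2]
  if (length(parts) >= 3L && nzchar(parts[3])) res$replicon <- parts[3]
  if (length(parts) >= 4L && nzchar(parts[4])) res$start <- as.integer(parts[4])
  if (length(parts) >= 5L && nzchar(parts[5])) res$end <- as.integer(parts[5])
  if (length(parts) >= 6L && nzchar(parts[6])) {
    if (!parts[6] %in% c("+", "-")) stop("bad strand '", parts[6], "' in header: ", h)
    res$strand <- parts[6]
  }
  res
}

clean_sequences <- function(seqs) {
  kept <- gsub(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), "", seqs)
  list(seq = kept, n_removed = nchar(seqs) - nchar(kept))
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of \code{\link{read_protein_fasta}}: coordinate fields present in
#' \code{records} are serialized back into the
#' \code{id|genome|replicon|start|end|strand} header convention.
#'
#' @param records Data frame as returned by \code{\link{read_protein_fasta}}
#'   (columns beyond \code{id} and \code{seq} are optional).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  hdr <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    fields <- c(r$id,
                if (!is.null(r$genome)) r$genome else NA,
                if (!is.null(r$replicon)) r$replicon else NA,
                if (!is.null(r$start)) r$start else NA,
                if (!is.null(r$end)) r$end else NA,
                if (!is.null(r$strand)) r$strand else NA)
    last <- max(c(1L, which(!is.na(fields))))
    paste(ifelse(is.na(fields[seq_len(last)]), "", fields[seq_len(last)]),
          collapse = "|")
  }, "")
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Attach coordinates from a BED file to sequence records
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read (\code{start + 1}, \code{end}
#' unchanged). The BED \code{name} column (4th) links rows to record ids.
#'
#' @param records Sequence data frame (\code{\link{read_protein_fasta}}).
#' @param path Path to a 4- to 6-column BED file
#'   (\code{chrom start end name [score] [strand]}).
#' @return \code{records} with \code{replicon}, \code{start}, \code{end},
#'   \code{strand} filled for the ids named in the BED file. The replicon's
#'   genome is left untouched unless absent, in which case \code{chrom} is
#'   reused as \code{genome}.
#' @export
read_bed_coords <- function(records, path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 4L) stop("BED sidecar needs at least 4 columns (name in col 4)")
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  idx <- match(bed$name, records$id)
  if (anyNA(idx))
    stop("BED name(s) not in records: ",
         paste(bed$name[is.na(idx)], collapse = ", "))
  records$replicon[idx] <- bed$chrom
  records$start[idx] <- as.integer(bed$start) + 1L  # 0-based -> 1-based
  records$end[idx] <- as.integer(bed$end)
  if (ncol(bed) >= 6L) records$strand[idx] <- bed[[6]]
  if (all(is.na(records$genome[idx]))) records$genome[idx] <- bed$chrom
  records
}

#' Read a square labeled distance matrix
#'
#' Reads a tab-separated matrix with matching row and column labels, as
#' produced by phylogenetic distance estimation. The matrix must be
#' symmetric (asymmetry beyond 1e-6 is an error), non-negative, and have a
#' zero diagonal.
#'
#' @param path Path to a TSV with column labels in the first row and row
#'   labels in the first column.
#' @return A numeric matrix with \code{dimnames} set to the sequence ids.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric cell(s) in distance matrix")
  if (nrow(m) != ncol(m)) stop("distance matrix is not square: ",
                               nrow(m), " x ", ncol(m))
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      any(!nzchar(rownames(m))))
    stop("distance matrix must carry row and column labels")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ")
  validate_distance_matrix(m)
  m
}

validate_distance_matrix <- function(m, tol = 1e-6) {
  if (anyNA(m)) stop("missing values in distance matrix")
  if (max(abs(m - t(m))) > tol)
    stop("distance matrix asymmetric beyond ", tol)
  if (any(m < 0)) stop("negative distances")
  if (any(abs(diag(m)) > tol)) stop("nonzero diagonal")
  invisible(m)
}

#' Write a labeled distance matrix
#' @param m Symmetric numeric matrix with dimnames.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  validate_distance_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write classifier predictions to a TSV file
#'
#' One row per query, in input order: query id, identifier of the per-gene
#' model that scored it, the decision value f(x), and the class call
#' (\code{"GTA"} when f(x) < 0, \code{"virus"} otherwise).
#'
#' @param ids Character vector of query ids.
#' @param scores Numeric decision values, aligned with \code{ids}.
#' @param model_id Model identifier(s); length 1 or \code{length(ids)}.
#' @param path Output path.
#' @return The prediction data frame, invisibly.
#' @export
write_predictions <- function(ids, scores, model_id = "model", path) {
  if (length(ids) != length(scores))
    stop("ids and scores differ in length (", length(ids), " vs ",
         length(scores), ")")
  if (!length(model_id) %in% c(1L, length(ids)) && length(ids) > 0L)
    stop("model_id must have length 1 or length(ids)")
  df <- data.frame(
    id = as.character(ids),
    model = if (length(ids)) rep_len(as.character(model_id), length(ids)) else character(),
    score = as.numeric(scores),
    class = ifelse(scores < 0, "GTA", "virus"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
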