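# Sequence-logo conservation over a query-anchored MSA assembled from
# pairwise hits: per-column consensus-character height (bits) and occupancy.

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Stack pairwise hits into a query-anchored multiple alignment
#'
#' Each pairwise hit contributes one row: its subject residues are placed at
#' the query coordinates they align to. Columns where the hit's query row is
#' gapped (subject insertions) are dropped, so every row has exactly one
#' column per query residue; positions outside the hit's aligned span are
#' gap-filled. Row 1 is always the ungapped query itself.
#'
#' @param query Query amino-acid sequence (string).
#' @param hits List of [pairwise_alignment()] objects with the query as
#'   their `qseqid` side.
#' @param query_id Optional query accession; when given, hits whose
#'   `qseqid` differs raise an error.
#' @return A list of class `query_anchored_msa` with `query`, `rows`
#'   (character matrix, one row per sequence, one column per query
#'   position) and `ids`.
#' @export
stack_alignments <- function(query, hits = list(), query_id = NULL) {
  query <- toupper(query)
  qlen <- nchar(query)
  if (qlen == 0L) stop("empty query sequence", call. = FALSE)
  rows <- matrix("-", nrow = 1L + length(hits), ncol = qlen)
  rows[1L, ] <- strsplit(query, "")[[1]]
  ids <- c(if (is.null(query_id)) "query" else query_id,
           vapply(hits, `[[`, character(1), "sseqid"))
  for (h in seq_along(hits)) {
    aln <- hits[[h]]
    if (!is.null(query_id) && aln$qseqid != query_id) {
      stop(sprintf("hit %d has query id '%s', expected '%s'",
                   h, aln$qseqid, query_id), call. = FALSE)
    }
    if (aln$qstart < 1L || aln$qend > qlen) {
      stop(sprintf("hit %d (%s) spans query %d..%d, outside 1..%d",
                   h, aln$sseqid, aln$qstart, aln$qend, qlen), call. = FALSE)
    }
    co <- .alignment_coords(aln)
    keep <- !is.na(co$qpos)   # drop subject-insertion columns
    rows[h + 1L, co$qpos[keep]] <- toupper(co$s[keep])
  }
  structure(list(query = query, rows = rows, ids = ids),
            class = "query_anchored_msa")
}

# letters outside the 20-residue alphabet (B, Z, X, U, O, ...) carry no
# defined frequency class and are treated as gaps throughout
.column_letters <- function(msa, j) {
  col <- msa$rows[, j]
  col[col %in% .aa20]
}

#' Logo statistics for one MSA column
#'
#' Occupancy is the fraction of rows holding a standard residue in the
#' column. Frequencies over the 20-letter alphabet are taken among those
#' rows only; the column information content is R = log2(20) - H with H the
#' Shannon entropy of the frequencies, and the consensus height is the
#' consensus letter's frequency times R (ties broken alphabetically). An
#' empty column yields (consensus NA, height 0, occupancy 0).
#'
#' @param msa A [stack_alignments()] result.
#' @param j Column index (1-based query position).
#' @param small_sample_correction Subtract the small-sample correction
#'   (19 / (2 ln 2 n)) from R? Default FALSE.
#' @return A list with `consensus`, `height` (bits), `occupancy`.
#' @export
column_stats <- function(msa, j, small_sample_correction = FALSE) {
  stopifnot(inherits(msa, "query_anchored_msa"))
  if (j < 1L || j > ncol(msa$rows)) {
    stop(sprintf("column %d out of range 1..%d", j, ncol(msa$rows)),
         call. = FALSE)
  }
  letters <- .column_letters(msa, j)
  n <- length(letters)
  total <- nrow(msa$rows)
  if (n == 0L) {
    return(list(consensus = NA_character_, height = 0, occupancy = 0))
  }
  counts <- table(factor(letters, levels = .aa20))
  f <- as.numeric(counts) / n
  nz <- f > 0
  H <- -sum(f[nz] * log2(f[nz]))
  R <- log2(20) - H
  if (small_sample_correction) {
    R <- max(R - (length(.aa20) - 1) / (2 * log(2) * n), 0)
  }
  consensus <- .aa20[which.max(f)]  # which.max takes the first = alphabetical
  list(consensus = consensus, height = f[which.max(f)] * R,
       occupancy = n / total)
}

#' Per-column conservation track of a query-anchored MSA
#'
#' @param msa A [stack_alignments()] result.
#' @param small_sample_correction See [column_stats()].
#' @return `data.frame` with one row per query position: `position`,
#'   `query_aa`, `consensus`, `height_bits`, `occupancy`.
#' @export
conservation_track <- function(msa, small_sample_correction = FALSE) {
  stopifnot(inherits(msa, "query_anchored_msa"))
  n <- ncol(msa$rows)
  stats <- lapply(seq_len(n), column_stats, msa = msa,
                  small_sample_correction = small_sample_correction)
  data.frame(
    position = seq_len(n),
    query_aa = msa$rows[1L, ],
    consensus = vapply(stats, `[[`, character(1), "consensus"),
    height_bits = vapply(stats, `[[`, numeric(1), "height"),
    occupancy = vapply(stats, `[[`, numeric(1), "occupancy"),
    stringsAsFactors = FALSE
  )
}
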