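#' Construct a table of annotated regions
#'
#' Regions are 1-based inclusive intervals on a protein sequence, following
#' the UniProt convention, each carrying a controlled-vocabulary triplet
#' (evidence / feature / source).
#'
#' @param start,end Integer vectors of interval bounds, 1-based inclusive.
#' @param feature,evidence,source Character vectors (recycled) with the CV
#'   terms attached to each region.
#' @return A `data.frame` with columns `start`, `end`, `feature`, `evidence`,
#'   `source`. Zero-row input is allowed and yields a zero-row table.
#' @examples
#' region_table(c(1, 20), c(10, 30), feature = "disorder",
#'              evidence = "prediction", source = "alphafold-plddt")
#' @export
region_table <- function(start = integer(), end = integer(),
                         feature = character(), evidence = character(),
                         source = character()) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("'start' and 'end' must have the same length", call. = FALSE)
  }
  n <- length(start)
  if (n > 0L) {
    if (anyNA(start) || anyNA(end)) stop("region bounds must not be NA", call. = FALSE)
    if (any(start < 1L)) stop("region start must be >= 1", call. = FALSE)
    if (any(end < start)) stop("region end must be >= start", call. = FALSE)
  }
  recycle <- function(x, default) {
    if (length(x) == 0L) x <- default
    rep_len(as.character(x), n)
  }
  df <- data.frame(
    start = start,
    end = end,
    feature = recycle(feature, NA_character_),
    evidence = recycle(evidence, NA_character_),
    source = recycle(source, NA_character_),
    stringsAsFactors = FALSE
  )
  class(df) <- c("region_table", "data.frame")
  df
}

#' Region lengths
#'
#' @param regions A region table (see [region_table()]).
#' @return Integer vector of `end - start + 1`.
#' @export
region_length <- function(regions) {
  regions$end - regions$start + 1L
}

#' Extract maximal runs of a residue mask as regions
#'
#' Converts a logical per-residue mask into the maximal runs of consecutive
#' `TRUE` flags, reported as 1-based inclusive regions. Runs shorter than
#' `min_length` are discarded.
#'
#' @param mask Logical vector, one flag per residue. Must be non-empty; `NA`
#'   is not allowed.
#' @param min_length Minimum run length to keep (default 1).
#' @param feature,evidence,source CV terms attached to the emitted regions.
#' @return A region table, sorted by start, pairwise disjoint.
#' @examples
#' regions_from_mask(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
#'                   min_length = 2)
#' @export
regions_from_mask <- function(mask, min_length = 1L,
                              feature = NA_character_,
                              evidence = NA_character_,
                              source = NA_character_) {
  if (length(mask) == 0L) stop("mask must contain at least one residue", call. = FALSE)
  if (!is.logical(mask) || anyNA(mask)) {
    stop("mask must be a logical vector without NA", call. = FALSE)
  }
  min_length <- as.integer(min_length)
  if (is.na(min_length) || min_length < 1L) {
    stop("min_length must be a positive integer", call. = FALSE)
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  region_table(starts[keep], ends[keep],
               feature = feature, evidence = evidence, source = source)
}

#' Elementwise intersection of residue masks
#'
#' @param a,b Logical vectors of equal length.
#' @return Logical vector: `a & b`.
#' @export
mask_intersection <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("mask lengths differ (%d vs %d)", length(a), length(b)),
         call. = FALSE)
  }
  if (!is.logical(a) || !is.logical(b)) stop("masks must be logical", call. = FALSE)
  a & b
}

#' Resolve overlapping regions greedily, longest first
#'
#' Candidates are visited in order of decreasing length; a candidate is kept
#' if and only if it overlaps none of the regions already kept. Ties on
#' length are broken by smaller start, then by lexicographic source term, so
#' the result is deterministic. The output is sorted by start, pairwise
#' non-overlapping, and maximal: no rejected candidate could be added back
#' without creating an overlap.
#'
#' @param candidates A region table.
#' @return The accepted subset, as a region table sorted by start.
#' @examples
#' greedy_overlap_resolve(region_table(c(1, 40), c(50, 60)))
#' @export
greedy_overlap_resolve <- function(candidates) {
  candidates <- as.data.frame(candidates)
  n <- nrow(candidates)
  if (n == 0L) {
    return(region_table())
  }
  if (any(candidates$start < 1L) || any(candidates$end < candidates$start)) {
    stop("invalid region in candidates", call. = FALSE)
  }
  len <- candidates$end - candidates$start + 1L
  src <- as.character(candidates$source)
  src[is.na(src)] <- ""
  ord <- order(-len, candidates$start, src, method = "radix")
  kept <- integer(0)
  for (i in ord) {
    s <- candidates$start[i]
    e <- candidates$end[i]
    if (length(kept) == 0L ||
        all(e < candidates$start[kept] | s > candidates$end[kept])) {
      kept <- c(kept, i)
    }
  }
  out <- candidates[kept[order(candidates$start[kept])], , drop = FALSE]
  rownames(out) <- NULL
  region_table(out$start, out$end,
               feature = out$feature, evidence = out$evidence,
               source = out$source)
}
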