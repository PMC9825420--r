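#' Read a FASTA file of protein sequences
#'
#' @param path FASTA file, multi-line records accepted.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header. Empty files and
#'   duplicate identifiers raise errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file holds no records: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Build an annotation document
#'
#' The document is the package's output unit: one protein with its sequence
#' and a list of annotation tracks, each keyed by a controlled-vocabulary
#' triplet (evidence / feature / source) and carrying its regions as
#' 1-based inclusive `[start, end]` pairs, optionally with per-residue
#' scores.
#'
#' @param accession Protein accession.
#' @param sequence Amino-acid sequence.
#' @param tracks List of tracks; each a list with `evidence`, `feature`,
#'   `source`, `regions` (two-column matrix or list of pairs), and optional
#'   `scores` (numeric, one per residue).
#' @return A list of class `annotation_document`, validated: every triplet
#'   must exist in the packaged vocabulary and every region must lie within
#'   the sequence.
#' @export
annotation_document <- function(accession, sequence, tracks = list()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  norm <- lapply(tracks, function(tr) {
    cv_validate_triplet(tr$evidence, tr$feature, tr$source)
    regions <- tr$regions
    if (is.data.frame(regions)) regions <- cbind(regions$start, regions$end)
    if (is.list(regions) && !is.data.frame(regions)) {
      regions <- do.call(rbind, lapply(regions, as.integer))
    }
    if (is.null(regions) || length(regions) == 0L) {
      regions <- matrix(integer(), ncol = 2L)
    }
    regions <- matrix(as.integer(regions), ncol = 2L)
    if (nrow(regions) > 0L) {
      if (any(regions[, 1] < 1L) || any(regions[, 2] < regions[, 1])) {
        stop("invalid region bounds in track", call. = FALSE)
      }
      if (any(regions[, 2] > n)) {
        stop(sprintf("region end %d exceeds sequence length %d",
                     max(regions[, 2]), n), call. = FALSE)
      }
    }
    out <- list(evidence = tr$evidence, feature = tr$feature,
                source = tr$source, regions = regions)
    if (!is.null(tr$scores)) {
      if (length(tr$scores) != n) {
        stop("per-residue scores must match sequence length", call. = FALSE)
      }
      out$scores <- as.numeric(tr$scores)
    }
    out
  })
  structure(list(accession = accession, sequence = sequence, tracks = norm),
            class = "annotation_document")
}

#' Write an annotation document as JSON
#'
#' Key order is fixed and numbers are written in full precision, so
#' write -> read -> write is byte-stable.
#'
#' @param doc An [annotation_document()].
#' @param path Output file.
#' @export
write_annotation_json <- function(doc, path) {
  stopifnot(inherits(doc, "annotation_document"))
  tracks <- lapply(doc$tracks, function(tr) {
    out <- list(
      evidence = jsonlite::unbox(tr$evidence),
      feature = jsonlite::unbox(tr$feature),
      source = jsonlite::unbox(tr$source),
      regions = if (nrow(tr$regions) == 0L) list() else
        lapply(seq_len(nrow(tr$regions)), function(i) tr$regions[i, ])
    )
    if (!is.null(tr$scores)) out$scores <- tr$scores
    out
  })
  body <- list(accession = jsonlite::unbox(doc$accession),
               sequence = jsonlite::unbox(doc$sequence),
               tracks = tracks)
  json <- jsonlite::toJSON(body, digits = NA, pretty = 2)
  writeLines(json, path)
  invisible(path)
}

#' Read an annotation document written by [write_annotation_json()]
#'
#' @param path JSON file.
#' @return An [annotation_document()] (re-validated on read).
#' @export
read_annotation_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tracks <- lapply(x$tracks, function(tr) {
    out <- list(evidence = tr$evidence, feature = tr$feature,
                source = tr$source,
                regions = lapply(tr$regions, function(p) c(p[[1]], p[[2]])))
    if (!is.null(tr$scores)) out$scores <- unlist(tr$scores)
    out
  })
  annotation_document(x$accession, x$sequence, tracks)
}

#' Write the per-residue profile table of a structure annotation as TSV
#'
#' @param profiles The `profiles` data.frame from [annotate_structure()].
#' @param path Output file.
#' @export
write_profile_tsv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a curated-region TSV
#'
#' @param path Tab-separated file with header columns `accession`, `start`,
#'   `end`, `feature`, `source`.
#' @return `data.frame` with those columns.
#' @export
read_region_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "start", "end", "feature", "source")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("region TSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  if (anyNA(d$start) || anyNA(d$end) || any(d$start < 1L) || any(d$end < d$start)) {
    stop("invalid region bounds in ", path, call. = FALSE)
  }
  d
}
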