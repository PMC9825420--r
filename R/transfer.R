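#' Acceptance thresholds for homology transfer
#'
#' A projected region is transferred only when the alignment fragment covers
#' at least `min_query_coverage` of the annotated query region, gap columns
#' make up at most `max_gap_fraction` of the fragment, and at least
#' `min_identity` of the fragment columns are identical residue pairs.
#' Boundaries are inclusive on the passing side.
#'
#' @param min_query_coverage Fraction in (0, 1\]; default 0.90.
#' @param max_gap_fraction Fraction in (0, 1\]; default 0.20.
#' @param min_identity Fraction in (0, 1\]; default 0.80.
#' @return A list of class `transfer_thresholds`.
#' @export
transfer_thresholds <- function(min_query_coverage = 0.90,
                                max_gap_fraction = 0.20,
                                min_identity = 0.80) {
  for (v in c(min_query_coverage, max_gap_fraction, min_identity)) {
    if (!is.numeric(v) || v <= 0 || v > 1) {
      stop("thresholds must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(min_query_coverage = min_query_coverage,
                 max_gap_fraction = max_gap_fraction,
                 min_identity = min_identity),
            class = "transfer_thresholds")
}

#' Construct a validated pairwise alignment
#'
#' @param qseqid,sseqid Query and subject accessions.
#' @param qstart,qend,sstart,send 1-based inclusive coordinates on the
#'   ungapped query and subject sequences.
#' @param qseq,sseq Aligned strings of equal length, gap symbol `-`.
#' @return A list of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(qseqid, sseqid, qstart, qend, sstart, send,
                               qseq, sseq) {
  qstart <- as.integer(qstart); qend <- as.integer(qend)
  sstart <- as.integer(sstart); send <- as.integer(send)
  if (nchar(qseq) != nchar(sseq)) {
    stop("aligned strings differ in length", call. = FALSE)
  }
  qv <- strsplit(qseq, "")[[1]]
  sv <- strsplit(sseq, "")[[1]]
  if (any(qv == "-" & sv == "-")) {
    stop("column gapped in both rows", call. = FALSE)
  }
  if (sum(qv != "-") != qend - qstart + 1L) {
    stop(sprintf("query aligned string has %d residues but coordinates span %d",
                 sum(qv != "-"), qend - qstart + 1L), call. = FALSE)
  }
  if (sum(sv != "-") != send - sstart + 1L) {
    stop(sprintf("subject aligned string has %d residues but coordinates span %d",
                 sum(sv != "-"), send - sstart + 1L), call. = FALSE)
  }
  structure(list(qseqid = qseqid, sseqid = sseqid,
                 qstart = qstart, qend = qend,
                 sstart = sstart, send = send,
                 qseq = qseq, sseq = sseq),
            class = "pairwise_alignment")
}

#' Parse one BLAST tabular record
#'
#' Expects the eight tab-separated fields `qseqid sseqid qstart qend sstart
#' send qseq sseq` (BLAST `-outfmt "6 qseqid sseqid qstart qend sstart send
#' qseq sseq"`).
#'
#' @param line One text record.
#' @param line_number Used in error messages.
#' @return A [pairwise_alignment()].
#' @export
parse_blast_record <- function(line, line_number = NA_integer_) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  where <- if (is.na(line_number)) "" else sprintf(" (line %d)", line_number)
  if (length(fields) != 8L) {
    stop(sprintf("expected 8 tab-separated fields, got %d%s",
                 length(fields), where), call. = FALSE)
  }
  coords <- suppressWarnings(as.integer(fields[3:6]))
  if (anyNA(coords)) {
    stop(sprintf("non-integer alignment coordinates%s", where), call. = FALSE)
  }
  tryCatch(
    pairwise_alignment(fields[1], fields[2], coords[1], coords[2],
                       coords[3], coords[4], fields[7], fields[8]),
    error = function(e) {
      stop(sprintf("invalid alignment record%s: %s", where, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

#' Read a BLAST tabular file of alignments
#'
#' @param path File with one record per line (see [parse_blast_record()]);
#'   empty lines and `#` comment lines are skipped.
#' @return List of [pairwise_alignment()] objects.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  lapply(keep, function(i) parse_blast_record(lines[i], i))
}

# per-column query/subject coordinates of an alignment; gap columns get NA
.alignment_coords <- function(aln) {
  qv <- strsplit(aln$qseq, "")[[1]]
  sv <- strsplit(aln$sseq, "")[[1]]
  qpos <- rep(NA_integer_, length(qv))
  qpos[qv != "-"] <- seq(aln$qstart, aln$qend)
  spos <- rep(NA_integer_, length(sv))
  spos[sv != "-"] <- seq(aln$sstart, aln$send)
  list(q = qv, s = sv, qpos = qpos, spos = spos)
}

#' Project an annotated query region through a pairwise alignment
#'
#' The fragment is the set of alignment columns whose query coordinate lies
#' within the region; query-gap columns (subject insertions) are included
#' when their insertion point falls strictly inside the region. The
#' candidate records the projected subject interval plus the three filter
#' statistics: query coverage (region residues present in the fragment /
#' region length), gap fraction (gap columns in either row / fragment
#' columns) and identity (identical residue pairs / fragment columns).
#'
#' @param aln A [pairwise_alignment()].
#' @param region One-row region table (or list with `start`, `end`,
#'   `feature`, `source`).
#' @return A list of class `transfer_candidate` with fields `query_region`,
#'   `projected` (NULL when nothing projects), `fragment_columns`,
#'   `coverage`, `gap_fraction`, `identity`, `verdict` (`"pending"`,
#'   `"rejected"`), `reason`.
#' @export
project_region <- function(aln, region) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  rstart <- as.integer(region$start)
  rend <- as.integer(region$end)
  rlen <- rend - rstart + 1L
  cand <- structure(list(
    qseqid = aln$qseqid, sseqid = aln$sseqid,
    query_region = c(start = rstart, end = rend),
    feature = if (!is.null(region$feature)) as.character(region$feature) else NA_character_,
    source = if (!is.null(region$source)) as.character(region$source) else NA_character_,
    projected = NULL, fragment_columns = 0L,
    coverage = 0, gap_fraction = 0, identity = 0,
    verdict = "pending", reason = NA_character_
  ), class = "transfer_candidate")
  if (rend < aln$qstart || rstart > aln$qend) {
    cand$verdict <- "rejected"
    cand$reason <- "no-overlap"
    return(cand)
  }
  co <- .alignment_coords(aln)
  # carry the preceding query coordinate into gap columns to place insertions
  last_q <- co$qpos
  for (i in seq_along(last_q)) {
    if (is.na(last_q[i])) last_q[i] <- if (i == 1L) aln$qstart - 1L else last_q[i - 1L]
  }
  in_frag <- (!is.na(co$qpos) & co$qpos >= rstart & co$qpos <= rend) |
    (is.na(co$qpos) & last_q >= rstart & last_q <= rend - 1L)
  ncol_frag <- sum(in_frag)
  q <- co$q[in_frag]; s <- co$s[in_frag]
  spos <- co$spos[in_frag]
  cand$fragment_columns <- ncol_frag
  cand$coverage <- sum(q != "-") / rlen
  cand$gap_fraction <- if (ncol_frag > 0L) sum(q == "-" | s == "-") / ncol_frag else 0
  cand$identity <- if (ncol_frag > 0L) sum(q != "-" & s != "-" & q == s) / ncol_frag else 0
  if (all(is.na(spos))) {
    cand$verdict <- "rejected"
    cand$reason <- "subject-all-gaps"
    return(cand)
  }
  cand$projected <- c(start = min(spos, na.rm = TRUE),
                      end = max(spos, na.rm = TRUE))
  cand
}

#' Apply the transfer acceptance filters to a candidate
#'
#' Accept when coverage >= min_query_coverage AND gap fraction <=
#' max_gap_fraction AND identity >= min_identity; otherwise reject,
#' recording the first failing criterion (checked in that order).
#'
#' @param candidate A candidate from [project_region()].
#' @param t A [transfer_thresholds()].
#' @return The candidate with `verdict` set to `"accepted"` or
#'   `"rejected"` and `reason` filled in.
#' @export
apply_thresholds <- function(candidate, t = transfer_thresholds()) {
  stopifnot(inherits(candidate, "transfer_candidate"))
  if (identical(candidate$verdict, "rejected")) return(candidate)
  if (candidate$coverage < t$min_query_coverage) {
    candidate$verdict <- "rejected"; candidate$reason <- "coverage"
  } else if (candidate$gap_fraction > t$max_gap_fraction) {
    candidate$verdict <- "rejected"; candidate$reason <- "gaps"
  } else if (candidate$identity < t$min_identity) {
    candidate$verdict <- "rejected"; candidate$reason <- "identity"
  } else {
    candidate$verdict <- "accepted"; candidate$reason <- NA_character_
  }
  candidate
}

# flatten a candidate into one audit row
.candidate_row <- function(cand) {
  data.frame(
    qseqid = cand$qseqid, sseqid = cand$sseqid,
    query_start = cand$query_region[["start"]],
    query_end = cand$query_region[["end"]],
    subject_start = if (is.null(cand$projected)) NA_integer_ else cand$projected[["start"]],
    subject_end = if (is.null(cand$projected)) NA_integer_ else cand$projected[["end"]],
    feature = cand$feature, source = cand$source,
    fragment_columns = cand$fragment_columns,
    coverage = cand$coverage, gap_fraction = cand$gap_fraction,
    identity = cand$identity, verdict = cand$verdict, reason = cand$reason,
    stringsAsFactors = FALSE
  )
}

#' Transfer curated region annotations through a set of alignments
#'
#' For every alignment and every curated region on its query, the region is
#' projected, filtered, and — per subject protein — overlaps among accepted
#' projections are resolved with the greedy longest-first rule
#' ([greedy_overlap_resolve()], lengths measured on the subject). Transferred
#' regions keep the curated feature and source terms; their evidence term
#' becomes `"homology"`.
#'
#' @param alignments List of [pairwise_alignment()] objects.
#' @param annotations `data.frame` of curated regions with columns
#'   `accession`, `start`, `end`, `feature`, `source`.
#' @param t A [transfer_thresholds()].
#' @return A list with `regions` (named list: subject accession -> region
#'   table) and `audit` (one row per candidate with its statistics and
#'   verdict).
#' @export
transfer_annotations <- function(alignments, annotations,
                                 t = transfer_thresholds()) {
  need <- c("accession", "start", "end", "feature", "source")
  if (!all(need %in% names(annotations))) {
    stop("annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  query_ids <- vapply(alignments, `[[`, character(1), "qseqid")
  unknown <- setdiff(unique(annotations$accession), unique(query_ids))
  if (length(unknown) > 0L) {
    warning("skipping annotations for accession(s) with no alignment: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  audit <- list()
  for (aln in alignments) {
    regs <- annotations[annotations$accession == aln$qseqid, , drop = FALSE]
    for (k in seq_len(nrow(regs))) {
      cand <- project_region(aln, regs[k, ])
      cand <- apply_thresholds(cand, t)
      audit[[length(audit) + 1L]] <- .candidate_row(cand)
    }
  }
  audit <- if (length(audit) > 0L) do.call(rbind, audit) else .candidate_row(
    structure(list(qseqid = NA_character_, sseqid = NA_character_,
                   query_region = c(start = NA_integer_, end = NA_integer_),
                   feature = NA_character_, source = NA_character_,
                   projected = NULL, fragment_columns = NA_integer_,
                   coverage = NA_real_, gap_fraction = NA_real_,
                   identity = NA_real_, verdict = NA_character_,
                   reason = NA_character_), class = "transfer_candidate"))[0, ]
  acc <- audit[audit$verdict %in% "accepted", , drop = FALSE]
  regions <- lapply(split(acc, acc$sseqid), function(d) {
    cands <- region_table(d$subject_start, d$subject_end,
                          feature = d$feature, evidence = "homology",
                          source = d$source)
    greedy_overlap_resolve(cands)
  })
  list(regions = regions, audit = audit)
}
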