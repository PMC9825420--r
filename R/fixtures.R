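# Deterministic synthetic-data generators: toy structures with controllable
# per-residue confidence and alignment sets with known transfer outcomes,
# so every pipeline is testable without downloads.

#' Specification for a synthetic structure or alignment set
#'
#' @param seed Integer seed for all randomness (default 20220707).
#' @param segments For structures: `data.frame` with columns `kind`
#'   (`"helix"` or `"extended"`), `length` (residues) and `plddt`
#'   (confidence level written to the temperature-factor column).
#' @param alignments For alignment sets: `data.frame` with columns
#'   `identity`, `coverage` (percent, 0-100) and `gap_columns` — see
#'   [make_alignment_set()].
#' @param query_length,region_start,region_end Query geometry for alignment
#'   sets: a random query of `query_length` residues carries one curated
#'   region at `region_start..region_end`.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 20220707L, segments = NULL, alignments = NULL,
                         query_length = 120L, region_start = 41L,
                         region_end = 70L) {
  if (!is.null(segments)) {
    stopifnot(all(c("kind", "length", "plddt") %in% names(segments)))
    if (any(segments$length < 1L)) stop("zero-length segment", call. = FALSE)
    if (!all(segments$kind %in% c("helix", "extended"))) {
      stop("segment kind must be 'helix' or 'extended'", call. = FALSE)
    }
    if (any(segments$plddt < 0 | segments$plddt > 100)) {
      stop("segment pLDDT must lie in [0,100]", call. = FALSE)
    }
  }
  if (!is.null(alignments)) {
    stopifnot(all(c("identity", "coverage", "gap_columns") %in% names(alignments)))
    if (any(alignments$identity < 0 | alignments$identity > 100) ||
        any(alignments$coverage < 0 | alignments$coverage > 100)) {
      stop("identity and coverage must lie in [0,100]", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), segments = segments,
                 alignments = alignments,
                 query_length = as.integer(query_length),
                 region_start = as.integer(region_start),
                 region_end = as.integer(region_end)),
            class = "fixture_spec")
}

# backbone template offsets: N and C flank the alpha-carbon along the chain
# direction, the carbonyl oxygen sits off the C
.backbone_atoms <- function(ca, u, p) {
  list(
    N = ca - 1.2 * u + 0.6 * p,
    CA = ca,
    C = ca + 1.2 * u + 0.3 * p,
    O = ca + 1.4 * u + 1.4 * p
  )
}

#' Build a synthetic structure model from a segment specification
#'
#' Helical segments follow ideal alpha-helix alpha-carbon geometry (1.5
#' Angstrom rise, 100 degree turn per residue, 2.3 Angstrom radius);
#' extended segments are straight chains with 3.8 Angstrom alpha-carbon
#' spacing. Only backbone atoms (N, CA, C, O) are generated. Helical
#' residues are written as arginine and extended residues as glycine, so
#' that after max-ASA normalisation the two classes read as buried-like and
#' exposed (side chains are not modelled). The segment's pLDDT level fills
#' the temperature-factor column. Fully deterministic.
#'
#' @param spec A [fixture_spec()] with `segments`.
#' @return A [structure_model()].
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), !is.null(spec$segments))
  segs <- spec$segments
  kinds <- rep(segs$kind, segs$length)
  plddt <- rep(segs$plddt, segs$length)
  n <- length(kinds)
  ca <- matrix(0, n, 3)
  origin <- c(0, 0, 0)
  i <- 1L
  for (s in seq_len(nrow(segs))) {
    L <- segs$length[s]
    idx <- seq(i, i + L - 1L)
    if (segs$kind[s] == "helix") {
      t <- seq_len(L) - 1L
      local <- cbind(2.3 * cos(t * 100 * pi / 180),
                     2.3 * sin(t * 100 * pi / 180),
                     1.5 * t)
      local <- sweep(local, 2, local[1, ], "-")
      ca[idx, ] <- sweep(local, 2, origin, "+")
    } else {
      t <- seq_len(L) - 1L
      local <- cbind(3.8 * t, 0.4 * (t %% 2L), rep(0, L))
      ca[idx, ] <- sweep(local, 2, origin, "+")
    }
    # continue the next segment from beyond this one's last residue
    origin <- ca[idx[L], ] + c(4.5, 0, 0)
    i <- i + L
  }
  atoms <- vector("list", n)
  for (r in seq_len(n)) {
    u <- if (r < n) ca[r + 1L, ] - ca[r, ] else ca[r, ] - ca[r - 1L, ]
    u <- u / sqrt(sum(u^2))
    # a deterministic perpendicular
    p <- c(-u[2], u[1], 0)
    if (sqrt(sum(p^2)) < 1e-8) p <- c(1, 0, 0)
    p <- p / sqrt(sum(p^2))
    bb <- .backbone_atoms(ca[r, ], u, p)
    atoms[[r]] <- data.frame(
      resno = r,
      resid = if (kinds[r] == "helix") "ARG" else "GLY",
      elety = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(bb$N[1], bb$CA[1], bb$C[1], bb$O[1]),
      y = c(bb$N[2], bb$CA[2], bb$C[2], bb$O[2]),
      z = c(bb$N[3], bb$CA[3], bb$C[3], bb$O[3]),
      b = plddt[r],
      stringsAsFactors = FALSE
    )
  }
  structure_model(do.call(rbind, atoms), chain = "A")
}

#' Write a structure model as a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  name4 <- sprintf(" %-3s", at$elety)  # backbone names start in column 14
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, at$resid, model$chain, at$resno,
    at$x, at$y, at$z, 1.00, at$b, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure model as an mmCIF file (AlphaFold-style atom_site loop)
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @export
write_structure_mmcif <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  header <- c(
    "data_synthetic_fixture",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
    seq_len(nrow(at)), at$element, at$elety, at$resid, model$chain,
    at$resno, at$x, at$y, at$z, at$b, at$resno, at$resid, model$chain,
    at$elety)
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

# rotate a residue letter to a guaranteed different one within the alphabet
.mutate_letter <- function(x) {
  idx <- match(x, .aa20)
  .aa20[(idx %% length(.aa20)) + 1L]
}

#' Build a synthetic alignment set with known transfer outcomes
#'
#' A random query protein of `spec$query_length` residues carries one
#' curated region; for each row of `spec$alignments` a homolog alignment is
#' constructed by controlled mutation so that the region fragment attains
#' the requested coverage (by truncating the alignment into the region),
#' gap fraction (subject-gap columns placed at the region's end) and
#' identity (mismatches substituted at the region's start). The returned
#' manifest states, from the construction's integer counts alone, which
#' transfers must be accepted or rejected and why.
#'
#' @param spec A [fixture_spec()] with `alignments`.
#' @param t [transfer_thresholds()] used for the manifest verdicts.
#' @param dir Optional directory; when given, `alignments.tsv` (BLAST
#'   tabular), `regions.tsv` (curated regions) and `manifest.tsv` are
#'   written there.
#' @return List with `query` (sequence), `alignments` (list of
#'   [pairwise_alignment()]), `annotations` (curated-region data.frame),
#'   `manifest` (data.frame: sseqid, coverage, gap_fraction, identity,
#'   verdict, reason) and, if `dir` was given, `files`.
#' @export
make_alignment_set <- function(spec, t = transfer_thresholds(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), !is.null(spec$alignments))
  set.seed(spec$seed)
  qlen <- spec$query_length
  rs <- spec$region_start
  re <- spec$region_end
  L <- re - rs + 1L
  if (re > qlen || rs < 1L) stop("region outside query", call. = FALSE)
  query <- paste(sample(.aa20, qlen, replace = TRUE), collapse = "")
  qv <- strsplit(query, "")[[1]]
  qid <- "QRY1"
  alns <- list()
  manifest <- list()
  for (i in seq_len(nrow(spec$alignments))) {
    a <- spec$alignments[i, ]
    present <- as.integer(floor(a$coverage / 100 * L + 1e-9))
    if (present < 1L) stop("coverage leaves no region residue aligned", call. = FALSE)
    g <- as.integer(a$gap_columns)
    matches <- as.integer(floor(a$identity / 100 * present + 1e-9))
    if (matches + g > present) {
      stop(sprintf("alignment spec %d contradictory: %d matches + %d gaps > %d columns",
                   i, matches, g, present), call. = FALSE)
    }
    qstart <- rs + (L - present)   # truncate into the region to cut coverage
    qend <- qlen
    sub_q <- qv[qstart:qend]
    sv <- sub_q
    # region columns within this alignment, in alignment-local coordinates
    reg_cols <- seq(1L, present) + (rs + (L - present) - qstart)
    mm <- present - g - matches
    if (mm > 0L) {
      pos <- reg_cols[seq_len(mm)]
      sv[pos] <- .mutate_letter(sv[pos])
    }
    if (g > 0L) {
      pos <- reg_cols[seq(present - g + 1L, present)]
      sv[pos] <- "-"
    }
    sseq <- paste(sv, collapse = "")
    slen <- sum(sv != "-")
    sid <- sprintf("SBJ%03d", i)
    alns[[i]] <- pairwise_alignment(qid, sid, qstart, qend, 1L, slen,
                                    paste(sub_q, collapse = ""), sseq)
    cov_f <- present / L
    gap_f <- g / present
    id_f <- matches / present
    if (cov_f < t$min_query_coverage) {
      verdict <- "rejected"; reason <- "coverage"
    } else if (gap_f > t$max_gap_fraction) {
      verdict <- "rejected"; reason <- "gaps"
    } else if (id_f < t$min_identity) {
      verdict <- "rejected"; reason <- "identity"
    } else {
      verdict <- "accepted"; reason <- NA_character_
    }
    manifest[[i]] <- data.frame(sseqid = sid, coverage = cov_f,
                                gap_fraction = gap_f, identity = id_f,
                                verdict = verdict, reason = reason,
                                stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  annotations <- data.frame(accession = qid, start = rs, end = re,
                            feature = "disorder", source = "disprot",
                            stringsAsFactors = FALSE)
  out <- list(query = query, alignments = alns, annotations = annotations,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    aln_path <- file.path(dir, "alignments.tsv")
    writeLines(vapply(alns, function(a) {
      paste(a$qseqid, a$sseqid, a$qstart, a$qend, a$sstart, a$send,
            a$qseq, a$sseq, sep = "\t")
    }, character(1)), aln_path)
    reg_path <- file.path(dir, "regions.tsv")
    utils::write.table(annotations, reg_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    man_path <- file.path(dir, "manifest.tsv")
    utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fa_path <- file.path(dir, "query.fasta")
    writeLines(c(paste0(">", qid), query), fa_path)
    out$files <- c(alignments = aln_path, regions = reg_path,
                   manifest = man_path, query = fa_path)
  }
  out
}
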