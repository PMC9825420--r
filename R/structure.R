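#' Parameters for structure-derived disorder and LIP calling
#'
#' Bundles the thresholds of the structure pipeline: residues with predicted
#' confidence (pLDDT) strictly below `plddt_threshold` are called
#' disordered; residues whose relative solvent accessibility, averaged over
#' a centred sliding `window`, is strictly above `rsa_threshold` are called
#' disordered by exposure; residues that are confident AND exposed are
#' called linear interacting peptides (LIPs), the conditional-folding
#' signature.
#'
#' @param plddt_threshold pLDDT cut, percent in (0, 100); default 70.
#' @param rsa_threshold smoothed-RSA cut in (0, 1); default 0.58.
#' @param window sliding-window width in residues, odd; default 25.
#' @param probe_radius solvent probe radius in Angstrom; default 1.4.
#' @return A list of class `disorder_params`.
#' @export
disorder_params <- function(plddt_threshold = 70, rsa_threshold = 0.58,
                            window = 25L, probe_radius = 1.4) {
  if (!is.numeric(plddt_threshold) || plddt_threshold <= 0 || plddt_threshold >= 100) {
    stop("plddt_threshold must lie in (0, 100)", call. = FALSE)
  }
  if (!is.numeric(rsa_threshold) || rsa_threshold <= 0 || rsa_threshold >= 1) {
    stop("rsa_threshold must lie in (0, 1)", call. = FALSE)
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  structure(list(plddt_threshold = plddt_threshold,
                 rsa_threshold = rsa_threshold,
                 window = window,
                 probe_radius = probe_radius),
            class = "disorder_params")
}

#' Build a structure model from an atom table
#'
#' The model is the minimal view of a predicted structure this package
#' needs: ordered residues, their heavy-atom coordinates, and the
#' per-residue confidence stored in the temperature-factor column
#' (AlphaFoldDB convention: every atom of a residue carries the residue's
#' pLDDT).
#'
#' @param atoms `data.frame` with columns `resno` (residue index), `resid`
#'   (3-letter residue name), `elety` (atom name), `element` (element
#'   symbol), `x`, `y`, `z` (Angstrom) and `b` (temperature factor, read as
#'   pLDDT in 0-100).
#' @param chain Chain identifier (default "A").
#' @return An object of class `structure_model` with the atom table plus
#'   `resno`, `resid` and one-letter `sequence` at residue level.
#' @export
structure_model <- function(atoms, chain = "A") {
  need <- c("resno", "resid", "elety", "element", "x", "y", "z", "b")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("structure model has no atoms", call. = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  resno <- unique(atoms$resno)
  if (any(diff(resno) <= 0L)) {
    stop("residue indices must be strictly increasing", call. = FALSE)
  }
  if (any(atoms$b < 0 | atoms$b > 100)) {
    bad <- atoms$resno[which(atoms$b < 0 | atoms$b > 100)[1]]
    stop(sprintf("temperature factor outside [0,100] at residue %d", bad),
         call. = FALSE)
  }
  resid <- atoms$resid[match(resno, atoms$resno)]
  seq1 <- bio3d::aa321(resid)
  structure(list(atoms = atoms, chain = chain, resno = resno,
                 resid = resid, sequence = paste(seq1, collapse = "")),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: chain %s, %d residues (%d..%d), %d atoms\n",
              x$chain, length(x$resno), min(x$resno), max(x$resno),
              nrow(x$atoms)))
  invisible(x)
}

#' Read a structure model from a PDB or mmCIF file
#'
#' Accepts AlphaFold-style coordinate files in either format; the
#' temperature-factor column is interpreted as per-residue pLDDT. Only the
#' requested chain is kept; hydrogens and HETATM records are dropped.
#'
#' @param path Path to a `.pdb` or `.cif` file (format chosen by
#'   extension unless `format` is given).
#' @param chain Chain to extract; default: first chain in the file.
#' @param format `"pdb"`, `"cif"`, or `NULL` to infer from the extension.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain = NULL, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- withCallingHandlers(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    warning = function(w) {
      # bio3d flags its mmCIF reader as beta and warns on absent secondary
      # structure records; neither affects the atom table we consume
      if (grepl("beta version|helix/sheet", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain, call. = FALSE)
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- substr(gsub("^[0-9]+", "", at$elety), 1, 1)
  }
  element <- toupper(trimws(element))
  keep <- element != "H"
  atoms <- data.frame(resno = at$resno[keep], resid = at$resid[keep],
                      elety = at$elety[keep], element = element[keep],
                      x = at$x[keep], y = at$y[keep], z = at$z[keep],
                      b = at$b[keep], stringsAsFactors = FALSE)
  structure_model(atoms, chain = chain)
}

#' Per-residue pLDDT profile of a structure model
#'
#' AlphaFoldDB files carry the residue's pLDDT on every atom; if atoms of a
#' residue disagree, the alpha-carbon's value is used.
#'
#' @param model A [structure_model()].
#' @return Numeric vector of pLDDT values (0-100), one per residue, named by
#'   residue index.
#' @export
extract_plddt <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  vals <- vapply(model$resno, function(r) {
    b <- at$b[at$resno == r]
    if (length(unique(b)) == 1L) {
      b[1]
    } else {
      ca <- at$b[at$resno == r & at$elety == "CA"]
      if (length(ca) == 0L) b[1] else ca[1]
    }
  }, numeric(1))
  if (any(vals < 0 | vals > 100)) {
    bad <- model$resno[which(vals < 0 | vals > 100)[1]]
    stop(sprintf("pLDDT outside [0,100] at residue %d", bad), call. = FALSE)
  }
  names(vals) <- model$resno
  vals
}

#' Per-residue relative solvent accessibility of a structure model
#'
#' Computes heavy-atom SASA with [shrake_rupley_sasa()], sums it per residue
#' and divides by the residue type's theoretical maximum accessible area
#' (Tien et al. 2013), clamping to \[0, 1\]. Residue types absent from the
#' normalisation table get RSA 1.0 with a warning.
#'
#' @param model A [structure_model()].
#' @param params A [disorder_params()] (only `probe_radius` is used here).
#' @param n_points Shrake-Rupley test points per atom (default 960).
#' @return Numeric vector of RSA values in \[0, 1\], named by residue index.
#' @export
compute_rsa <- function(model, params = disorder_params(), n_points = 960L) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  heavy <- at$element %in% names(.vdw_radii)
  at <- at[heavy, , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms with known radii", call. = FALSE)
  sasa <- shrake_rupley_sasa(cbind(at$x, at$y, at$z), at$element,
                             probe_radius = params$probe_radius,
                             n_points = n_points)
  per_res <- vapply(model$resno, function(r) sum(sasa[at$resno == r]),
                    numeric(1))
  maxasa <- .max_asa[model$resid]
  if (anyNA(maxasa)) {
    unknown <- unique(model$resid[is.na(maxasa)])
    warning("unknown residue type(s) ", paste(unknown, collapse = ", "),
            "; assigning RSA 1.0", call. = FALSE)
    maxasa[is.na(maxasa)] <- per_res[is.na(maxasa)]  # ratio 1
    maxasa[maxasa == 0] <- 1
  }
  rsa <- pmin(pmax(per_res / maxasa, 0), 1)
  rsa[is.nan(rsa)] <- 1
  names(rsa) <- model$resno
  rsa
}

#' Sliding-window average of a per-residue profile
#'
#' Each position becomes the arithmetic mean over a centred window of
#' `window` residues; at the chain ends the window is truncated to the
#' available positions, so output length equals input length.
#'
#' @param profile Numeric vector.
#' @param window Odd positive integer window width.
#' @return Numeric vector of the same length (names preserved).
#' @export
smooth_profile <- function(profile, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  n <- length(profile)
  if (n == 0L) stop("empty profile", call. = FALSE)
  half <- window %/% 2L
  cs <- cumsum(c(0, profile))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  names(out) <- names(profile)
  out
}

#' Disorder mask from pLDDT
#'
#' A residue is disordered when its predicted confidence is strictly below
#' the threshold.
#'
#' @param plddt Numeric pLDDT profile (0-100).
#' @param params A [disorder_params()].
#' @return Logical mask, TRUE = disordered.
#' @export
disorder_by_plddt <- function(plddt, params = disorder_params()) {
  plddt < params$plddt_threshold
}

#' Disorder mask from window-averaged RSA
#'
#' A residue is disordered by exposure when its smoothed relative solvent
#' accessibility is strictly above the threshold.
#'
#' @param smoothed_rsa Numeric smoothed-RSA profile (0-1).
#' @param params A [disorder_params()].
#' @return Logical mask, TRUE = disordered.
#' @export
disorder_by_rsa <- function(smoothed_rsa, params = disorder_params()) {
  smoothed_rsa > params$rsa_threshold
}

#' LIP mask: confident yet exposed residues
#'
#' Linear interacting peptides are called where the model is confident
#' (pLDDT at or above the disorder threshold) AND the smoothed RSA exceeds
#' the exposure threshold — the intersection of the well-predicted and the
#' exposed residue sets, the signature of conditional folding.
#'
#' @param plddt Numeric pLDDT profile.
#' @param smoothed_rsa Numeric smoothed-RSA profile of equal length.
#' @param params A [disorder_params()].
#' @return Logical mask, TRUE = LIP.
#' @export
derive_lip <- function(plddt, smoothed_rsa, params = disorder_params()) {
  if (length(plddt) != length(smoothed_rsa)) {
    stop("pLDDT and RSA profiles differ in length", call. = FALSE)
  }
  mask_intersection(plddt >= params$plddt_threshold,
                    smoothed_rsa > params$rsa_threshold)
}

# Map a residue-level mask (over model$resno, which may contain index gaps)
# to regions in residue-index coordinates; gaps break runs.
.mask_to_resno_regions <- function(mask, resno, feature, evidence, source) {
  full <- logical(max(resno))
  full[resno[mask]] <- TRUE
  out <- regions_from_mask(full, feature = feature, evidence = evidence,
                           source = source)
  out
}

#' Full structure-derived annotation pipeline
#'
#' Runs pLDDT extraction, solvent accessibility, window smoothing, the
#' three masks and region extraction, returning regions labelled with their
#' controlled-vocabulary triplets:
#' \itemize{
#'   \item prediction / disorder / alphafold-plddt
#'   \item prediction / disorder / alphafold-rsa
#'   \item prediction / lip / alphafold
#' }
#' Residues missing from the model (index gaps) receive no annotation and
#' break region runs.
#'
#' @param model A [structure_model()].
#' @param params A [disorder_params()].
#' @param n_points Shrake-Rupley test points per atom.
#' @return A list with `regions` (region table over all three tracks),
#'   `profiles` (data.frame: resno, aa, plddt, rsa, smoothed_rsa,
#'   disorder_plddt, disorder_rsa, lip).
#' @export
annotate_structure <- function(model, params = disorder_params(),
                               n_points = 960L) {
  plddt <- extract_plddt(model)
  rsa <- compute_rsa(model, params, n_points = n_points)
  srsa <- smooth_profile(rsa, params$window)
  m_plddt <- disorder_by_plddt(plddt, params)
  m_rsa <- disorder_by_rsa(srsa, params)
  m_lip <- derive_lip(plddt, srsa, params)
  resno <- model$resno
  regions <- rbind(
    .mask_to_resno_regions(m_plddt, resno, "disorder", "prediction", "alphafold-plddt"),
    .mask_to_resno_regions(m_rsa, resno, "disorder", "prediction", "alphafold-rsa"),
    .mask_to_resno_regions(m_lip, resno, "lip", "prediction", "alphafold")
  )
  class(regions) <- c("region_table", "data.frame")
  profiles <- data.frame(
    resno = resno,
    aa = strsplit(model$sequence, "")[[1]],
    plddt = unname(plddt),
    rsa = unname(rsa),
    smoothed_rsa = unname(srsa),
    disorder_plddt = unname(m_plddt),
    disorder_rsa = unname(m_rsa),
    lip = unname(m_lip),
    stringsAsFactors = FALSE
  )
  list(regions = regions, profiles = profiles)
}
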