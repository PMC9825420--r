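# Solvent accessibility engine: Shrake-Rupley sphere sampling over heavy
# atoms, normalised per residue by the theoretical maximum accessible
# surface areas of Tien et al. (2013).

# van der Waals radii (Angstrom) for the heavy elements of standard residues
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Tien et al. 2013 "theoretical" maximum ASA (Angstrom^2), by 3-letter code
.max_asa <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

#' Theoretical maximum accessible surface area per residue type
#'
#' @return Named numeric vector (3-letter residue codes, Angstrom^2).
#' @export
max_asa_table <- function() .max_asa

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral), the test-point set of the Shrake-Rupley algorithm.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' For every atom, `n_points` quasi-uniform test points are placed on a
#' sphere of radius vdW + probe; the accessible fraction is the fraction of
#' points not buried inside any neighbouring atom's expanded sphere.
#'
#' @param xyz Numeric matrix, one row per atom (x, y, z in Angstrom).
#' @param elements Character vector of element symbols (C, N, O, S).
#'   Hydrogens must be removed by the caller.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @return Numeric vector of per-atom SASA in Angstrom^2.
#' @export
shrake_rupley_sasa <- function(xyz, elements, probe_radius = 1.4,
                               n_points = 960L) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have three columns", call. = FALSE)
  n <- nrow(xyz)
  if (n == 0L) stop("no atoms", call. = FALSE)
  if (length(elements) != n) stop("one element per atom required", call. = FALSE)
  radii <- .vdw_radii[toupper(elements)]
  if (anyNA(radii)) {
    bad <- unique(elements[is.na(radii)])
    stop(sprintf("unknown element(s) for SASA: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  ext <- radii + probe_radius
  pts <- sphere_points(n_points)
  out <- numeric(n)
  cutoff <- max(ext) + ext  # neighbour search radius per atom
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ext[i] + ext)^2 & seq_len(n) != i)
    test <- pts * ext[i]
    test <- sweep(test, 2, xyz[i, ], "+")
    if (length(nb) == 0L) {
      frac <- 1
    } else {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
          (test[, 3] - xyz[j, 3])^2
        free <- free & dj2 > ext[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    }
    out[i] <- frac * 4 * pi * ext[i]^2
  }
  out
}
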