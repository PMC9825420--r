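# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# Brute-force restatement of the greedy overlap rule: repeatedly pick the
# best remaining candidate by explicit pairwise comparison, keep it if
# compatible with everything kept so far.
oracle_greedy <- function(df) {
  df <- as.data.frame(df)
  better <- function(i, j) {
    li <- df$end[i] - df$start[i]
    lj <- df$end[j] - df$start[j]
    si <- ifelse(is.na(df$source[i]), "", df$source[i])
    sj <- ifelse(is.na(df$source[j]), "", df$source[j])
    if (li != lj) return(li > lj)
    if (df$start[i] != df$start[j]) return(df$start[i] < df$start[j])
    si <= sj
  }
  remaining <- seq_len(nrow(df))
  kept <- integer(0)
  while (length(remaining) > 0L) {
    best <- remaining[1]
    for (i in remaining) if (i != best && better(i, best)) best <- i
    ok <- TRUE
    for (k in kept) {
      if (!(df$end[best] < df$start[k] || df$start[best] > df$end[k])) ok <- FALSE
    }
    if (ok) kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
  }
  kept <- kept[order(df$start[kept])]
  out <- df[kept, c("start", "end"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Dense latitude/longitude surface quadrature for solvent-accessible area:
# numerical integration over each atom's expanded sphere, counting the
# quadrature weight of surface patches outside every other expanded sphere.
oracle_sasa <- function(xyz, elements, probe = 1.4, n_theta = 60L, n_phi = 120L) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[toupper(elements)] + probe
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta          # polar
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi            # azimuth
  grid <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  w <- sin(grid$theta) * (pi / n_theta) * (2 * pi / n_phi)  # dA = r^2 sin(t) dt dp
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * radii[i], 2, as.numeric(xyz[i, ]), "+")
    exposed <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > radii[j]^2
    }
    out[i] <- sum(w[exposed]) * radii[i]^2
  }
  out
}

# per-residue RSA through the quadrature oracle, Tien-normalised
oracle_rsa <- function(model, probe = 1.4) {
  at <- model$atoms[model$atoms$element %in% c("C", "N", "O", "S"), ]
  sasa <- oracle_sasa(cbind(at$x, at$y, at$z), at$element, probe = probe)
  per_res <- vapply(model$resno, function(r) sum(sasa[at$resno == r]), numeric(1))
  pmin(per_res / max_asa_table()[model$resid], 1)
}

# direct logo arithmetic on a character column
oracle_column_height <- function(letters) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  letters <- letters[letters %in% aa]
  if (length(letters) == 0L) return(0)
  f <- table(factor(letters, levels = aa)) / length(letters)
  f <- as.numeric(f)
  H <- -sum(ifelse(f > 0, f * log2(f), 0))
  max(f) * (log2(20) - H)
}
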