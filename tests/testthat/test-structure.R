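make_flat_model <- function(b_values, resid = "GLY") {
  n <- length(b_values)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(resno = i, resid = resid,
               elety = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = 3.8 * (i - 1) + c(-1.2, 0, 1.2, 1.6),
               y = c(0.6, 0, 0.3, 1.5), z = 0, b = b_values[i])
  }))
  structure_model(atoms)
}

test_that("pLDDT extraction reads the temperature-factor column per residue", {
  expect_equal(unname(extract_plddt(make_flat_model(rep(95, 4)))), rep(95, 4))
  expect_equal(unname(extract_plddt(make_flat_model(c(80, 60, 40)))),
               c(80, 60, 40))
  expect_error(structure_model(data.frame()), "lacks column")
  expect_error(make_flat_model(c(50, 120)), "outside \\[0,100\\]")
})

test_that("disagreeing atom factors fall back to the alpha-carbon value", {
  m <- make_flat_model(c(80, 80))
  m$atoms$b[m$atoms$elety != "CA" & m$atoms$resno == 1] <- 55
  expect_equal(unname(extract_plddt(m)), c(80, 80))
})

test_that("window smoothing truncates at the ends and preserves bounds", {
  expect_equal(smooth_profile(rep(0.4, 10), 25), rep(0.4, 10))
  x <- c(0.2, 0.9, 0.1, 0.5)
  expect_equal(smooth_profile(x, 1), x)
  expect_equal(smooth_profile(c(1, 0, 0, 0, 0), 3), c(0.5, 1 / 3, 0, 0, 0))
  expect_error(smooth_profile(x, 4), "odd")
  expect_error(smooth_profile(x, -3), "odd")

  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(5:60, 1))
    w <- sample(c(1, 3, 5, 25), 1)
    s <- smooth_profile(p, w)
    expect_true(all(s >= min(p) - 1e-12 & s <= max(p) + 1e-12))
    mono <- sort(p)
    expect_false(is.unsorted(smooth_profile(mono, w)))
  }
})

test_that("disorder thresholds are strict on the stated side", {
  p <- disorder_params()
  expect_equal(disorder_by_plddt(c(90, 69.9), p), c(FALSE, TRUE))
  expect_false(disorder_by_plddt(70, p))
  expect_false(any(disorder_by_plddt(rep(100, 5), p)))
  expect_equal(disorder_by_rsa(c(0.60, 0.58), p), c(TRUE, FALSE))
  expect_false(any(disorder_by_rsa(rep(0, 5), p)))
  expect_true(all(disorder_by_rsa(rep(1, 5), p)))
})

test_that("LIP calls require confidence AND exposure", {
  p <- disorder_params()
  expect_true(derive_lip(85, 0.7, p))
  expect_false(derive_lip(60, 0.7, p))   # disordered by pLDDT instead
  expect_false(derive_lip(85, 0.3, p))   # buried
  expect_error(derive_lip(c(85, 85), 0.7, p), "length")

  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    plddt <- runif(n, 0, 100)
    srsa <- runif(n)
    lip <- derive_lip(plddt, srsa, p)
    dis <- disorder_by_plddt(plddt, p)
    expect_false(any(lip & dis))
  }
})

test_that("the full structure pipeline annotates a helix-plus-tail chain", {
  ann <- annotate_structure(make_structure(helix_tail_spec()))
  plddt_reg <- ann$regions[ann$regions$source == "alphafold-plddt", ]
  expect_equal(plddt_reg$start, 31L)
  expect_equal(plddt_reg$end, 60L)
  rsa_reg <- ann$regions[ann$regions$source == "alphafold-rsa", ]
  expect_equal(nrow(rsa_reg), 1L)
  expect_gte(rsa_reg$start, 31L)  # smoothing blurs the boundary inward only
  expect_equal(rsa_reg$end, 60L)
  expect_equal(nrow(ann$regions[ann$regions$feature == "lip", ]), 0L)
})

test_that("a confident exposed segment flanked by disorder is called LIP", {
  ann <- annotate_structure(make_structure(lip_segment_spec()))
  lip <- ann$regions[ann$regions$feature == "lip", ]
  expect_equal(lip$start, 14L)
  expect_equal(lip$end, 33L)
  expect_equal(lip$evidence, "prediction")
  expect_equal(lip$source, "alphafold")
})

test_that("structure annotation is deterministic across repeated file reads", {
  dir <- withr::local_tempdir()
  model <- make_structure(helix_tail_spec())
  path <- file.path(dir, "m.pdb")
  write_structure_pdb(model, path)
  a1 <- annotate_structure(read_structure(path))
  a2 <- annotate_structure(read_structure(path))
  expect_identical(a1, a2)
})

test_that("residue-index gaps break region runs and stay unannotated", {
  m <- make_flat_model(rep(40, 8))
  keep <- m$atoms$resno != 4L
  gapped <- structure_model(m$atoms[keep, ])
  ann <- annotate_structure(gapped)
  plddt_reg <- ann$regions[ann$regions$source == "alphafold-plddt", ]
  expect_equal(plddt_reg$start, c(1L, 5L))
  expect_equal(plddt_reg$end, c(3L, 8L))
})
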