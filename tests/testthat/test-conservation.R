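test_that("stacking hits onto the query keeps exactly one column per residue", {
  q <- "ACDEFGHIKL"
  msa0 <- stack_alignments(q)
  expect_equal(nrow(msa0$rows), 1L)
  expect_equal(ncol(msa0$rows), 10L)

  msa1 <- stack_alignments(q, list(identity_alignment(q)))
  expect_identical(msa1$rows[1, ], msa1$rows[2, ])

  # two-residue subject insertion after query position 3 is discarded
  hit <- pairwise_alignment("Q1", "S1", 1L, 10L, 1L, 12L,
                            "ACD--EFGHIKL", "ACDWWEFGHIKL")
  msa2 <- stack_alignments(q, list(hit))
  expect_equal(ncol(msa2$rows), 10L)
  expect_identical(paste(msa2$rows[2, ], collapse = ""), q)

  # partial hit: uncovered positions are gap-filled
  part <- pairwise_alignment("Q1", "S1", 4L, 8L, 1L, 5L, "EFGHI", "EFGHI")
  msa3 <- stack_alignments(q, list(part))
  expect_identical(paste(msa3$rows[2, ], collapse = ""), "---EFGHI--")

  bad <- pairwise_alignment("Q1", "S1", 4L, 12L, 1L, 9L,
                            "EFGHIKLMN", "EFGHIKLMN")
  expect_error(stack_alignments(q, list(bad)), "outside")
})

test_that("column statistics reproduce logo arithmetic in closed form", {
  q <- "AAAA"
  msa <- stack_alignments(q, list(identity_alignment(q), identity_alignment(q)))
  st <- column_stats(msa, 1)
  expect_equal(st$consensus, "A")
  expect_equal(st$height, log2(20), tolerance = 1e-12)
  expect_equal(st$occupancy, 1.0)

  # half A half C: H = 1 bit, height = 0.5 * (log2 20 - 1), tie -> 'A'
  half <- stack_alignments("A", list(pairwise_alignment("q", "s", 1L, 1L,
                                                        1L, 1L, "A", "C")))
  st2 <- column_stats(half, 1)
  expect_equal(st2$consensus, "A")
  expect_equal(st2$height, 0.5 * (log2(20) - 1), tolerance = 1e-12)

  # 3 of 4 rows gapped, remaining W
  hits <- list(
    pairwise_alignment("q", "s1", 2L, 2L, 1L, 1L, "C", "C"),
    pairwise_alignment("q", "s2", 2L, 2L, 1L, 1L, "C", "C"),
    pairwise_alignment("q", "s3", 1L, 2L, 1L, 2L, "WC", "WC"))
  msa4 <- stack_alignments("WC", hits)
  st3 <- column_stats(msa4, 1)
  expect_equal(st3$occupancy, 0.5)  # query + s3 hold W; s1, s2 are gapped
  expect_equal(st3$consensus, "W")
  expect_equal(st3$height, log2(20), tolerance = 1e-12)

  expect_error(column_stats(msa4, 5), "out of range")
})

test_that("non-standard residues are excluded like gaps", {
  msa <- stack_alignments("A", list(
    pairwise_alignment("q", "s1", 1L, 1L, 1L, 1L, "A", "X"),
    pairwise_alignment("q", "s2", 1L, 1L, 1L, 1L, "A", "B")))
  st <- column_stats(msa, 1)
  expect_equal(st$occupancy, 1 / 3)
  expect_equal(st$consensus, "A")
  expect_equal(st$height, log2(20), tolerance = 1e-12)
})

test_that("the conservation track spans every query position with bounded stats", {
  set.seed(17)
  q <- random_aa_seq(40)
  hits <- lapply(1:5, function(i) {
    s <- strsplit(q, "")[[1]]
    flip <- sample(40, 8)
    s[flip] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 8, replace = TRUE)
    pairwise_alignment("q", paste0("s", i), 1L, 40L, 1L, 40L, q,
                       paste(s, collapse = ""))
  })
  msa <- stack_alignments(q, hits)
  track <- conservation_track(msa)
  expect_equal(nrow(track), 40L)
  expect_true(all(track$height_bits >= 0 & track$height_bits <= log2(20) + 1e-12))
  expect_true(all(track$occupancy >= 0 & track$occupancy <= 1))
  for (j in c(1, 7, 23, 40)) {
    expect_equal(track$height_bits[j],
                 oracle_column_height(msa$rows[, j]), tolerance = 1e-12)
  }
  # permuting rows leaves the statistics unchanged
  perm <- msa
  perm$rows <- perm$rows[c(3, 1, 6, 2, 5, 4), , drop = FALSE]
  expect_equal(conservation_track(perm)[, -2], track[, -2])
})

test_that("terminal gap-rich columns lower occupancy at the ends", {
  q <- random_aa_seq(30)
  hits <- lapply(1:4, function(i) {
    pairwise_alignment("q", paste0("s", i), 6L, 25L, 1L, 20L,
                       substr(q, 6, 25), substr(q, 6, 25))
  })
  track <- conservation_track(stack_alignments(q, hits))
  expect_lt(track$occupancy[1], track$occupancy[15])
  expect_lt(track$occupancy[30], track$occupancy[15])
})

test_that("duplicating the query row cannot lower a query-consensus column", {
  q <- "ACDEFGHIKL"
  hit <- pairwise_alignment("q", "s", 1L, 10L, 1L, 10L, q, q)
  base <- conservation_track(stack_alignments(q, list(hit)))
  more <- conservation_track(stack_alignments(q, list(hit, hit)))
  expect_true(all(more$height_bits >= base$height_bits - 1e-12))
})
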