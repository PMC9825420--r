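test_that("BLAST tabular records parse with coordinate validation", {
  aln <- parse_blast_record("Q1\tS1\t1\t4\t1\t4\tACDE\tACDE")
  expect_s3_class(aln, "pairwise_alignment")
  expect_equal(nchar(aln$qseq), 4L)

  # ungapped length disagreeing with the coordinates
  expect_error(parse_blast_record("Q1\tS1\t1\t5\t1\t4\tACDE\tACDE", 3),
               "line 3")
  expect_error(parse_blast_record("Q1\tS1\t1\t4"), "8 tab-separated")

  gapped <- parse_blast_record("Q1\tS1\t1\t5\t1\t4\tACDEF\tAC-EF")
  expect_equal(gapped$send, 4L)
  expect_error(pairwise_alignment("Q", "S", 1, 2, 1, 2, "A-", "A-"),
               "both rows")
})

test_that("region projection through an identity alignment is the identity", {
  q <- random_aa_seq(100)
  aln <- identity_alignment(q)
  cand <- project_region(aln, list(start = 10, end = 20))
  expect_equal(unname(cand$projected), c(10, 20))
  expect_equal(cand$coverage, 1.0)
  expect_equal(cand$gap_fraction, 0.0)
  expect_equal(cand$identity, 1.0)
})

test_that("partial overlap with the alignment span cuts coverage", {
  q <- random_aa_seq(100)
  aln <- pairwise_alignment("Q1", "S1", 5L, 100L, 1L, 96L,
                            substr(q, 5, 100), substr(q, 5, 100))
  cand <- project_region(aln, list(start = 1, end = 10))
  expect_equal(cand$coverage, 0.6)
  verdict <- apply_thresholds(cand)
  expect_equal(verdict$verdict, "rejected")
  expect_equal(verdict$reason, "coverage")
})

test_that("fragment statistics count gap columns and identities by column", {
  # region 1..10; two insertion columns inside, one mismatch at position 6
  qseq <- "ACDEF--GHIKL"
  sseq <- "ACDEFPQAHIKL"
  aln <- pairwise_alignment("Q1", "S1", 1L, 10L, 1L, 12L, qseq, sseq)
  cand <- project_region(aln, list(start = 1, end = 10))
  expect_equal(cand$fragment_columns, 12L)
  expect_equal(cand$coverage, 1.0)
  expect_equal(cand$gap_fraction, 2 / 12)
  expect_equal(cand$identity, 9 / 12)
})

test_that("regions outside the alignment span are rejected with a reason", {
  aln <- pairwise_alignment("Q1", "S1", 10L, 20L, 1L, 11L,
                            "ACDEFGHIKLM", "ACDEFGHIKLM")
  cand <- project_region(aln, list(start = 30, end = 40))
  expect_equal(cand$verdict, "rejected")
  expect_equal(cand$reason, "no-overlap")

  all_gap <- pairwise_alignment("Q1", "S1", 1L, 6L, 1L, 3L,
                                "ACDEFG", "---KLM")
  cand2 <- project_region(all_gap, list(start = 1, end = 3))
  expect_equal(cand2$reason, "subject-all-gaps")
})

test_that("the acceptance filters pass exactly the boundary-attaining candidate", {
  combos <- expand.grid(coverage = c(0.89, 0.90), gaps = c(0.20, 0.21),
                        identity = c(0.79, 0.80))
  for (i in seq_len(nrow(combos))) {
    cand <- structure(list(
      qseqid = "Q", sseqid = "S", query_region = c(start = 1L, end = 10L),
      feature = "disorder", source = "disprot",
      projected = c(start = 1L, end = 10L), fragment_columns = 10L,
      coverage = combos$coverage[i], gap_fraction = combos$gaps[i],
      identity = combos$identity[i], verdict = "pending",
      reason = NA_character_), class = "transfer_candidate")
    out <- apply_thresholds(cand)
    should_pass <- combos$coverage[i] >= 0.90 && combos$gaps[i] <= 0.20 &&
      combos$identity[i] >= 0.80
    expect_equal(out$verdict, if (should_pass) "accepted" else "rejected")
  }
})

test_that("transfer keeps curated terms, sets homology evidence, resolves overlaps", {
  q <- random_aa_seq(80)
  ann <- data.frame(accession = "Q1", start = c(1L, 40L), end = c(50L, 60L),
                    feature = "lip", source = c("dibs", "mfib"),
                    stringsAsFactors = FALSE)
  res <- transfer_annotations(list(identity_alignment(q)), ann)
  regs <- res$regions[["S1"]]
  expect_equal(nrow(regs), 1L)  # greedy drops the shorter overlapping region
  expect_equal(regs$start, 1L)
  expect_equal(regs$end, 50L)
  expect_equal(regs$evidence, "homology")
  expect_equal(regs$feature, "lip")
  expect_equal(regs$source, "dibs")
})

test_that("annotations without a matching alignment are skipped with a warning", {
  q <- random_aa_seq(30)
  ann <- data.frame(accession = c("Q1", "NOPE"), start = 1L, end = 10L,
                    feature = "disorder", source = "disprot",
                    stringsAsFactors = FALSE)
  expect_warning(res <- transfer_annotations(list(identity_alignment(q)), ann),
                 "NOPE")
  expect_equal(nrow(res$audit), 1L)
})

test_that("raising any threshold never accepts more candidates", {
  set.seed(99)
  for (rep in 1:30) {
    spec <- fixture_spec(seed = sample.int(1e6, 1), alignments = data.frame(
      identity = sample(60:85, 4, replace = TRUE),
      coverage = sample(80:100, 4, replace = TRUE),
      gap_columns = sample(0:3, 4, replace = TRUE)))
    as <- make_alignment_set(spec)
    base <- transfer_annotations(as$alignments, as$annotations)
    n_base <- sum(base$audit$verdict == "accepted")
    stricter <- list(
      transfer_thresholds(min_query_coverage = 0.95),
      transfer_thresholds(max_gap_fraction = 0.10),
      transfer_thresholds(min_identity = 0.90))
    for (t in stricter) {
      n <- sum(transfer_annotations(as$alignments, as$annotations,
                                    t)$audit$verdict == "accepted")
      expect_lte(n, n_base)
    }
  }
})

test_that("candidate statistics always lie in [0, 1]", {
  set.seed(123)
  for (rep in 1:20) {
    as <- make_alignment_set(fixture_spec(
      seed = sample.int(1e6, 1),
      alignments = data.frame(identity = sample(0:90, 3, replace = TRUE),
                              coverage = sample(70:100, 3, replace = TRUE),
                              gap_columns = sample(0:2, 3, replace = TRUE))))
    res <- transfer_annotations(as$alignments, as$annotations)
    expect_true(all(res$audit$coverage >= 0 & res$audit$coverage <= 1))
    expect_true(all(res$audit$gap_fraction >= 0 & res$audit$gap_fraction <= 1))
    expect_true(all(res$audit$identity >= 0 & res$audit$identity <= 1))
    for (regs in res$regions) {
      if (nrow(regs) > 1L) {
        expect_true(all(regs$start[-1] > regs$end[-nrow(regs)]))
      }
    }
  }
})
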