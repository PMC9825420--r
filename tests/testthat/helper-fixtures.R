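# Shared in-code fixture builders.

random_region_set <- function(n, max_pos = 60L, sources = c("disprot", "elm")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(15L, n, replace = TRUE)
  region_table(start, start + len - 1L,
               feature = "disorder", evidence = "curated",
               source = sample(sources, n, replace = TRUE))
}

helix_tail_spec <- function(plddt_helix = 90, plddt_tail = 40) {
  fixture_spec(segments = data.frame(kind = c("helix", "extended"),
                                     length = c(30L, 30L),
                                     plddt = c(plddt_helix, plddt_tail)))
}

lip_segment_spec <- function() {
  fixture_spec(segments = data.frame(kind = "extended",
                                     length = c(13L, 20L, 13L),
                                     plddt = c(40, 90, 40)))
}

# an ungapped identity alignment over a given query
identity_alignment <- function(query, qid = "Q1", sid = "S1") {
  pairwise_alignment(qid, sid, 1L, nchar(query), 1L, nchar(query),
                     query, query)
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
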