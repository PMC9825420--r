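Package: idrtracks
Title: Structure-Derived Disorder, Homology Transfer and Conservation Tracks for Intrinsically Disordered Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes controlled-vocabulary-keyed annotation tracks for
    intrinsically disordered proteins from three complementary sources.
    From AlphaFold-style predicted structures it derives two disorder
    definitions (low per-residue confidence, pLDDT < 70; window-averaged
    relative solvent accessibility > 0.58) and calls linear interacting
    peptides (LIPs) as confident yet exposed segments, using a built-in
    Shrake-Rupley solvent accessibility engine with theoretical max-ASA
    normalisation. It projects curated region annotations onto homologous
    proteins through pairwise alignments in BLAST tabular format, applying
    stringent coverage, gap and identity filters and a greedy longest-first
    overlap resolution. It builds query-anchored multiple alignments from
    pairwise hits and computes sequence-logo consensus heights and column
    occupancies. A deterministic fixture generator produces synthetic
    structures and alignment sets with known outcomes, and a command-line
    interface exposes all pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
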