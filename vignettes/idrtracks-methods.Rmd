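---
title: "Methods: structure-derived disorder, homology transfer and conservation tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-derived disorder, homology transfer and conservation tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrtracks)
```

# What this package computes

Intrinsically disordered regions (IDRs) lack a fixed three-dimensional
structure. `idrtracks` produces three families of per-protein annotation
tracks about them, each keyed by a controlled-vocabulary triplet
(evidence / feature / source):

1. **Structure-derived disorder and LIPs.** From an AlphaFold-style
   predicted structure it derives two complementary disorder definitions
   and one binding-region definition. A residue is *disordered by
   confidence* when its pLDDT (the predictor's per-residue confidence,
   0–100, stored in the coordinate file's temperature-factor column) is
   strictly below 70. A residue is *disordered by exposure* when its
   relative solvent accessibility (RSA), averaged over a centred sliding
   window of 25 residues, is strictly above 0.58. Residues that are
   confident (pLDDT ≥ 70) *and* exposed (smoothed RSA > 0.58) are called
   **linear interacting peptides (LIPs)**: segments predicted with high
   confidence in an extended, solvent-exposed conformation, the signature
   of conditional folding upon partner binding.
2. **Homology transfer.** Curated region annotations are projected onto
   homologous proteins through full-sequence pairwise alignments (BLAST
   tabular input). A projection is accepted only under stringent filters:
   the alignment fragment must cover ≥ 90% of the annotated query region,
   gap columns must make up ≤ 20% of the fragment, and ≥ 80% of the
   fragment columns must be identical residue pairs. Overlaps among
   accepted projections on one target protein are resolved by a greedy
   rule that prioritises longer regions.
3. **Sequence conservation.** Pairwise hits are stacked into a
   query-anchored multiple alignment by dropping the columns that are
   gaps in the query (subject insertions). Conservation is the height of
   the consensus character in the sequence-logo sense — the consensus
   letter's frequency times the column information content
   R = log2(20) − H bits — reported together with column occupancy, the
   fraction of non-gap rows.

# Model details and numerical choices

## Solvent accessibility

RSA requires an accessibility engine. The package implements the
Shrake–Rupley algorithm directly: each heavy atom's sphere (van der Waals
radius + 1.4 Å water probe) is sampled with 960 deterministic test points
from a golden-section spiral, and the accessible fraction is the share of
points outside every neighbouring atom's expanded sphere. Per-residue
areas are the sum over the residue's atoms, normalised by the residue
type's *theoretical* maximum accessible area (Tien et al. 2013) and
clamped to [0, 1]. Hydrogens are ignored; heavy-atom radii are C 1.70,
N 1.55, O 1.52, S 1.80 Å. Any max-ASA-normalised accessibility engine
satisfies the pipeline's contract; the built-in one keeps the package
self-contained with no external binary. The test suite and the acceptance
script compare it against an independent dense latitude/longitude
quadrature of the same surfaces and require agreement within 0.05 RSA;
observed deviation on the shipped fixtures is ~0.012.

Residue types outside the 20-residue normalisation table receive RSA 1.0
with a warning — an unknown residue cannot be claimed buried.

## Window smoothing and thresholds

The 25-residue smoothing window applies to the RSA profile only; pLDDT is
thresholded raw. At chain ends the window is truncated to the available
positions (a mean over fewer residues), so output length always equals
input length. Both thresholds follow strict inequalities (< 70, > 0.58);
the LIP confidence condition uses the complement (≥ 70), so no residue is
ever simultaneously a LIP and disordered-by-confidence. Residues missing
from a model (index gaps) receive no annotation and break region runs.

## Greedy overlap resolution

Candidates are visited longest first; a candidate is kept iff it overlaps
nothing already kept. Lengths are measured on the target (subject)
protein, where the conflict exists. Ties on length are broken by smaller
start, then lexicographic source term — a determinism choice, since the
rule itself does not dictate an order among equals. The suite checks the
implementation against an independently written brute-force restatement
over exhaustive sweeps of up to 15 regions.

## Transfer statistics: denominators

For a region fragment, *coverage* divides by the annotated region length;
*gap fraction* and *identity* divide by the fragment column count, so gap
columns count against identity. Query-gap columns (subject insertions)
whose insertion point falls strictly inside the region are part of the
fragment and inflate its gap fraction. All three boundaries are inclusive
on the passing side (≥ 0.90, ≤ 0.20, ≥ 0.80). No E-value or full-sequence
pre-filter is applied: exactly the three stated rules decide. Rejections
record the first failing criterion, checked in the order coverage, gaps,
identity.

## Conservation

Frequencies are computed over the 20 standard amino acids among the
non-gap rows of a column; occupancy is reported separately. Non-standard
letters (B, Z, X, U, O) carry no defined frequency class in a 20-letter
alphabet and are treated as gaps throughout — including for occupancy,
which keeps the invariant that zero occupancy implies zero height. No
small-sample correction is applied by default (the intended inputs are
large hit sets); `small_sample_correction = TRUE` subtracts the standard
19/(2·ln 2·n) term. Consensus ties break alphabetically. No sequence
weighting is applied.

# The synthetic-data generator

Every pipeline is testable offline through `make_structure()` and
`make_alignment_set()` (seed default 20220707).

**Structures.** Segments are either *helix* (ideal alpha-carbon helix
geometry: 1.5 Å rise, 100° turn, 2.3 Å radius) or *extended* (straight
chain, 3.8 Å alpha-carbon spacing), carrying a chosen pLDDT level in the
temperature-factor column. Only backbone atoms (N, CA, C, O) are built.
Because side chains are not modelled, exposure classes are realised
through the normaliser instead: helical residues are written as arginine
(large max-ASA, so a backbone-only surface reads as buried, RSA ≈ 0.2)
and extended residues as glycine (the backbone essentially *is* the
residue, RSA ≈ 1). This is a deliberate emulation device: the fixtures
exercise the thresholding, smoothing, intersection and region logic
exactly, but they are not physically realistic proteins, and passing on
them does not by itself demonstrate accuracy on real predicted
structures.

**Alignment sets.** A random query carries one curated region; each
homolog is constructed by controlled mutation so the region fragment
attains a requested coverage (alignment truncated into the region), gap
fraction (subject-gap columns at the region's end) and identity
(mismatches at its start). Requested percentages are attained from below
(`floor` of the implied counts), so a request below a threshold stays
below it after integer rounding. The expected accept/reject verdict in
the returned manifest is computed from the construction's integer counts
alone — independent of the projection code path it later checks.
Contradictory requests (identity plus gap shares exceeding the available
columns) raise an error rather than silently drifting.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: structures of 20–124 residues (80–496 heavy atoms), exhaustive
greedy sweeps over 300 region sets of up to 15 regions, 200 seeded
alignment sets of 3 homologs each, and quadrature cross-checks on
30-residue chains. These sizes keep the full suite under a minute while
exercising every code path; all statistics scale linearly or
quadratically (SASA neighbour checks) with residue count.

# Known limitations

- The structure pipeline is validated against synthetic backbone-only
  fixtures and an internal quadrature oracle, not against a database of
  real predicted structures; real AlphaFold models carry side chains,
  whose burial the fixtures only emulate through the normaliser.
- Homology transfer consumes alignments; it does not run BLAST, so any
  low-complexity masking is the alignment producer's concern.
- The controlled vocabulary ships as a minimal working subset (4 evidence
  terms mirroring the curated/derived/homology/prediction hierarchy, 5
  feature terms, and the source terms this package emits or ingests), not
  a replication of any database's full term set.
- Conservation assumes unweighted rows; strongly redundant hit sets will
  overstate consensus heights.
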