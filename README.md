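# idrtracks

Annotation tracks for intrinsically disordered proteins (IDPs), computed
three ways and keyed by controlled-vocabulary triplets
(evidence / feature / source):

- **Structure-derived disorder and LIP calling** from AlphaFold-style
  predicted structures. Two disorder definitions — per-residue confidence
  pLDDT < 70, and relative solvent accessibility (RSA) averaged over a
  25-residue sliding window > 0.58 — plus **linear interacting peptides
  (LIPs)**: residues that are confident (pLDDT ≥ 70) *and* exposed
  (smoothed RSA > 0.58), the intersection that marks conditional folding
  upon binding. RSA comes from a built-in Shrake–Rupley engine normalised
  by theoretical maximum accessible areas (Tien et al. 2013).
- **Homology transfer** of curated region annotations through pairwise
  alignments in BLAST tabular format. A projected region is accepted only
  when the fragment covers ≥ 90% of the annotated query region, gaps are
  ≤ 20% of the fragment columns and ≥ 80% of the columns are identical
  pairs; overlaps on a target protein are resolved greedily, longest
  region first.
- **Sequence-logo conservation** over a query-anchored multiple alignment
  built from pairwise hits: per column, the consensus character's height
  `f_max × (log2 20 − H)` bits and the occupancy (fraction of non-gap
  rows).

A deterministic fixture generator builds synthetic structures (folded
cores plus exposed tails with chosen confidence levels) and alignment
sets with known accept/reject outcomes, so everything is testable with no
downloads. Who it is for: maintainers of protein disorder resources and
anyone who wants these standard derivations reproducible on their own
models and alignments.

## Worked example

A 46-residue synthetic chain: a confident extended segment (pLDDT 90,
residues 14–33) flanked by low-confidence tails (pLDDT 40).

```r
library(idrtracks)
model <- make_structure(fixture_spec(segments = data.frame(
  kind = "extended", length = c(13L, 20L, 13L), plddt = c(40, 90, 40))))
ann <- annotate_structure(model)
ann$regions
#>   start end  feature   evidence          source
#> 1     1  13 disorder prediction alphafold-plddt
#> 2    34  46 disorder prediction alphafold-plddt
#> 3     1  46 disorder prediction   alphafold-rsa
#> 4    14  33      lip prediction       alphafold
```

The two tails are disordered by confidence; the whole exposed chain is
disordered by RSA; and the middle segment — confident *and* exposed — is
called a LIP at exactly the designed 14–33. The per-residue table shows
why, at the left boundary:

```r
ann$profiles[12:16, ]
#>    resno aa plddt       rsa smoothed_rsa disorder_plddt disorder_rsa   lip
#> 12    12  G    40 0.8144055    0.7984083           TRUE         TRUE FALSE
#> 13    13  G    40 0.8334942    0.7987851           TRUE         TRUE FALSE
#> 14    14  G    90 0.8421709    0.7891588          FALSE         TRUE  TRUE
#> 15    15  G    90 0.8078300    0.7891588          FALSE         TRUE  TRUE
#> 16    16  G    90 0.7593427    0.7891588          FALSE         TRUE  TRUE
```

The same pipelines are exposed on the command line (`exec/idrtracks`):

```sh
idrtracks af-disorder model.pdb --out-dir out      # JSON document + per-residue TSV
idrtracks transfer regions.tsv alignments.tsv      # transferred regions + audit TSV
idrtracks conserve query.fasta alignments.tsv      # per-column conservation TSV
idrtracks fixtures --out-dir corpus                # synthetic test corpus
idrtracks cv                                       # print the controlled vocabulary
```

All coordinates are 1-based inclusive. Alignments use BLAST
`-outfmt "6 qseqid sseqid qstart qend sstart send qseq sseq"`.

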