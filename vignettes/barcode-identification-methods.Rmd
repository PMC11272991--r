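---
title: "Methods: DNA-barcode species identification for Acropora and when it fails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-barcode species identification for Acropora and when it fails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrobar)
```

## The problem

Stony corals of the genus *Acropora* are the most heavily traded corals in
the aquarium industry, and trade regulation (CITES Appendix II; stricter
national rules in some jurisdictions) works best when specimens can be
identified to species. Morphological identification of *Acropora* is
notoriously hard, so DNA barcoding with two loci — the mitochondrial
putative control region (mtCR) and the nuclear *PaxC* intron — is the
common fallback. Both loci, however, evolve slowly relative to speciation
in this genus, and distinct species frequently carry identical haplotypes.
`acrobar` implements the full identification procedure (hit ranking,
hierarchical assignment, two-locus concordance), a leave-one-out protocol
for measuring whether a reference database can identify its own members,
and a simulator that generates barcode datasets with exactly the divergence
structure that makes identification fail.

## Hit ranking

Queries are compared to every reference record by Smith–Waterman local
alignment with affine gaps (Gotoh algorithm; a gap of length $k$ costs
`gap_open` $+ k \cdot$ `gap_extend`). Raw scores $S$ are rescaled to bit
scores with the Karlin–Altschul form

$$S' = \frac{\lambda S - \ln K}{\ln 2},$$

and E-values are reported as $mn\,2^{-S'}$ with $m$ the query length and
$n$ the summed database length (E-values are informational only; no
decision uses them). The default scoring scheme is the classic
blastn-style one: match $+2$, mismatch $-3$, gap open 5, gap extend 2,
$\lambda = 0.625$, $K = 0.41$. IUPAC ambiguity codes (including N) score as
mismatches and never count as identities — an `N` run cannot manufacture a
100% match. Percent identity is $100 \times$ identities / alignment
columns (gap columns included).

Two numeric conventions matter downstream and are fixed package-wide:
percent identities are rounded to 3 decimals and bit scores to 1 decimal
*before* any equality test. That is the precision of tabular BLAST
reports, i.e. the granularity at which real-world tie decisions are made,
and it makes results reproducible across ingested hit files and internally
computed ones. Hit tables keep one hit per subject (best raw score) and
are sorted by bit score (descending), percent identity (descending), then
subject id — a total order, so repeated runs and permuted databases give
byte-identical tables.

The alignment kernel is compiled code with deterministic tie-breaking
(diagonal over gap-in-subject over gap-in-query over restart; the optimum
is the first strictly best cell in row-major order). On x86 an AVX2
lane-parallel path aligns eight subjects in lockstep and is selected by a
runtime CPU check; the portable scalar path implements identical
recurrences, and the test suite asserts exact agreement between the two,
against an independent plain-matrix DP oracle, and against
`Biostrings::pairwiseAlignment` scores.

## The assignment decision tree

Per query and locus, evaluated over *distinct species* (several hits to
the same species never constitute a tie):

1. **Barcode mode only.** If exactly one species is matched at 100.000%
   identity, assign it (`UNIQUE_100`).
2. Otherwise, if exactly one species holds the maximum bit score, assign
   it (`BITSCORE_TOP`).
3. Otherwise, among the bit-score-tied hits, if exactly one species holds
   the maximum percent identity, assign it (`IDENTITY_TIEBREAK`).
4. Otherwise, no species is assigned (`UNASSIGNED_TIE`).

Genome mode — used for whole-mitogenome databases, where a perfect
full-length match is unrealistic — skips step 1 and never fires
`UNIQUE_100`. Step 2 ranks over the *whole* hit list, not just the
100%-identity subset, so a 99%-identity hit with the top bit score can
legitimately beat a perfect-identity hit to another species; `rule_path`
records which rule fired so such cases are auditable.

Reference labels with open-nomenclature qualifiers ("sp.", "cf.", "aff.")
or other non-binomial decoration are *ambiguous*: they participate in the
decision as candidates (a winning "Acropora sp." blocks the runner-up),
but the result is `ASSIGNED_AMBIGUOUS` and is excluded from every
"assigned" tally. We deliberately keep them in the candidate set rather
than filtering them out beforehand: removing them would promote the next
species and overstate how well barcoding works.

A specimen receives a final species only when both markers were cleanly
assigned and agree at binomial level (genus + epithet; qualifiers are
ignored in the comparison, and epithet-less labels match nothing). One
assigned marker gives a preliminary single-marker identity; two clean but
conflicting assignments are discordant.

## Leave-one-out evaluation

To measure whether a reference collection can identify its own members,
each record is queried against the database minus itself and assigned in
genome mode. Species with a single record are excluded as queries — they
cannot possibly self-identify — but stay in the database as hits, which is
exactly what makes shared haplotypes dangerous: a record can be pulled to a
singleton of another species. Correctness is judged at binomial level.
The success rate is $100 \times$ correct / evaluated, where unassigned
records count in the denominator (a tie is a failed identification).
Searches are directional (each query is re-aligned against the remaining
records); we verified empirically that co-optimal local alignments can
carry direction-dependent identity counts in roughly 1% of random pairs,
so a symmetric alignment matrix would not be exactly equivalent to the
per-record search the protocol defines.

An anchor-based rotation utility brings circular sequences (mitogenomes
deposited with arbitrary origins) into a common frame before evaluation:
the best local alignment of a short anchor within the doubled sequence
defines the rotation offset. This is an anchor-seeded standardisation, not
a cyclic-alignment algorithm; it assumes the anchor region is present and
reasonably conserved, and it fails loudly (below `min_anchor_bits`, default
50 bits) rather than guessing. Simulated linear data needs no rotation.

## The simulator

`simulate_dataset()` generates, per locus: one uniform-random ancestor
sequence; per species, a haplotype mutated from the ancestor at the
interspecific rate `inter_div`; with probability `share_prob`, a species
adopts another species' haplotype (species are processed in sequence, so
chained sharing collapses haplotype pools — with two species and
`share_prob = 1` both end up identical, the worst case for
identification); per specimen, a sequence mutated from its species
haplotype at `intra_div`; and per specimen and locus, recovery failure
with probability `dropout`. Substitutions are uniform over the three
alternative bases (Jukes–Cantor-like), with no indels by default — the
failure mode under study is identity ties, not gaps; an optional
`indel_rate` exists for robustness checks. Divergence parameters are raw
per-site substitution probabilities, not corrected distances. All
randomness comes from per-locus substreams derived from one seed by fixed
offsets, so adding a locus does not perturb earlier loci and identical
configurations give byte-identical datasets.

Defaults encode the two-locus *Acropora* survey the package models: 25
species × 5 colonies (125 specimens); an ~900 bp mtCR-like locus with
dropout 0.016 and a ~550 bp *PaxC*-intron-like locus with dropout 0.449,
reproducing the observed recovery asymmetry (~123/125 vs ~69/70 of the
specimens in expectation); low divergence at both loci (inter-species
0.010/0.020, intra-species 0.002/0.005) and mitochondrial haplotype
sharing `share_prob = 0.3`. No published estimates exist for the
divergence rates themselves, so these are our choices: they are set to the
regime the loci are known to occupy (interspecific divergence within a few
fold of intraspecific, far below the barcode-gap ideal), and they are
deliberately *not* tuned to reproduce any particular headline number.

What the simulator does not emulate: phylogenetic correlation among
species (every haplotype derives independently from one ancestor),
coalescent variation within species, the *PaxC* intron's length
polymorphism, sequencing error and chimeras, and the taxonomic
misidentifications that contaminate real public reference databases.
Passing tests on simulated data therefore show that the *procedure*
behaves correctly in controlled divergence regimes — not that real
GenBank-based identification would reach any particular accuracy.

`power_curve()` sweeps `inter_div` over a grid: per replicate it pools each
locus' reference and specimen records into one database, runs the
leave-one-out evaluation, and averages success over loci; replicates share
seeds across grid values (common random numbers), which makes the
monotonicity of the curve visible at modest replicate counts.

## Numerical and design choices

* **Tie precision.** 1 decimal (bits), 3 decimals (identity), everywhere.
* **"100% match"** means 100.000 at 3-decimal precision with no coverage
  requirement by default; `min_aln_length` exposes a coverage floor
  because short perfect fragments are a known trap in real data.
* **"Over 99%"** is a strict inequality.
* **Standard deviations** of identity among assigned queries are sample
  SDs (n − 1 denominator).
* **Species-name normalisation**: capitalised genus, lowercased remainder,
  collapsed whitespace; "A." expands to a configurable genus (default
  *Acropora*). Named hybrids are ordinary binomials. Qualifier tokens
  recognised: sp/sp./cf/cf./aff/aff.; any other decoration (isolate tags,
  bare genus) is ambiguous of kind `other` and is keyed by its full text,
  so distinct raw labels never merge. Public databases carry more
  decoration than the three canonical qualifiers, and treating the rest as
  ambiguous is the conservative choice for identification tallies.
* **Singletons** are defined on the species keys above, so five
  "Acropora sp." records are *not* five singletons.
* **Degenerate inputs**: empty hit tables give `NO_HITS`; an all-singleton
  database evaluates nothing and reports a missing success rate rather
  than 0 or 100; disjoint-alphabet sequence pairs score (0, 0, 0).
* **Ingested hit files** (12-column tabular format) carry no raw scores;
  decisions use the stored bit scores, which is what the format provides.
* **Spreadsheet ingestion** resolves column headers through an external
  key=value mapping because survey spreadsheets have no standard schema;
  the package ships mappings matching its synthetic example tables, which
  mimic the expected layout of a real survey's supplementary tables and
  carry hand-derived statistics in the test suite.

## Problem sizes used by the checks

The test suite and acceptance script run entirely on simulated and
constructed data at desk scale, chosen to exercise each regime while
keeping the whole suite fast: oracle comparisons over the exhaustive
31,179-table decision grid; 200 random databases for ordering stability;
6 species × 3 specimens × 300 bp for the leave-one-out regimes; 10 species
× 4 specimens × 1000 bp × 20 replicates for the power curve; 127 × 2-locus
specimens for the recovery-rate check; and the default 25 × 5 two-locus
study for the end-to-end survey quantities. The acceptance script prints
every number it reports; nothing in the documentation states a result the
code does not compute.

## Known limitations

* The aligner is exhaustive local DP — right for desk-scale reference
  panels (hundreds of records), not a substitute for indexed search over
  nucleotide archives.
* Rotation is anchor-seeded; genomes whose anchor region is rearranged or
  highly diverged will be rejected rather than rotated.
* The simulator's independence assumptions (above) make it a mechanism
  probe, not a generative model of *Acropora* evolution.
* Identification accuracy against live public databases depends on the
  state and curation of those databases and is outside what this package
  can certify.
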