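# acrobar

DNA-barcode species identification for *Acropora* corals — and a testbed
for measuring when it cannot work.

Trade in stony corals is CITES-regulated, and *Acropora* is both the most
heavily traded and the hardest genus to identify morphologically. The
standard molecular fallback is two-locus barcoding: the mitochondrial
putative control region (mtCR) and the nuclear *PaxC* intron. Both loci
evolve slowly relative to speciation in this genus and distinct species
often carry identical haplotypes, so the top of a hit list is frequently a
tie between species. `acrobar` implements the complete identification
procedure and the evaluation machinery needed to quantify that failure
mode:

* **Reference curation** (`read_records`, `build_reference_db`): FASTA +
  metadata ingestion, species-label parsing with open-nomenclature
  qualifiers (sp./cf./aff. are "ambiguous" and never count as identified
  species), genus filtering, singleton detection.
* **Hit ranking** (`search_db`, `local_align`, `bit_score`): exhaustive
  Smith–Waterman local alignment with affine gaps (AVX2-accelerated with a
  portable fallback), Karlin–Altschul bit scores, deterministic total
  ordering; BLAST 12-column tabular files can be ingested instead
  (`read_tabular_hits`).
* **Assignment** (`assign_species`, `concord`): the hierarchical decision
  tree — unique 100% match (barcode mode), then top bit score, then percent
  identity among bit-ties, else unassigned — plus two-locus concordance at
  binomial level.
* **Evaluation** (`loo_evaluate`, `success_rate`): leave-one-out
  self-identification of a reference database, with singleton species
  excluded as queries but kept as hits.
* **Simulation** (`simulation_config`, `simulate_dataset`, `power_curve`):
  seeded two-locus barcode datasets with controllable intra-/inter-species
  divergence, cross-species haplotype sharing and per-locus recovery
  dropout; success-vs-divergence sweeps.
* **Reporting and ingestion** (`summarize_assignments`,
  `hit_distributions`, `read_s1`/`read_s2`/`recompute_results`): survey
  summary statistics and readers for per-sample/per-record result
  spreadsheets with external column mappings.

The assignment rule, per query and locus, over *distinct* species:

1. barcode mode: a single species matched at 100.000% identity wins;
2. else the single species at the maximum bit score (1-decimal precision);
3. else the single species at the maximum percent identity (3 decimals)
   among the bit-score-tied hits;
4. else no assignment.

A specimen gets a final identity only when both loci are cleanly assigned
and agree at binomial level.

## Worked example

```r
library(acrobar)

cfg <- simulation_config(seed = 7)   # 25 species x 5 colonies, mtCR + PaxC
ds  <- simulate_dataset(cfg)
ds
#> synthetic_dataset: 25 species x 5 samples, loci: mtCR, PaxC (seed 7)
#>   mtCR: 25 reference record(s), 122 recovered queries
#>   PaxC: 25 reference record(s), 66 recovered queries

q    <- ds$queries[ds$queries$locus == "mtCR", ][1, ]
hits <- search_db(q$sequence, ds$reference$mtCR, query_id = q$query_id)
head(hits[, c("subject_id", "subject_species", "pct_identity", "bit_score")], 4)
#>     subject_id subject_species pct_identity bit_score
#> 1 REF_mtCR_001   Acropora sima       99.778    1615.3
#> 2 REF_mtCR_017   Acropora simq       99.778    1615.3
#> 3 REF_mtCR_024   Acropora simx       98.109    1545.9
#> 4 REF_mtCR_011   Acropora simk       98.000    1543.2

assign_species(hits, mode = "barcode", locus = "mtCR")
#>   query_id locus         status species rule_path top_identity n_species_at_100
#> 1     S001  mtCR UNASSIGNED_TIE    <NA>      NONE       99.778                0
```

The recovery counts mirror the loci's amplification asymmetry (mtCR almost
always recovers, *PaxC* fails in roughly half the samples). The query's two
best hits are *different species* with identical bit scores and identical
percent identity — the haplotype-sharing signature — so the decision tree
correctly refuses to assign a species. `concord_all()` then combines the
two loci per specimen, and `summarize_assignments()` /
`hit_distributions()` produce the survey-level tables (assigned counts,
identity means ± SD, and the histogram of how many species tie at 100%).

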