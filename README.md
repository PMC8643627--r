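# starrkit

Quantitative analysis of UMI-tagged STARR-seq reporter screens in R.

STARR-seq measures enhancer activity by letting candidate DNA fragments
drive their own transcription from a reporter plasmid; tagging reporter
transcripts with unique molecular identifiers (UMIs) makes the readout
quantitative by separating independent transcripts from PCR duplicates.
`starrkit` implements the full downstream analysis for such screens:

* **UMI deduplication** — exact and directional (Hamming-distance
  network) collapsing of PCR duplicates, per replicate and condition.
* **Activity quantification** — normalized STARR scores
  `((u+1)/(U+1)) / ((i+1)/(I+1))` per region (reporter molecules `u`
  over input fragments `i`, each normalized by library totals), log2
  scale, replicates merged on the log scale; stored in a
  `StarrExperiment` (a `RangedSummarizedExperiment`).
* **Enhancer calling** — one-sided exact binomial test of each region's
  reporter abundance against the input-library background (conditioned
  on `u + i`), BH-adjusted, with "called in ≥ 2 replicates", "called in
  the merged pool" and "≥ 3 distinct fragments" confidence filters.
* **Activity ranking** — quantile groups of ascending activity and
  round-half-up extreme sets (1% of 170,190 regions = 1702; 10% of
  16,769 = 1677).
* **Differential activity** — RA-inducible vs LIF-dependent enhancers by
  log2 fold change of merged scores plus Fisher exact tests on pooled
  molecule counts (|log2FC| ≥ 1, adjusted p ≤ 0.05), and classification
  of receptor-occupied sites into induced / repressed / non-responding.
* **Motif toolkit** — JASPAR PFM I/O, log-odds scanning with exact
  dynamic-programming score thresholds, AME-style two-set enrichment
  with seeded background subsampling (E ≤ 1e-3), per-region hit counts,
  Ward/Manhattan clustering of enrichment matrices, and construction of
  all 27 DR/IR/ER × 0–8 bp spacing variants of the RGKTCA
  nuclear-receptor half-site.
* **Sequence classifier** — elastic-net logistic regression (motif hit
  counts + region width) with nested cross-validation (4 outer × 5
  inner folds, AUC-maximizing grid search, leakage-free
  standardization).
* **Chromatin context** — k-means clustering of 8-mark
  histone-modification profiles with activity-ordered labels, nearest-TSS
  expression comparisons, and overlap accounting between enhancer
  catalogs.
* **Synthetic study generator** — seeded, fully ground-truthed toy
  genomes, UMI-tagged reporter libraries with PCR-duplicate (and
  jackpot) structure, planted differential enhancers, motif-planted
  sequences and HM matrices, used by the test suite for
  parameter-recovery checks.

## Worked example

```r
library(starrkit)

cfg <- synthConfig(seed = 3, conditions = "LIF",
                   fracRaInducible = 0, fracLifDependent = 0)
sim <- simulateGenome(cfg)                 # toy genome + 200 regions
lib <- simulateReporterLibrary(cfg, sim)   # ~1.9M reads, ~470k molecules
mol <- dedupUmi(lib$fragments)             # collapse PCR duplicates
se  <- quantifyRegions(sim$regions, mol, lib$input)
se  <- callEnhancers(se)                   # fdr 0.05, >=2 reps, >=3 frags
se
#> StarrExperiment: 200 regions x 3 samples
#> conditions: LIF
#> active regions: 10 / 200

at <- activityTable(se)
head(at[at$is_active, c("region", "log_score", "called_in")], 3)
#>                  region log_score called_in
#> region_0012 region_0012 1.2716138         3
#> region_0013 region_0013 0.2744143         3
#> region_0018 region_0018 2.2677719         3
```

All ten planted enhancers (fold-activations 2–32×) are recovered with no
false positives; `log_score` is the log2 STARR score (reporter over
input, library-normalized), and `called_in` counts the replicates in
which the region passed the background test individually.

The full pipeline — simulation, dedup, calling, ranking, differential
testing, receptor response classes, motif enrichment, spacing scan,
classifier and HM clustering — runs end to end with:

```r
summary <- runDemo("demo_out", seed = 1)
summary$calling_precision   # 1
summary$calling_recall      # 1
summary$hm_ari              # 1
```

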