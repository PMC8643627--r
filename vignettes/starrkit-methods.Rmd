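---
title: "Quantifying enhancer activity from UMI-tagged STARR-seq: models and design"
author: "starrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enhancer activity from UMI-tagged STARR-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and the quantification model

STARR-seq places candidate DNA fragments downstream of a minimal promoter
so that active fragments transcribe themselves; the abundance of
reporter-derived transcripts measures the enhancer activity of the
fragment. When the candidate library is built from accessible chromatin,
the screen covers the regions most likely to act as promoters or
enhancers, and each accessible region is represented by several distinct
sheared fragments. Reporter transcripts are tagged with a random unique
molecular identifier (UMI) during reverse transcription, which lets the
analysis separate independent transcripts from PCR copies of the same
molecule — without this, a single jackpot amplification can dominate a
region's apparent activity.

`starrkit` implements the computational side of such a screen:

1. **UMI deduplication** (`dedupUmi()`). Reads collapse to one molecule
   per distinct (chromosome, start, end, strand, UMI) tuple within each
   replicate and condition. The optional *directional* mode additionally
   absorbs UMIs at the same coordinates that are within a small Hamming
   distance of a UMI at least twice as abundant — the standard network
   rule for sequencing errors in UMIs. `N` bases match nothing, so
   damaged UMIs never cause spurious merging. Deduplication never crosses
   replicates.

2. **STARR scores** (`starrScore()`, `mergedLogScores()`). The activity
   of region *r* in sample *s* is the depth-normalized ratio of its
   unique-molecule count to its input-library count,
   $\mathrm{score} = \frac{(u_r + c)/(U + c)}{(i_r + c)/(I + c)}$,
   reported as log2 with pseudocount $c = 1$; replicate scores are
   averaged on the log scale. The source study does not print its score
   formula; this is the simplest normalized ratio consistent with a
   logarithmic activity axis, and all downstream steps treat it as a
   relative, not absolute, quantity.

3. **Enhancer calling** (`callEnhancers()`). Per replicate, a region is
   *called* when a one-sided exact binomial test finds its reporter
   abundance above the input expectation after Benjamini–Hochberg
   adjustment (default FDR 0.05); a region is *active* when called in at
   least 2 replicates, called in the merged pool, and supported by at
   least 3 distinct fragment coordinates. The output partitions the
   candidate set into active and inactive regions. The test conditions on
   the region's combined reporter + input count
   ($u_r \sim \mathrm{Binom}(u_r + i_r,\ U/(U+I))$), the exact test for a
   ratio of two counting processes. An earlier draft fixed the input
   share $i_r/I$ as a known constant; because the input is itself a
   Poisson sample shared by all replicates, that variant produced
   coherent false positives whenever a region's input coverage dipped,
   and the conditional form removes this failure mode exactly.

4. **Ranking** (`activityQuantiles()`, `selectExtremes()`). Active
   regions are ranked by log score into *k* equal rank groups (default
   5, remainders to the lowest groups), and extreme sets take the
   fraction-of-n highest and lowest scorers with sizes rounded half up —
   the rounding is pinned by the set sizes a 1%/10% split of a
   170,190/16,769-region library produces (1702 and 1677).

5. **Differential activity** (`differentialEnhancers()`). The effect is
   the difference of merged log scores (RA − LIF); significance comes
   from a two-sided Fisher exact test on pooled molecule counts (region
   vs rest of library, by condition), BH-adjusted. Classes use
   |log2FC| ≥ 1 and adjusted p ≤ 0.05 — the same thresholds commonly
   applied to differential gene expression. Swapping the condition
   labels exactly swaps the RA-inducible and LIF-dependent sets.

6. **Receptor response classes** (`classifyResponseSites()`). Among
   quantified regions overlapping a ChIP peak and clearing a minimum
   mean activity, the 10% most induced, 10% most repressed, and an equal
   number of regions closest to zero change form three disjoint sets.
   The genome-scale default floor (mean log score ≥ 2.5) is kept as the
   function default; the scale of that floor (log2 vs natural log) is
   not recoverable from the source material, and at desk scale the
   library-composition normalization shifts absolute scores, so the demo
   pipeline disables the floor and documents it.

# Motif machinery

**Scanning** (`scanMotif()`). Motifs are scored as log2 odds against the
background base composition at every offset on both strands. The hit
threshold for tail probability *p* (default 1e-4) is computed from the
*exact* distribution of the window score under the background model by
per-column convolution on scores discretized to 0.01 bits; thresholds
are therefore reproducible and sequence-independent. Windows containing
`N` are skipped; for counting, overlapping hits are resolved greedily by
descending score. Short motifs (width ≤ 6) cannot reach a 1e-4 tail (a
perfect 4-mer match already has probability 0.4%), so scans of such
matrices return no hits unless a larger *p* is chosen — a property, not
a bug, that the documentation flags.

**Enrichment** (`enrichTwoSets()`). AME-style: per motif, the number of
foreground vs background regions containing at least one hit enters a
one-sided Fisher exact test, and p is scaled by the number of motifs
tested into an E-value (enriched at E ≤ 1e-3 by default). When the
background outnumbers the foreground, ten seeded equal-size background
subsamples are drawn and the mean E is reported. The log-ratio
−log10(E<sub>fg</sub>) + log10(E<sub>bg</sub>) contrasts two sets
symmetrically. Of the several statistics AME offers, the
Fisher-on-hit-regions variant was chosen because an exact hypergeometric
oracle can verify it to machine precision.

**Repeat variants** (`buildComposite()`). Nuclear-receptor response
elements are direct (DR), inverted (IR) and everted (ER) repeats of the
hexameric half-site RGKTCA with spacers of 0–8 bp: DR = H·S·H,
IR = H·S·revcomp(H) (head-to-head), ER = revcomp(H)·S·H (tail-to-tail),
with a background-uniform spacer. IR/ER orientation follows standard
nuclear-receptor nomenclature; published figures indicate orientation
only with arrows, so the convention is stated here explicitly. The
half-site matrix is consensus-derived (degenerate positions split
0.455/0.455, determinate ones 0.91) rather than taken from a reference
matrix; `rarHalfSite()` documents this. `spacingEnrichment()` enriches
each response class against the pooled others over all 27 variants,
keeps variants with min E ≤ 1e-3, and Z-scores −log10 E within rows.

**Enrichment-matrix clustering** (`clusterEnrichmentMatrix()`): Ward
linkage on Manhattan distances, the combination used for motif-by-class
heatmaps.

# Sequence classifier

`nestedCvElasticNet()` fits a regularized logistic regression (elastic
net, via glmnet) to separate activity extremes from sequence features:
region width plus the count of significant hits per clustered motif
(`buildFeatureTable()`). "Enrichment" of a motif in a region is
operationalized as this hit count — the simplest region-level statistic;
best-hit scores are a plausible alternative the source does not
disambiguate. Nested cross-validation separates model selection from
evaluation: four stratified outer folds each hold out 25% (so every
region is held out exactly once, matching a 75/25 split); the inner
5-fold loop grid-searches the mixing parameter α ∈ {0, 0.1, …, 1} and
30 log-spaced penalties λ ∈ [1e-3, 1e2] to maximize mean inner AUC.
Standardization parameters (mean/sd) are learned on the training portion
of every split only, so no information leaks from held-out data; final
coefficients come from refitting the overall best configuration on all
data. `buildTrainingSets()` implements the two-branch design: candidate
regions are first split by overlap with promoter windows (500 bp
upstream of a TSS), then 1% extremes train the enhancer model and 10%
extremes the promoter model — the promoter branch is an order of
magnitude smaller, hence the larger fraction. Two promoter definitions
coexist deliberately: 1 kb upstream for genomic annotation
(`promoterWindows()` default) and 500 bp upstream for the classifier
split, both kept as per-analysis defaults.

# Chromatin-state clustering

`kmeansHm()` column-standardizes the region × 8-mark enrichment matrix,
runs k-means with 10 restarts, and relabels clusters by descending mean
of an activity mark (H3K27ac by default) so that labels are stable and
ordered. k defaults to 8 — the number of chromatin-state groups commonly
distinguished at enhancers (promoter-like, classical active, poised,
repeat-associated, repressed…) — but is configurable since the right k is
a property of the data. `expressionByGroup()` pairs regions to genes by
nearest TSS (midpoint distance, ties lexicographic, 1 Mb cap — an
explicit, simple stand-in for distance-based pairing tools) and compares
neighboring groups with two-sided Mann–Whitney tests, BH-adjusted;
degenerate all-tie comparisons report p = 1.

# The synthetic study

`synthConfig()` + `simulateGenome()` / `simulateReporterLibrary()` /
`simulateHmMatrix()` / `simulateLabeledSequences()` generate every input
with known ground truth. What they emulate:

* i.i.d. genome at GC 0.45 with non-overlapping accessible regions,
  log-normal widths (median 350 bp — active enhancers in such screens
  average ~340–390 bp);
* unique molecules per region ∝ depth × planted fold-activation
  (grid 2–32×, three replicates, 500 molecules/region/replicate);
* random 10-bp UMIs (collisions allowed, as with real random-mers);
  PCR duplicates with geometric multiplicity (mean 4 reads/molecule)
  and an optional 100× jackpot molecule;
* fragment-coordinate jitter (mean 8 variants/region) so the distinct-
  fragment filter is meaningful — real regions are captured by hundreds
  of distinct fragments, so a mean of 8 is deliberately conservative and
  occasionally (≈0.6% of regions) produces a region with fewer than 3
  variants that the confidence filter will rightly exclude even if
  planted active;
* a 5% active fraction: the real screen finds ~2.5% of accessible
  regions active, but at 200 desk-scale regions that would leave too few
  planted enhancers to estimate recovery rates; 5% preserves "active
  regions are a minority";
* condition-specific enhancers (RA-inducible / LIF-dependent) as 4×
  fold-changes between conditions;
* motif insertions: driver motifs at 60% probability in active vs 10%
  in inactive regions;
* HM matrices with 3 planted mean-shifted clusters (separation 3, noise
  sd 0.5).

What they do **not** emulate: read-level errors (no FASTQ, no UMI
sequencing errors beyond the Hamming machinery), alignment artifacts,
fragment-length or GC bias, chromatin-context correlations between
neighboring regions, and genome-scale library sizes. Passing
recovery tests therefore demonstrates correctness of the algorithms
under the stated sampling model, not performance on real sequencing
data.

# Numerical choices and problem sizes

* PFM→probability conversion uses a 0.5 pseudocount per cell; log-odds
  scores floor motif probabilities at 1e-4; scan DP granularity is
  0.01 bits.
* All tie-breaks are deterministic (score, then input order; UMI merges
  by abundance then lexicographic), so every result is reproducible
  under a fixed seed.
* Set sizes from fractions round half up everywhere.
* The test-suite and demo problem sizes — 200 regions × 500
  molecules × 3 replicates × 2 conditions for calling, 300 regions for
  differential recovery, 600 labeled sequences for the classifier, 1000
  sequences × 4 motifs × 20 seeds for enrichment recovery — were chosen
  as the smallest sizes at which the planted effects dominate sampling
  noise by a comfortable margin.
* At desk scale some genome-scale analyses are intentionally
  underpowered and report honest nulls: ten active regions cannot reach
  E ≤ 1e-3 in a motif enrichment, and three-region response classes
  cannot power a spacing scan; the dedicated fixtures size these
  analyses properly.

# Known limitations

* The STARR score is a relative quantity; absolute thresholds quoted on
  other scales (e.g. an activity floor of 2.5) need recalibration to the
  library at hand.
* The caller assumes molecule counts are Poisson-like after UMI
  collapse; strong overdispersion beyond PCR duplication (e.g.
  transfection batch effects) is not modeled.
* `nearestTss()` pairing is a deliberate simplification of regulatory
  domain tools; it ignores domain boundaries and multi-gene assignment.
* The directional UMI merge is greedy, not a full network resolution;
  for the UMI lengths and depths simulated here the difference is
  negligible.
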