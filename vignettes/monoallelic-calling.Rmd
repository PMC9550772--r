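---
title: "Calling allele-specific expression states: models, thresholds, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling allele-specific expression states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoallelix)
```

## Scope and model

`monoallelix` analyses allele-resolved count tables from F1-hybrid
RNA-seq, where every sample carries a maternal (e.g. C57BL/6J) and a
paternal (e.g. CAST/EiJ) count per gene. The quantity everything rests on
is the allelic fraction

  f = mat / (mat + pat),

and the target is a per-gene, per-population label among `biallelic`,
`DeMA_mat`, `DeMA_pat` (deterministic monoallelic — the active allele is
predetermined, as for imprinted genes), `RaMA` (random autosomal
monoallelic — the active allele is an independent coin flip per cell),
`not_expressed`, and `inconclusive`.

Upstream processing — read alignment to a diploid reference, SNP-level
read assignment, cell clustering — is out of scope; the package consumes
count tables whose samples already carry population labels.

## The classifier and its thresholds

Six thresholds drive the calls (`call_thresholds()`); all are exposed in
configuration and none is hidden in code:

| parameter | default | units | role |
|---|---|---|---|
| `min_total` (m) | 5 | counts | detection floor for an informative (gene, sample) pair |
| `mono_fraction` (θ) | 0.98 | fraction | `f ≥ θ` → mono-maternal, `f ≤ 1−θ` → mono-paternal |
| `min_cells` | 5 | cells | informative cells needed for any population call |
| `rama_min_cells` (k) | 3 | cells | cells required on *each* allele for RaMA |
| `max_biallelic_frac` (β) | 0.10 | fraction | biallelic-cell share tolerated by a monoallelic verdict |
| `min_expressed_frac` (q) | 0.05 | fraction | informative share of samples for "expressed" |

Choices worth justifying:

- **θ-exclusivity instead of literal zero.** "Expressed solely from one
  allele" is brittle at the read level because a small fraction of reads
  is misassigned across alleles at shared or mis-genotyped SNPs. We treat
  a gene as monoallelic in a sample when the minor allele carries at most
  2% of reads (θ = 0.98); the literal-zero semantics is the θ = 1 limit
  and remains available. Ties at exactly θ resolve to the monoallelic
  call (`≥`), so the rule is symmetric under allele relabeling.
- **Expression gating on raw counts, not CPM.** Per-cell libraries are
  small; m is a detection floor, not an abundance measure. CPM
  (`cpm_normalize()`, combined maternal+paternal library) is provided for
  reporting only.
- **β, the biallelic tolerance, is our construct.** Some cells of a
  genuinely monoallelic gene show intermediate fractions (leak, doublets,
  ambient reads). A monoallelic or RaMA verdict tolerates at most a 10%
  biallelic share; any larger share is evidence for genuine biallelic
  expression and wins outright.
- **Bulk never calls RaMA.** Clonal replicates expand from single cells,
  so a RaMA gene's allele choice is fixed within each clone; with three
  clones, all-same-allele happens with probability 1/4 and mimics DeMA
  perfectly. The bulk filter therefore only separates DeMA (same allele
  exclusive in *every* replicate) from biallelic, sending unanimity
  violations to `inconclusive` (strict default) or `biallelic` (lenient
  switch). RaMA detection requires single cells, where
  `rama_min_cells` cells on each allele plus the β gate identify it.

DeMA is checked before RaMA, and the two cannot overlap: DeMA requires
zero cells on the silent allele while RaMA requires at least k on each.

## The generator: what it emulates, what it does not

`sim_params()` defines the study conditions the package is tested under:

- per-gene expected total expression is log-normal (log-mean log(100),
  log-sd 1 — a realistic spread for detected genes in scRNA-seq);
  per-sample totals are negative-binomial with dispersion 0.1;
- class proportions default to biallelic 0.72, DeMA_mat 0.055, DeMA_pat
  0.01, RaMA 0.015, not_expressed 0.20 — a 5.5:1 maternal:paternal DeMA
  imbalance and a RaMA share of roughly 1.5–2% of expressed genes,
  matching the magnitudes reported for mouse embryonic stem cells;
- allelic dropout d = 0.3: each expressed allele of a cell is
  independently zeroed with probability d before counts are drawn —
  the main confound the classifier must resist;
- leak ε = 0.005: a monoallelic gene's reads are Binomial-misassigned to
  the silent allele at this rate, modelling SNP misassignment; the
  "solely expressed" regime is ε = 0;
- class counts are assigned by **largest-remainder quota**, not per-gene
  multinomial sampling, so realized class sizes equal their expectations
  exactly and recovery tests have exact targets;
- every gene draws from a counter-based substream of the global seed, so
  enlarging a simulation never perturbs earlier genes' data.

The transcript-state generator assigns expressed genes to
`active_only` / `mature_only` / `active_and_mature` by quota. Its default
fractions (0.314 / 0.605) are the unique solution under which 88.2% of
mature-transcript-bearing genes lack nascent signal and 79.5% of actively
transcribing genes lack mature transcripts — the two census quantities
the package reports, each on its own denominator. Present channels are
drawn from a *zero-truncated* negative binomial so that a gene's realized
state at detection threshold 1 equals its assigned state; without
truncation, NB zeros would contaminate quota recovery.

Deliberately not modelled: batch effects, read-level or SNP-level
structure, gene length, doublets, cell-cycle signal, and any correlation
between expression level and class. Passing the recovery tests therefore
shows the *filters implement their definitions correctly under NB noise,
dropout and leak* — not that the thresholds are optimal for any
particular real data set, where these unmodelled features exist.

## Comparison and enrichment statistics

- `imbalance_ratio()` is the DeMA_mat:DeMA_pat gene-count quotient with a
  bootstrap percentile CI from resampling the classified gene list
  (genes, not cells — the ratio is a gene-census statistic; resampling is
  realized as a multinomial draw over class counts, which is the same
  distribution, vectorized).
- `status_change()` buckets genes classified in both of two tables into
  mono→biallelic, biallelic→mono, mono-same-allele,
  mono-switched-allele (enumerated explicitly — the rare outliers), and
  biallelic-stable. Genes RaMA, inconclusive, or unexpressed in either
  table are excluded and counted, not guessed: the statistic concerns the
  classified cohorts. Whether switch candidates may pass through an
  inconclusive intermediate was an open design point; we require a firm
  monoallelic call on both sides.
- `intersect_classes()` computes exclusive (UpSet-style) intersections,
  ordered by descending size then lexicographically, so outputs are
  deterministic.
- `fisher_enrich()` is the upper-tail hypergeometric test
  P(X ≥ k | N, K, n); `bh_adjust()` applies Benjamini–Hochberg (it
  validates and delegates to `stats::p.adjust`; the test suite holds it
  against an independent step-up implementation). `combined_score()`
  multiplies −ln(p) by the z-score of the term's rank deviation from its
  expected rank under random same-size queries. The background-rank
  construction (uniform same-size query draws, default 1,000, seeded) is
  an interpretation of the one-line definition in common use; draw count
  and seed are exposed because different background choices shift
  magnitudes. Natural log and the μ−observed orientation make stronger
  enrichment give larger positive scores. When the universe is not
  supplied it defaults, with a warning, to the union of the term sets.
- `transcripts_per_gene_summary()` tabulates (optionally protein-coding)
  transcripts per gene by class and applies a one-sample t-test against a
  reference mean; constant groups sitting on the reference return t = 0,
  p = 1 rather than an error.

## Numerical and degenerate-input policy

- A (0, 0) count pair is `not_expressed`, never an error; f is undefined
  (NA) there.
- `imbalance_ratio()` with zero paternal genes reports the counts with an
  NA ratio instead of raising.
- Sparse TSV cells are read as 0 with a warning; unpaired B/C columns,
  duplicate genes, negative, fractional or non-numeric counts are errors
  naming the offending gene and column.
- BH adjustment is *not* idempotent (applying it to its own output
  rescales by m/j again); the package makes no such claim and tests
  monotonicity (adjusted ≥ raw, ≤ 1) and oracle agreement instead.
- All stochastic steps take explicit seeds; pipeline stage seeds are
  derived from the global seed and recorded in the run manifest, and a
  rerun under an identical configuration is byte-identical.

## Problem sizes used in the test suite

Recovery and robustness properties are exercised at 2,000 genes × 200
cells (noise-free recovery), 20 × 1,000 genes × 200 cells at dropout 0.3
(biallelic-as-RaMA rate ≤ 1%), 200 bulk simulations of 2,000 genes with a
550:100 DeMA quota (CI calibration against the 5.5 ratio), 1,000 genes
for the census quota, and 1,000 random instances each for the Fisher
(N ≤ 12, exhaustive enumeration) and BH oracles. These sizes give exact
quota targets and negligible Monte-Carlo ambiguity while keeping the
full suite under a minute of compute.

## Known limitations

- Thresholds are heuristics over counts; they are not a likelihood model
  of dropout, and very high dropout with small β will eventually push
  biallelic genes into monoallelic calls — the failure mode is
  documented and monotone in the thresholds rather than silent.
- Bulk RaMA is structurally unidentifiable (above); bulk tables can only
  contribute DeMA/biallelic calls.
- The nascent/mature census consumes caller-supplied nascent and mature
  count columns; deriving them from alignments (intronic vs junction
  reads) is upstream of this package.
- Combined scores are comparable within one analysis, not across
  different backgrounds or draw counts.
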