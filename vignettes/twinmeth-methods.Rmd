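---
title: "Methods: differential and variable methylation in MZ twin designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential and variable methylation in MZ twin designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
options(twinmeth.verbose = FALSE)
```

## The design and its assumptions

`twinmeth` analyses methylation beta values (β = M/(M+U+α), the methylation
fraction of a CpG site estimated from methylated and unmethylated
fluorescence intensities with a stabilising offset α, default 100) in a
monozygotic-twin sample partitioned into three diagnostic groups of pairs:
*concordant* (both co-twins affected), *discordant* (exactly one affected)
and *healthy* (neither). Because MZ co-twins are genetically near-identical,
within-pair differences are attributed to unique environment plus stochastic
epigenetic drift; the three-group contrast is what lets the two analyses
separate systematic disease-associated shifts from group-specific
variability.

Assumptions the methods rely on:

* the sample sheet is the single source of pair/group/affected labels;
  beta-matrix columns are joined on sample id, order-free;
* probes with missing values among the samples a given analysis uses are
  dropped from that analysis, with a logged count (missingness is assumed
  uninformative);
* all statistics operate on the β scale. A logit `beta_to_mvalue()`
  transform is provided as an opt-in utility only, without any claim that it
  matches the original analytic choice, which is unstated in the tradition
  this package follows.

## DMPs: rank combination over discordant pairs

Per probe, a classical paired t-test (df = n−1) is applied to the
affected-minus-unaffected differences Δβ across the n discordant pairs, and
the mean Δβ is kept as the effect size (sign convention: affected minus
unaffected, so hypomethylation in affected co-twins yields negative values).
Two linear rank scores are then assigned over the m probes: from P (lower is
better) and from |mean Δβ| (higher is better); each maps to 1..m with best =
m and ties averaged. The combined score is their sum and probes are ranked
by it, descending.

Design choices that were genuinely open:

* **Score construction.** The rank-combination tradition assigns "a score"
  from P and from |Δβ| without fixing the mapping. We use linear rank scores
  (ties averaged) — the simplest monotone mapping consistent with "the lower
  the P, the higher the score". A binned score would change only the
  granularity, not the top of the ranking, for continuous data.
* **Tie handling.** Equal combined scores are broken by smaller P, then by
  probe id, so output order is deterministic. Ties in P or |Δβ| are detected
  after rounding to 12 decimals: both quantities live in [0, 1], and the
  rounding keeps analytically equal values (e.g. identical difference
  multisets producing last-ulp floating-point discrepancies) in a single tie
  group. The brute-force acceptance oracle applies the same contract.
* **Degenerate probes.** Zero-variance difference vectors are flagged; the
  limiting P is 0 for a non-zero common difference and 1 otherwise, which
  keeps constant probes rankable without special-casing downstream.
* **No multiple-testing correction.** The procedure is a ranking, not an
  inference; raw P values are reported.

## Cross-group validation

A top probe is only biologically interesting as a disease marker if its
intrapair differences are specific to discordant pairs — a probe with large
|Δβ| in every group is merely environmentally sensitive. For each top probe
we compute |Δβ| in all pairs and run two one-sided Wilcoxon–Mann–Whitney
tests (discordant greater than concordant; discordant greater than healthy).
With 6 discordant vs 4 concordant or 7 healthy pairs the pooled sample is at
most 13, so the exact rank-sum null distribution is used whenever the pooled
values are tie-free and n₁+n₂ ≤ 13; otherwise the normal approximation with
continuity correction and tie-corrected variance takes over (small twin
samples produce ties and zeroes readily, which is also why the exact path
refuses them). Validation is per probe, at a configurable α (default 0.05 —
the directional hypotheses come from the design; the level is our choice).
Orientation of concordant/healthy pairs is arbitrary, and results are
invariant to it because only absolute differences enter.

## VMPs: group-median thresholding and exclusivity

Absolute intrapair differences |Δβ| for all pairs form a probes × pairs
matrix; collapsing each group's pair columns to the median yields the
m × 3 group-median matrix at the core of the procedure. Medians rather than
means: with 4–7 pairs per group a single outlying pair would otherwise
dominate (the breakdown property is asserted in the tests). Even-sized
groups average the two central order statistics.

A probe is *variable* in a group when its median ≥ 0.1. The threshold is
**inclusive** — the conventional reading of "differences of 10% or larger
are biologically meaningful" on these arrays — and configurable within
(0, 1). The Venn partition operates on the three thresholded median
indicators (not per-pair indicators): probes variable in exactly one group
are the group-exclusive VMPs; all seven non-empty regions plus "none" are
reported even though the exclusive sets carry the biological reading
(discordant-only: stochastic change in affected co-twins; concordant-only:
symptom heterogeneity within affected pairs; healthy-only: processes
unrelated to, or suppressed in, disease). These readings are interpretive
labels, not computations.

Two summaries accompany the partition: the exceedance fraction (share of all
|Δβ| cells ≥ threshold, with numerator and denominator) and per-exclusive-
group percentages over UCSC gene-region feature categories (TSS1500, TSS200,
5′UTR, first exon, body, 3′UTR, intergenic; multi-category probes count once
per distinct category, unannotated probes are counted explicitly).

## Enrichment stand-in

The original pathway step in this research tradition runs through a GUI
network tool with a dated interaction network — not reproducible as a
library call. It is replaced by transparent over-representation analysis:
one-sided hypergeometric tail P per GMT set (universe defaulting to all
annotated genes), Benjamini–Hochberg FDR across sets. Output metadata
declares the substitution; published pathway tables are not claimed
reproducible.

## The synthetic-data generator

`simulate_twins()` emulates the stated world of the target design: 4
concordant + 6 discordant + 7 healthy pairs (34 samples), per-probe baseline
methylation from a two-component Gaussian mixture (modes 0.15/0.85, sd 0.05,
equal weights — the bimodal shape of 450K beta distributions), additive
per-twin Gaussian noise with sd 0.02 (small intrapair discordance typical of
MZ twins on the β scale), 10 planted DMPs at Δβ = −0.08 in discordant pairs
(the magnitude of the top published effects in this design family) and
(8, 17, 22) group-exclusive VMPs at magnitude 0.3 planted as a ± shift on
one random co-twin per target-group pair. Planted sets are pairwise
disjoint; everything is clipped to [0, 1]; identical config + seed is
bit-identical.

What it deliberately does **not** model: probe-type/dye chemistry, batch
effects, cell-type composition, spatial correlation along the genome, and
logit-scale heteroscedasticity. Additive Gaussian noise with clipping was
chosen over a logit-normal model because it keeps the null analytically
tractable: with baselines held inside [0.2, 0.8] (10 noise sd from the
boundary) clipping never fires, the twin difference is N(0, 2σ²), and the
expected exceedance fraction has the closed form 2·Φ(−0.1/(σ√2)) — the
independent oracle used for null calibration. A green calibration test
therefore establishes correctness of the pipeline's counting and
thresholding under the stated noise model, not fidelity to real-array
artefact structure.

## Numerical choices

* Tie detection in DMP ranking: 12-decimal rounding (above).
* Exact WMW switches to the tie-corrected normal approximation on any tie in
  the pooled sample, or when n₁+n₂ > 13; the all-identical corner returns
  P = 1.
* Degenerate paired-t variance is detected at `sqrt(.Machine$double.eps)`
  relative to max(|mean|, 1).
* Group medians are computed by a vectorised row-sort (a single `order()`
  call), keeping the 473k-probe scale run on one CPU inside minutes.
* VMP planting picks the shift sign uniformly among directions that stay in
  [0, 1] (both are feasible for baselines in [0.3, 0.7]), so zero-noise
  recovery is exact by construction.

## Known limitations

* The rank-score mapping is documented as a choice, not asserted as
  identical to any published implementation.
* Validation tests each probe marginally; no joint inference over the top-k
  list is attempted, and selection (ranking then testing the selected
  probes) makes the per-probe validation slightly anti-conservative under
  the null — the calibration test bounds this empirically at the study's
  group sizes, where the discreteness of the exact WMW compensates.
* The enrichment module is a stand-in; its results are not comparable to
  network-based pathway output.
* Published headline counts from undeposited cohort data (top-10 tables,
  group-exclusive VMP counts, data-set-wide exceedance percentages) are not
  reproduction targets; every quantitative claim in this package is
  established by its own tests and oracles.
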