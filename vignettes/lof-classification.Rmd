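---
title: "Classifying loss-of-function tumor phenotypes from expression data"
author: "lofscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying loss-of-function tumor phenotypes from expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofscape)
```

# The model

A tumor can silence a transcription-factor program without mutating the
factor: epigenetic loss, loss of a cofactor (for HNF1A, the H3K27me3
demethylase KDM6A), or regulatory rewiring all produce the same functional
end state. The observable consequence is coordinated downregulation of the
factor's direct target genes. `lofscape` formalizes this as a per-sample
statistical test and couples it to the regulatory-genomics evidence layer
(binding, chromatin, motifs) and a protein-level readout (tissue-microarray
scoring).

## Per-sample ranking

For sample $s$ and gene $g$ with linear-scale expression $x_{gs}$,

$$r_{gs} = \log_2 \frac{x_{gs} + c}{\operatorname{median}_t(x_{gt}) + c},$$

with pseudocount $c = 1$ by default. The median profile is the cohort
reference; a sample that equals it ranks every gene at zero. The
pseudocount choice is the package's own (the log base and offset of
per-tumor rankings are rarely reported); $c = 1$ keeps zero counts finite
and barely perturbs genes expressed above a few counts. Score ties are
broken by gene identifier, ascending, so ranked lists are total orders and
every downstream statistic is deterministic.

## Weighted running-sum enrichment

Given the ranked list $r_{(1)} \ge \dots \ge r_{(N)}$ and a gene set $S$
with $k = |S \cap \text{list}|$, the running sum gains
$|r_{(i)}|^w / \sum_{j \in S} |r_{(j)}|^w$ at members and loses $1/(N-k)$
at non-members; the enrichment score (ES) is the signed extremum of this
walk and always lies in $[-1, 1]$. The default $w = 1$ is the "weighted"
scoring scheme; $w = 0$ recovers the classic Kolmogorov–Smirnov-like
statistic, for which the walk ends exactly at zero. When every member of a
set carries a zero score the hit weights degenerate; the implementation
falls back to equal weights rather than dividing by zero. If the positive
and negative extrema tie in absolute value, the positive one is reported —
an arbitrary but fixed convention, relevant only on adversarial inputs.

The leading edge is the set members at or before a positive extremum, or
strictly after a negative one (the trough of a downward walk always sits
at a non-member position, so the members that climb back toward zero are
the depleted core).

## Permutation null, NES, and p

Because the input is a single sample's ranked list, only a gene-tag null
is available: `n_perm` uniformly random subsets of size $k$ are scored on
the same list. The normalized enrichment score divides ES by the mean
absolute value of same-sign null draws, and the nominal p-value is the
same-sign tail with add-one smoothing, $p = (b+1)/(m+1)$ — never exactly
zero, with floor $1/(m+1)$. If no same-sign draw exists (possible only for
tiny `n_perm`), the NES is reported as 0 with $p = 1$. The reference
permutation depth is 10,000 with the weighted scheme; per-sample
classification in the examples and tests uses 500–1,000 permutations,
which bounds the attainable p at 1/501–1/1001, comfortably below the 0.05
decision threshold.

For multi-set runs, FDR q-values use the sign-stratified pooled-NES rule:
null ES values of all sets are normalized to null NES, pooled per sign,
and the q-value at an observed NES is the null tail fraction divided by
the observed tail fraction, clipped to $[0,1]$ and monotonized so a weaker
score never receives a smaller q. Per-set permutation streams are seeded
by the set's rank in name order, so results are invariant to the order in
which gene sets are supplied.

## The three-way classification

A sample is **LoF** when $\mathrm{NES} < 0$ and $p < \alpha$ (default
$\alpha = 0.05$), **Control1** when $\mathrm{NES} < 0$ with $p \ge \alpha$,
and **Control2** when $\mathrm{NES} \ge 0$. Two boundary conventions are
ours: a NES of exactly zero falls in Control2, and $p = \alpha$ falls in
Control1 (the non-rejecting class); the published rule covers only strict
inequalities. Under a null cohort the LoF label requires both a negative
NES (probability about one half) and a sub-$\alpha$ p within the negative
stratum, so the expected false-LoF rate is near $\alpha/2$.

Per-sample permutation seeds derive from the sample identifier's rank
among sorted identifiers, making cohort classification invariant to
column order.

# Statistical layer

Exact and asymptotic primitives delegate to the standard R implementations
behind a stable surface: Fisher's exact test (two-sided by the
probability-mass rule), Benjamini–Hochberg adjustment, Kruskal–Wallis with
tie correction, Mann–Whitney (exact by enumeration when both groups have
at most eight untied observations), Pearson chi-square without continuity
correction, and the upper-tail binomial. Odds ratios are reported as the
sample cross-product $ad/bc$ — with a flagged Haldane 0.5 correction on
zero cells — rather than the conditional maximum-likelihood estimate, so
printed ratios match hand arithmetic on the table. Note that BH
adjustment is not idempotent: re-adjusting adjusted values inflates
non-maximal entries, which is why the test suite checks the step-up
formula directly rather than a reapplication identity.

# Regulatory integration

Coordinates follow the BED convention (0-based, half-open) in files and
the `GRanges` convention internally; conversion happens only at I/O.
"Within 1 kb of a TSS" is measured from the peak edge (interval-to-point
gap $\le$ 1,000; 0 means overlap) — peak-summit distance would be a
defensible alternative, but edge distance needs no summit column and is
what `bedtools closest` measures. Closest-gene assignment resolves exact
distance ties by leftmost gene start, then gene identifier; the
implementation builds its candidate set from overlaps plus nearest
neighbors on each side because `GenomicRanges::nearest()` alone does not
surface all distance ties.

Signal aggregation centers a $\pm$`flank` window on each region midpoint
(`floor((start + end)/2)` in 0-based terms), divides it into 10-bp bins,
and averages the track per bin. Bins extending past the covered extent of
a chromosome are zero-filled and flagged rather than dropped, keeping the
region-by-bin matrix rectangular. Track fold changes rescale both tracks
to a common total before the log ratio, so a global scaling of either
track cancels exactly.

Differential binding between two conditions is deliberately simple: pooled
per-condition counts, a two-sided exact binomial test of each region's
condition-A fraction against the global library-size fraction, and BH
adjustment. This is an intentionally transparent statistic with calibrated
behavior on balanced counts; it does not model biological overdispersion
across replicates, and regions with zero counts in both conditions are
excluded with a flag.

# Motif scanning

Position frequency matrices (JASPAR text layout) are normalized to
probabilities; log-odds scores use the PWM's background with probabilities
floored at $10^{-4}$ before the log. A hit requires at least 80% of the
maximal attainable log-odds score by default — thresholds of this kind are
tool-specific conventions, so the fraction is exposed as a parameter.
Both strands of the central $\pm$250 bp of each region are scanned;
positions containing `N` can never contribute a hit, and sequences shorter
than the motif are skipped with a flag. Enrichment is the one-tailed
binomial upper tail of the motif-bearing region count against a background
probability, supplied directly or estimated by scanning background
regions; the "union" coverage is the fraction of regions hit by at least
one of several motifs.

# Immunoreactive scoring

The published proportion bins overlap at exactly 50% ("10–50%" and
"50–80%"); 50 is assigned to the lower bin. Values in the printed 9–10%
gap fall in the 1–9% bin (category 1), reading the bins as contiguous
half-open intervals. Case-level means of per-core IRS values can be
non-integer, so grouping uses the continuous extension of the printed
integer bins: $[0,2)$ negative, $[2,4)$ weak, $[4,9)$ moderate, $[9,12]$
strong. The grade association uses plain Pearson chi-square (no Yates
correction), dropping undetermined-grade (Gx) cases and zero-margin
columns (flagged).

# What the generators emulate — and what they do not

`gen_cohort` draws per-gene baselines uniformly on 3–8 log2 units, adds
i.i.d. Gaussian log2 noise (sd 0.5), and downshifts the planted gene set
by `effect_log2` in exactly `round(lof_fraction * n_samples)` samples;
mutation status follows a 19%-vs-2% penetrance/background split, the
association strength reported for the cohort this emulates. The defaults
(120 samples, 2,000 genes, 100-gene set, 1 log2 effect) describe a
mid-sized consortium cohort. Real tumor data differ in ways the generator
deliberately omits: correlated gene-gene noise, tumor purity gradients,
library-size and batch effects, heavy-tailed counts, and partial (rather
than all-or-none) pathway loss. Passing the recovery tests therefore
demonstrates that the statistical machinery is correct and calibrated
under its stated model, not that real cohorts will separate this cleanly.

`gen_regulatory_landscape` places TSSs on a jittered grid (so promoters
never collide), puts a configurable fraction of active peaks within 1 kb
of a TSS and the rest 1.5–2 kb away, and binds one TF peak near the TSS of
each bound gene so closest-gene assignment provably recovers the intended
target. Downregulation probabilities for bound and unbound genes are
solved numerically so the bound-vs-down odds ratio and the overall down
fraction match their configured values in expectation. Coverage tracks
are sparse by design — 10-bp steps within $\pm$2 kb of peak centers, zero
elsewhere — with the A track doubled (or halved) at functional regions.

`gen_motif_sequences` draws background bases i.i.d. from the PWM's
background and plants instances sampled column-wise from the PWM (not the
fixed consensus), so planted sites have realistic strength variation; at
the default 0.8 score threshold roughly half of sampled instances score
as hits, which is why scanner sensitivity is asserted against the planted
truth at a permissive threshold and detection-rate tests use the truth
sets directly. `gen_tma_cases` gives each case a latent staining level
(Normal(1.5, 0.8)) shifted by `grade_effect` for G3 cases, rounds with
core-level noise into the 0–3 intensity scale, and lets percent-positive
track intensity; about 2% of cases are graded Gx.

All generators restore the caller's RNG state and are byte-reproducible
for a fixed seed.

# Problem sizes and numerical choices

The test suite and acceptance checks run at deliberately chosen desk
scales: cohort recovery at 120 samples with 1,000 permutations per sample,
null calibration at 200 samples with 500 permutations, odds-ratio recovery
over 100 landscape replicates of 1,000 genes, permutation-versus-
enumeration agreement at $N = 8$ with 50,000 draws, and exhaustive Fisher
enumeration over all 2-by-2 tables with total at most 30. These sizes give
stable pass/fail behavior at conventional tolerances (sensitivity and
specificity at least 0.9; sampled p within 0.02 of the enumerated value;
confidence-interval coverage at least 90/100) while keeping a full run in
the minutes range on one core.

# Known limitations

- The gene-tag permutation null ignores inter-gene correlation; on real
  data its nominal p-values are anti-conservative relative to a
  sample-permutation null, which single-sample input cannot provide.
- The differential-binding surrogate has no overdispersion model and
  should not be used as a drop-in replacement for replicate-aware
  negative-binomial methods on real ChIP-seq.
- Motif scanning implements fixed-threshold log-odds hits and a binomial
  region test; it does not optimize the central-window statistic of
  dedicated motif-enrichment tools.
- Probe collapsing keeps the highest-variance probe, which is simple and
  reproducible but can prefer noisy probes on arrays with few samples.
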