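---
title: "Kinetics of poly(A) tails and mRNA decay: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of poly(A) tails and mRNA decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padk)
```

## The question and the models

A long-standing view of cytoplasmic mRNA decay in yeast holds that
deadenylation is the committed, rate-limiting first step: the poly(A) tail is
shortened until an oligoadenylated species is recognized and decapped, after
which the body of the message is degraded 5′→3′. If that were the whole
story, unstable mRNAs should be found with short tails at steady state. Yet
large-scale measurements repeatedly find the opposite: short average tails on
the most *stable* messages.

`padk` packages the quantitative machinery needed to examine this tension. An
mRNA population is coarse-grained into three poly(A) species — long (`PAl`),
medium (`PAm`) and short (`PAs`) — and two mass-action wirings are compared:

* **serial** (deadenylation-dependent): production `P` feeds `PAl`;
  deadenylation moves molecules down the cascade at rate `kA`
  (`PAl → PAm → PAs`); only `PAs` is decapped/degraded, at rate `kD`:

  $$\frac{d\,\mathrm{PAl}}{dt} = P - k_A\,\mathrm{PAl},\qquad
    \frac{d\,\mathrm{PAm}}{dt} = k_A\,\mathrm{PAl} - k_A\,\mathrm{PAm},\qquad
    \frac{d\,\mathrm{PAs}}{dt} = k_A\,\mathrm{PAm} - k_D\,\mathrm{PAs}.$$

* **parallel** (deadenylation-independent): the same cascade, but *every*
  species is additionally degraded at `kD`, so decapping is uncoupled from
  tail length.

Both are linear, so chases (production switched off) have closed forms and
the steady states are algebraic. Serial:
$(P/k_A,\,P/k_A,\,P/k_D)$ — long/medium levels depend only on deadenylation,
short-tail accumulation only on decapping. Parallel:
$\bigl(\tfrac{P}{k_A+k_D},\,\tfrac{P k_A}{(k_A+k_D)^2},\,
\tfrac{P k_A^2}{k_D (k_A+k_D)^2}\bigr)$.

Assumptions worth keeping in mind: first-order (pseudo-first-order) kinetics
for every step; exactly three tail classes (a deliberate coarse-graining, not
a claim about tail-length resolution); a single constant `P` absorbing all
upstream events (synthesis, processing, export — two constants appear
multiplied in finer formulations and are not separately identifiable, so they
are collapsed); and no feedback of decay products on production.

With representative tail lengths of 70, 40 and 10 nucleotides
(`tail_profile()`), the abundance-weighted steady-state mean tail follows
from the fixed point. A factor-25 scan of both rates makes the central point
quantitative:

```{r}
grid_scan("serial")
```

Along the fast-decapping row (`kD = 0.5`), slowing deadenylation 25-fold
*lengthens* half-life (≈5 → ≈115 min) while mean tails stay in a narrow 46–55
nt band; whereas slowing decapping at fixed `kA` lengthens half-life (≈5 →
≈10 → ≈36 min) and *shortens* tails (46 → 30 → 16 nt). The inverse
tail/stability relationship seen transcriptome-wide therefore needs either
strong `kD` variation in the serial wiring, or the parallel wiring — in both
cases decapping, not deadenylation speed, is the discriminating rate.

## Two half-life estimators, on purpose

`half_life_crossing()` reports the time at which the chase total falls to
half its initial value — unambiguous, estimator-free, found by bracketed root
search on the analytic solution (bracket doubled from `2(2/k_A + 1/k_D)`
until a sign change; tolerance 1e-9 min).

`half_life_expfit()` instead samples the chase on a grid, normalizes to
`t = 0` and fits a single exponential — the way bench chase data are usually
processed. For the serial model the chase total is *not* a single
exponential (the cascade produces a shoulder), so this estimate is
window-dependent and differs from the crossing by up to ~15% at the default
rate grid. Neither is "the" half-life of a shouldered curve; published
whole-minute figures for such simulations are consistent with the fitted
estimator on some grids and with the crossing on others. Both are exported,
and the crossing is used wherever a single number is needed because it does
not depend on a sampling grid.

A useful exact fact: in the parallel model the transfer terms cancel in the
sum, so the chase total is *exactly* `total(0)·exp(-kD·t)` and the half-life
is `ln 2 / kD` for any `kA` — deadenylation redistributes molecules among
tail classes without touching bulk stability.

## Decay fitting: lag model, gates, intervals

`fit_exponential()`/`fit_lag_exponential()` fit `A₀·e^{-k(t-l)}` by
Levenberg–Marquardt least squares, with `k` initialized from a log-linear
regression and `A₀` free (initialized at 1). The guard that the reported SSE
never exceeds the concentrated initialization makes the fit deterministic
and monotone. Choices the data do not dictate:

* **Before the lag** (`t < l`) the model value is held at `A₀`: the lag
  represents the delay between a transcription shut-off and its effect on
  the measured pool, during which the level is unchanged. The `t = 0` point
  then anchors the normalization. The default lag of 1.2 min is the
  wild-type reporter estimate and is applied uniformly across conditions.
* **Half-life** is `ln 2 / k + l`, so the lag is part of the reported
  survival time.
* **Weights**: none. Series are normalized to `t = 0` before fitting (both
  reporter fractions and conversion rates are ratios to their own `t = 0`).
* **Failure is data**: non-convergence or `k ≤ 0` yields a flagged record
  (`fit_failed`), kept for audit and excluded downstream, never an error in
  batch mode.

Confidence intervals on `k` invert the profile-*t* statistic: for each
candidate `k` the amplitude is concentrated out analytically,
`τ(k) = \mathrm{sign}(k-\hat k)\sqrt{(SSE(k)-SSE_{\min})/s^2}` is compared
with the Student quantile, and the two crossings are found by root search.
This mirrors the profiling behind `confint` on `nls` objects; when profiling
fails a Wald interval is substituted and the method is recorded in the fit.
On noiseless data the interval collapses to a point. The goodness-of-fit
measure is the pseudo-R², `1 − SS_{res}/SS_{tot}` on the normalized values,
which can be negative for fits worse than the mean.

## The SLAM-seq pipeline

`slam_pipeline()` takes a per-observation conversion table (transcript ×
sample × time, with read counts and T→C conversion rates, the shape produced
by standard SLAM-seq quantifiers) and applies, in order: a ≥20-read gate and
a ≥1e-4 conversion-rate gate per observation; exclusion of any series that
loses its `t = 0` observation; normalization to 1 at `t = 0`; per-series
exponential fits; and a pseudo-R² > 0.8 quality gate. Half-life is
`ln 2 / k` with no lag and no correction for growth dilution of the labeled
pool. Interpretation choices: the read gate acts per observation because the
table is per-sample (dropping a whole transcript is reserved for the loss of
its anchor point); the conversion gate applies to raw, pre-normalization
rates; replicates are fitted separately and combined on the log2 scale.
Condition effects (`slam_compare_conditions()`) are
`mean log₂(half-life) − mean log₂(half-life over control runs)`, the natural
scale for fold-stabilization.

## RIP-seq enrichment and category tests

`compute_enrichment()` follows the classical input-normalized recipe:
drop features with <10 reads in any used sample (which also floors the log2
away from zero counts — no pseudocounts are ever added), divide by library
totals, log2, average replicates per condition, subtract the input
condition, and finally center each feature by its median across
purifications. The centered value asks "which purification is this feature
*most* associated with?"; the uncentered value is the plain IP-vs-input
log2 ratio, and is the right surface for single-purification designs (where
centering is degenerate and yields zeros) and for comparison with qPCR-style
`raw_enrichment()` per-replicate ratios. `category_test()` compares two
feature classes per purification with a Welch two-sample t-test and reports
each group's median and quartiles. Note that with fraction-based
normalization a planted enrichment of one feature class necessarily
depresses the apparent enrichment of the rest (compositional closure), so
effect recovery on synthetic data is measured as the difference between
group means.

## Poly(A) tail summaries and comparisons

`qc_filter()` keeps only reads whose length estimate carries the caller's
`PASS` tag. `summarize_transcripts()` requires ≥20 reads in *each* of ≥2
replicates (the conservative reading of a two-replicate threshold), computes
per-replicate medians, and reports their mean as the transcript statistic —
replicates, not reads, are the experimental unit — alongside the pooled-read
median for reference. Condition comparisons use the paired Wilcoxon
signed-rank test with continuity correction on matched transcripts; zero
differences are dropped (standard signed-rank convention) and counted, and
an all-zero comparison reports `p = 1`. `delta_correlation()` relates
changes in tail length to changes in log2 level with Pearson's r and a
Fisher-z interval (`atanh` scale, SE `1/√(n−3)`).

## What the synthetic data emulate — and what they do not

The generators exist so that every consumer stage can be exercised offline
with known ground truth. Noise families are the minimal standard choices for
each data type's support: lognormal multiplicative noise (mean 1, given CV)
for chase abundances; Poisson read counts with binomial conversion sampling
for SLAM tables (default 100 reads per observation, 25 convertible T
positions per read, 5% conversion at `t = 0` — typical of 4-thiouracil
labeling); multinomial species assignment from the kinetic steady state with
truncated-normal tail lengths (SDs 5/5/3 nt) for per-read poly(A) tables;
and negative-binomial counts over lognormal feature abundances (dispersion
0.05, library sizes varying ±30%) for RIP-seq matrices. All generators are
byte-deterministic under a fixed seed and restore the caller's RNG state.

They do **not** emulate: alignment or base-calling artifacts, SNP-driven
conversion miscalls, transcript-length or GC biases, batch effects,
replicate-correlated noise, or growth dilution of labels. Passing recovery
tests on these inputs therefore demonstrates the correctness and calibration
of the estimators under their own assumptions, not robustness to every
failure mode of real libraries.

Two quantitative limits surfaced by the recovery suite are worth stating.
First, CI coverage for reporter-style fits is nominal (≈95% observed over
200 simulated series at CV 0.1). Second, SLAM half-life precision is
intrinsically depth- and window-limited: with ~2500 convertible positions
per observation and a 30-min chase, transcripts whose half-life approaches
or exceeds the window cannot be pinned to 15% relative accuracy — the
overall within-15% fraction across half-lives of 4–60 min falls short of
90%, with essentially all misses above ~20 min, and the R² > 0.8 gate
screens such series only partially. Estimates are unbiased (median
relative error within a few percent); the spread, not the center, is the
limitation. Longer chases or deeper sequencing, not a different estimator,
are the remedy.

## Numerical choices

* ODE integration (`numeric_chase()`): `lsoda` with `rtol = 1e-9`,
  `atol = 1e-12` — rate ratios up to 25× in the default grids, and far
  beyond in limit checks, warrant a stiff-capable method.
* Analytic/numeric agreement is measured relative to the *initial* total.
  Late in a chase the parallel total decays like `e^{-k_D t}` regardless of
  `kA`, reaching magnitudes below any solver's absolute tolerance within the
  comparison window; pointwise ratios there compare roundoff with roundoff.
* The serial closed form switches to the repeated-eigenvalue
  (polynomial × exponential) branch when `kA = kD` rather than perturbing a
  rate: exactness beats a perturbation's spurious 1/(kD−kA) cancellation.
* Root searches use `uniroot` to 1e-9 min (crossing) and `khat`-scaled
  tolerances (profile CI); profile brackets grow/shrink geometrically until
  the t-statistic brackets the quantile.
* Degenerate inputs are first-class: zero-total states make `mean_tail()`
  signal explicitly; constant series are flagged, not fitted; empty filter
  results warn and return empty tables with full audit counts.

## Problem sizes in the test suite

The suite checks solver agreement on 50 random rate draws per model
(including the repeated-eigenvalue case), CI coverage and null-calibration
on 200 seeded simulations each, SLAM recovery on 200 transcripts, and
direction-of-effect comparisons on 50-transcript two-replicate nanopore-style
datasets — sizes chosen so each stochastic check has enough resolution to
detect miscalibration while the whole suite stays fast.

## Known limitations

* Three tail classes cannot represent continuous tail-length dynamics or
  terminal oligo-uridylation; the mean tail is bounded by the assigned
  species lengths by construction.
* The kinetic models are not fitted to experimental datasets here; the
  package simulates and estimates, it does not infer `kA`/`kD` from data.
* The lag model's plateau before `l` is a convention; data sampled densely
  inside the lag could distinguish alternatives, typical reporter designs do
  not.
* The Wilcoxon comparison assumes transcripts are exchangeable pairs;
  strongly expression-dependent tail effects would call for a stratified
  analysis that is out of scope.
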