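# padk — poly(A) tail kinetics and mRNA decay estimation

`padk` is an R package for researchers studying cytoplasmic mRNA turnover —
specifically the question of whether decapping (and hence degradation) is
rate-limited by prior deadenylation of the poly(A) tail, or proceeds
independently of it.

## The models

An mRNA population is coarse-grained into three poly(A) species — long
(PA<sub>l</sub>), medium (PA<sub>m</sub>), short (PA<sub>s</sub>) — produced
at rate *P* and connected by a deadenylation cascade with rate constant
*k<sub>A</sub>* and a decapping/degradation constant *k<sub>D</sub>*
(both min⁻¹):

**serial** (deadenylation-dependent — only short-tailed RNA is degraded):

    dPAl/dt = P − kA·PAl
    dPAm/dt = kA·PAl − kA·PAm
    dPAs/dt = kA·PAm − kD·PAs

**parallel** (deadenylation-independent — every species can be decapped):
the same cascade with an extra −kD·PAx term in each equation.

Both systems are linear: `padk` provides their steady states in closed form,
exact chase trajectories (production off) including the repeated-eigenvalue
case k<sub>A</sub> = k<sub>D</sub>, a stiff numerical integrator as an
independent oracle, abundance-weighted mean tail lengths (species tails
70/40/10 nt by default), and two half-life estimators: the 50%-crossing time
of the chase total and a single-exponential fit to the sampled curve (the
way bench data are processed — window-dependent, on purpose).

Around the models sit the estimation pipelines used in this field:

* **decay fitting** — (lag-)exponential nonlinear least squares with
  profile-likelihood 95% CIs on the decay constant, pseudo-R², and
  half-life `ln2/k + l` (default lag 1.2 min);
* **SLAM-seq** — half-lives from T→C conversion tables with ≥20-read and
  ≥1e-4 conversion gates, t₀ normalization, pseudo-R² > 0.8 quality gate,
  and log2 comparison against a multi-run control baseline;
* **RIP-seq** — input-normalized log2 enrichment (≥10-read filter, library
  normalization, replicate averaging, input subtraction, per-feature median
  centering), per-replicate raw enrichment, and Welch tests between feature
  categories;
* **poly(A) tail statistics** — nanopore-style per-read tables: PASS-tag QC
  filter, per-transcript replicate medians with a ≥20-reads-in-each-of-two-
  replicates rule, paired Wilcoxon condition comparisons, and Pearson
  correlations with Fisher-z CIs;
* **synthetic data** — seeded generators with known ground truth for every
  pipeline input (chase curves, conversion tables, per-read tail tables,
  count matrices).

## Worked example

Scan the default factor-25 rate grid for the serial model:

```r
library(padk)
grid_scan("serial")
#  model_kind kA_per_min kD_per_min half_life_min mean_tail_nt
#      serial       0.25       0.50         5.411        46.00
#      serial       0.05       0.50        23.537        52.86
#      serial       0.01       0.50       115.170        54.55
#      serial       0.25       0.10         9.824        30.00
#      serial       0.05       0.10        27.053        46.00
#      serial       0.01       0.10       117.686        52.86
#      serial       0.25       0.02        35.574        16.21
#      serial       0.05       0.02        49.119        30.00
#      serial       0.01       0.02       135.265        46.00
```

Read the first column block: at fast decapping (k_D = 0.5), slowing
deadenylation 25-fold stretches the half-life from ~5 to ~115 min while the
mean tail barely moves (46 → 55 nt). Slowing decapping instead (k_D 0.5 →
0.1 → 0.02 at k_A = 0.25) lengthens half-life from ~5 to ~10 to ~36 min
while *shortening* tails 46 → 30 → 16 nt. Only decapping-rate variation
reproduces the anti-correlation between tail length and stability seen
transcriptome-wide.

The two half-life estimators differ on shouldered serial chases:

```r
spec <- model_spec("serial", kA = 0.05, kD = 0.5)
half_life_crossing(spec)                      # 23.54 min
half_life_expfit(spec, seq(0, 60, by = 2))    # 21.43 min
```

Recover half-lives from a synthetic SLAM-seq chase (three transcripts,
100-read depth, times 0–30 min):

```r
tbl  <- gen_slam(c(ADA2 = 6, SRO9 = 11, PIR1 = 25),
                 times = seq(0, 30, 5), depth = 100, seed = 7)
slam_pipeline(tbl)$fits[, c("transcript_id", "half_life", "pseudo_r2",
                            "k_ci_low", "k_ci_high", "status")]
#  transcript_id half_life pseudo_r2 k_ci_low k_ci_high status
#           ADA2     6.576    0.9886  0.08811   0.12598     ok
#           PIR1    23.634    0.9712  0.02333   0.03557     ok
#           SRO9    12.336    0.9514  0.04034   0.07475     ok
```

Each row is one fitted chase: `half_life` in minutes (`ln2/k`), the 95%
profile-likelihood interval on `k` (min⁻¹), and the pseudo-R² quality gate
(> 0.8 required for `ok` status). The planted truths (6, 11, 25 min) are
recovered within counting noise.

See `vignette("polya-decay-kinetics")` for the models, estimator
definitions, and all design decisions.

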