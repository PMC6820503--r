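---
title: "Donor-aware analysis of mass cytometry data with cytoboot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor-aware analysis of mass cytometry data with cytoboot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoboot)
```

## The problem

Mass cytometry (CyTOF) measures ~40 protein markers on hundreds of
thousands of single cells per blood sample. In a typical immune-profiling
study — here, NK cells from control, pregnant and post-partum women, the
last two being the same donors sampled twice — the scientific unit is the
*donor*, but the data arrive as *cells*. Cells from one donor are strongly
correlated: a model that treats them as independent will report absurdly
narrow confidence intervals and flood the marker list with false
positives.

`cytoboot` implements a donor-aware workflow around that problem:

1. read/write per-cell data (FCS 3.0/3.1 or delimited text),
2. arcsinh-transform raw intensities,
3. gate live NK cells with declarative boolean thresholds and split
   CD56^dim^ / CD56^bright^ subsets,
4. fit a cell-level logistic regression in which standardized marker
   expressions jointly predict donor condition, with a donor-stratified
   cluster bootstrap supplying the confidence intervals,
5. summarise donors by median profiles and run Fisher LDA across the
   three groups,
6. compare gated frequencies with exact Mann-Whitney / Wilcoxon
   signed-rank tests,

plus a synthetic-study generator with known ground truth, which is how the
whole pipeline is tested.

## The core model

For a contrast (reference, comparison) — say control vs pregnant — each
cell contributes one Bernoulli observation:

$$\operatorname{logit} P(\text{donor is in comparison group}) =
  \beta_0 + \sum_m \beta_m z_m,$$

where $z_m$ is the cell's arcsinh-transformed expression of marker $m$,
standardized to mean 0, sd 1 over all cells in the contrast. $\beta_m$ is
therefore a log-odds per 1 SD of expression, comparable across markers on
a single forest plot; positive values mean the marker predicts the
comparison state. The direction of regression is deliberately flipped
relative to the causal picture — condition is the outcome, expression the
predictor — because it lets all markers be modelled jointly in one GLM.

Maximization is Newton–Raphson with step-halving, converged at max
gradient $<10^{-8}$ or 100 iterations. Complete and quasi-complete
separation deserve care here: along a separating direction the gradient
vanishes while the coefficient diverges, so convergence alone is not
evidence of a finite MLE. A fit whose slope passes ±15 (log-odds per SD;
$e^{15}$-fold odds per SD cannot arise from overlapping data) is flagged
`separated` and its last iterate retained rather than reported as an
estimate.

### Why a donor bootstrap

The cell-level likelihood ignores the donor hierarchy, so the point
estimates are fine but the curvature-based standard errors are not.
Uncertainty instead comes from resampling *donors with replacement*,
stratified by group with group sizes preserved, reassembling all retained
cells of each sampled donor (duplicated donors enter as distinct
clusters), and refitting. For the paired pregnant/post-partum contrast
the pregnant–post-partum pair is the resampling unit, preserving the
within-woman correlation. The 95% interval is the percentile interval of
the bootstrap coefficient distribution — the simplest interval consistent
with the "bar does not cross zero" significance reading, and robust to
skew. A marker is *significant* when its interval excludes zero; no
multiplicity correction is applied beyond that per-marker rule, a
deliberate mirror of the descriptive convention in this field and a
documented limitation.

Three design choices worth stating explicitly:

* **Standardize once.** Scaling is computed on the full assembled
  contrast data and reused in every bootstrap refit, so all resampled
  coefficients live on one scale. Re-standardizing inside each resample
  would conflate scale jitter with sampling variability.
* **Balance donors first.** By default every donor is downsampled
  (without replacement, seeded) to the smallest donor cell count, so a
  donor with 10× the cells cannot dominate the likelihood. This is
  configurable (`cells_per_donor = Inf` keeps everything).
* **Separated resamples are excluded and counted**, surfacing in
  `n_failed_resamples`; an analysis with > 20% failures aborts with
  advice rather than returning a quietly biased interval. For the *point*
  estimate only, a separated full-data fit is rerun with a tiny ridge
  (10⁻⁶ on slopes, never the intercept) to report something finite,
  still flagged.

Seeds expand deterministically: one model seed yields the subsampling
stream plus one stream per resample, so results are reproducible and
label-swap antisymmetry (reversing the contrast exactly negates every
estimate and reflects every interval) holds at the same seed.

## LDA on donor medians

The discriminant analysis runs on one row per donor-sample — the median
arcsinh expression of each marker over the donor's gated subset — not on
cells. Donors are the independent units; cell-level LDA would
pseudo-replicate by the thousands. Axes are eigenvectors of
$(S_W + \lambda I)^{-1} S_B$ via a symmetric whitening decomposition,
unit-norm, sign-fixed so the largest-magnitude loading is positive; at
most (groups − 1) axes. Marker contributions are axis coefficients scaled
by pooled within-class sd, and `rank_markers()` orders by their absolute
value (alphabetical tie-break) — the "markers that best separate the
groups" reading. Shrinkage defaults to 0 when donors outnumber markers
and to $10^{-3}\,\mathrm{tr}(S_W)/p$ otherwise, since wide validation
panels sit near singularity. Whether the original analyses of such
studies run LDA on cells or donor summaries is typically unstated; the
donor-median unit here is this package's own documented choice.

## Gating

Manual gating is replaced by declarative static thresholds on the arcsinh
scale: a gate tree is an ordered list of named populations, each a
conjunction of (marker, threshold, above/below) terms, evaluated
first-match so terminal populations are disjoint by construction. The NK
definition is the classical exclusion chain
CD3⁻CD19⁻CD20⁻CD14⁻CD56⁺ among viability-low events; the
CD56^dim^/CD56^bright^ split uses two CD56 thresholds with a CD16
conjunction (bright: CD56 > hi and CD16 ≤ thr; dim: lo < CD56 ≤ hi and
CD16 > thr; boundaries resolved by those ≤/> conventions). Thresholds are
configuration, never claimed to match any particular study's manual
gates; the defaults are tuned to the synthetic generator's bimodal
CD56/CD16 geometry. If a cohort's panel lacks an exclusion marker (panels
differ between cohorts in practice), the gate degrades gracefully with a
warning rather than failing.

Per-donor frequencies (e.g. % CD38⁺NKp46⁺ of CD56^dim^ NK cells) count
cells above all thresholds of a conjunction; donors with empty
denominators are kept as flagged rows, never silently dropped.

## Group comparisons

Frequencies are compared with the classical nonparametric pair: exact
Mann-Whitney U for unpaired contrasts, Wilcoxon signed-rank on within-pair
differences for pregnant vs post-partum. Exactness is by full enumeration
— all $\binom{n_1+n_2}{n_1}$ labelings (feasible to total $n \le 12$ with
ties, $\le 20$ tie-free) and all $2^n$ sign patterns ($n \le 15$) — with
midranks for ties, zero differences discarded (the classical, not the
Pratt, convention), two-sided p doubling the smaller tail capped at 1.
Beyond the crossover the normal approximation applies tie-corrected
variance and a 0.5 continuity correction; the suite checks the two
branches agree within 0.02 at the crossover. Stars follow the usual
convention (\*: p < 0.05, \*\*: p < 0.01, \*\*\*: p < 0.001).

## The synthetic generator

`simulate_study()` emulates the structure the analyses assume — it is the
test bed, not a model of any particular dataset. Latent expression on
the arcsinh scale is

$$y = \mu_m + \text{offset}_{pm} + \delta_m \cdot
  \mathbb{1}[\text{pregnant}] + u_{dm} + \varepsilon,\qquad
  u_{dm}\sim N(0,\tau_m^2),\ \varepsilon\sim N(0,\sigma_m^2),$$

with the donor effect $u_{dm}$ shared across a donor's cells and reused
in her paired post-partum sample (cell noise redrawn; post-partum
condition effects default to zero). Raw values are
$\text{cofactor}\cdot\sinh(\max(y,0))$ — the floor is a deliberate
truncation guaranteeing nonnegative raw intensities while keeping
arcsinh∘generate approximately Normal away from zero — and each value is
a structural zero with probability $\pi_m$, emulating non-expressing
cells. Populations (NK_dim, NK_bright, T, B, monocyte, dead) mix with
configured fractions; default offsets make CD56/CD16 bimodal exactly so
the dim/bright thresholds are exercised, and a cisplatin-like viability
channel separates dead cells by 8 pooled sds so threshold gating is
near-perfect. One study seed expands hierarchically (study → donor →
cell), so partial regeneration is stable.

Defaults are chosen to look like a realistic pregnancy cohort: 21 donors
per group (a typical discovery-cohort size), 1000 cells per donor-sample
after gating-level downsampling, σ = 0.4, τ = 0.15, π = 0.05 on receptor
channels (0 on gating channels, so gates behave deterministically), and
condition effects concentrated on CD38 (both NK subsets), NKp46 (dim
only) and a negative CXCR3 shift.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: spillover and acquisition drift, doublets,
batch effects between cohorts, heavy-tailed or multimodal receptor
distributions beyond the zero-inflated Normal, and any dependence between
markers within a cell beyond population structure. The Normal-on-arcsinh
model is an assumption of convenience, flagged as such.

## Numerical and sizing choices

* Logistic convergence 10⁻⁸ on the max gradient; separation threshold
  ±15 on standardized slopes; bootstrap failure budget 20%.
* Percentile intervals use the default (type 7) empirical quantile.
* Median uses the midpoint convention for even counts.
* LDA ties and signs are fixed (alphabetical; largest loading positive)
  so plots are reproducible run to run.
* The calibration and recovery simulations in the test suite use 50
  replicate studies of 10+10 donors × 1000 cells × 10 markers with
  n_boot = 200, and the end-to-end recovery uses 20 replicates of a
  21-donor-per-group cohort — sizes chosen to make Monte-Carlo error
  small relative to the properties asserted while keeping the suite
  quick to run; the acceptance script reports the same quantities at
  somewhat smaller replicate counts, with each `n` recorded alongside.

Under those null conditions the donor bootstrap's empirical rate of 95%
intervals excluding zero sits near 7–10% rather than 5% — the familiar
small-cluster anti-conservativeness of the percentile cluster bootstrap
with 10 donors per group. It shrinks as donors grow; with cohort-scale
donor counts (≥ 20 per group) recovery of true effects is essentially
certain at δ ≈ 0.5 SD while false flags stay near the nominal rate.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = sim_config(n_donors_per_group = 10, cells_per_donor = 1000,
                          seed = 1),
  n_boot = 200, seed = 1, outdir = "run1")
run <- run_pipeline(cfg)

run$effects$effects_NK_dim_control_vs_pregnant   # forest-plot table
autoplot(run$effects$effects_NK_dim_control_vs_pregnant)
autoplot(run$lda$dim)
run$comparisons                                   # MW / Wilcoxon + stars
```

Every artifact lands in `outdir` as plain CSV/YAML with an md5 manifest;
re-running the same config and seed reproduces every checksum.

## Known limitations

* Inference is purely the per-marker CI-excludes-zero rule; no joint or
  multiplicity-adjusted error control.
* No mixed-effects (random-intercept GLMM) alternative; the bootstrap is
  the only accounting for donor heterogeneity.
* Gates are static thresholds; no density-based or automated gating.
* FCS support covers list-mode float/double/integer datasets and the
  channel/event keywords only — no spillover matrices, no keyword
  preservation beyond what round trips need.
* Cohorts are analysed separately; no harmonization across panels.
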