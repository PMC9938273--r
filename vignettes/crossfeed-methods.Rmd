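---
title: "Methods: single-cell growth dynamics in a cross-feeding community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell growth dynamics in a cross-feeding community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeed)
```

# The measurement problem

In a mother-machine experiment fed by a live batch culture, single cells in
dead-end microfluidic channels experience the same changing chemical
environment as the community in the feeding flask — here a chitin-degrading
*Vibrio* and an *Alteromonas* cross-feeder that grows on excreted by-products
such as acetate — but cannot themselves change it. Imaging every 5 minutes
for ~40 hours yields, after segmentation and tracking (out of scope here),
per-frame cell lengths organised into lineages: each cell id runs from birth
to division, the mother line is followed indefinitely, and daughters wash
out of the open channel end.

`crossfeed` covers everything downstream of tracking: estimating
instantaneous single-cell elongation rates from the length trajectories,
aggregating them into channel-level biomass, testing how the mono- versus
co-culture feeding environment changes growth over time, and quantifying
growth-rate heterogeneity late in the growth season. Because the pipeline's
statistical behaviour must be testable without microscopy data, the package
also ships a generative model of the whole experiment.

# Elongation-rate estimation

Cell length grows exponentially, `L(t) = L(0) e^{r t}`, with `r` (1/h)
varying over the season from ~0.9 to 0. The estimator must work both for
large fast-growing and for small non-growing cells, with multiplicative
segmentation noise. The procedure, per cell (`estimate_growth_rates()`):

1. log-transform the lengths (natural log, since `r` is a continuous
   exponential rate);
2. smooth with robust local quadratic regression over a moving window of 60
   time points (5 h) — tricube nearest-neighbour weights, 5 rounds of
   bisquare reweighting with scale 6 times the median absolute residual,
   windows shrinking asymmetrically at the trajectory ends. This is the
   estimator behind MATLAB's `rloess`; the implementation delegates to
   `stats::loess(degree = 2, family = "symmetric", surface = "direct")`,
   which uses exactly these ingredients. Cells shorter than the window are
   fitted with all their points (a single robust quadratic), which is what
   nearest-neighbour spans degrade to;
3. estimate the instantaneous rate at each interior point as the ordinary
   least-squares slope of the smoothed log length over a centred 7-point
   (30 min) window; points without a full window carry no estimate;
4. remove points whose 7-point linear fit has a residual sum of squares
   `chi2 > 1e-4` (natural-log units squared). `chi2` is defined as the raw
   residual sum of squares: that is the simplest statistic on the `1e-4`
   scale for near-perfect fits of smoothed data, and the threshold is
   configurable precisely because the convention has alternatives (mean or
   reduced residuals).

Numerical choices worth recording: smoothing windows are index-based but the
regressions use actual times, so irregular sampling is tolerated; gaps
larger than 3 nominal frame intervals split a cell into independently
smoothed segments; times are centred per fit to keep the quadratic design
well conditioned late in the experiment; and when the plain local fit is
already exact to 1e-10 the robustness iterations are skipped, because the
bisquare scale collapses to zero on exact data. Slope windows are never
shrunk at the edges — an estimate is either computed from a full window or
not reported.

The estimator's contracts are tested: local quadratic smoothing reproduces
quadratics exactly; slopes and `chi2` match a brute-force normal-equations
solution to 1e-12; scaling all lengths by a constant changes nothing
(log-shift invariance); doubling the time stamps halves every rate.

# Channel biomass

Cells leave the channels constantly, so total produced biomass cannot be read
off the images. It is reconstructed from rates: with `<r_i>` the mean
QC-passing rate over the cells of a channel (or replicate) at frame `i` and
`dt` the frame interval,
`B_T = exp(dt * sum_{i<=T} <r_i>)`,
the fold biomass produced up to frame `T` (`B_0 = 1`). Using the mean rate
deliberately ignores between-cell variation. Frames where no cell passes QC
contribute zero to the sum — a conservative "no growth where nothing is
measurable" convention; their count is logged. The default grouping is the
individual mother machine (channel), matching how biomass accumulation is
usually reported per device; per-replicate grouping is one switch away, since
the averaging unit is genuinely ambiguous in practice. `log(B_T)` is exactly
`dt` times the running rate sum, which is also how condition contrasts on
biomass are computed (log scale keeps the response linear in the rates).

# Time-resolved condition contrasts

The interaction between the species is time-dependent, so rates are compared
within 20-hour phases (`[0,20)` and `[20,40)` by default; boundary times fall
in the right-hand bin). The unit of analysis follows the experimental
design: per-timepoint replicate mean rates (240 frames per phase per
replicate, so a 4-replicate design gives ~960 observations per condition and
phase, minus slope-window edges). Within each species and phase the model is

```
mean_rate ~ condition + (1 | replicate)
```

fitted by REML through `lmerTest`, with the experiment day as a random
intercept and a Satterthwaite p-value for the condition effect. The fit is
exercised against closed forms in the tests: with a zero replicate-variance
estimate it reduces to ordinary least squares to 1e-8, and in balanced
designs its variance components equal the classical ANOVA method-of-moments
estimators to 1e-6. Percent differences are reported as
`100 * difference / baseline mean` with the delta-method standard error
`100 * SE / baseline`, with the lower condition as baseline in each
direction. Welch's unequal-variance t-test (`welch_t()`) covers the
plate-assay comparisons; it is two-sided by default with one-sided options,
and adopts the `t = 0, p = 1` convention for two constant equal samples.

Per-timepoint means of an autocorrelated process are treated as independent
observations by this model — a simplification inherited from the analysis
design it reproduces; its p-values are therefore anti-conservative and the
package reports them as such rather than attempting a correction.

# Heterogeneity and bimodality

Within a late window (34–36 h by default) all QC-passing rates are pooled
per species and condition; `heterogeneity_summary()` reports the coefficient
of variation and sample variance. Near-zero mean rates make the cv
sign-ambiguous; rather than silently using the absolute mean the cv is
reported `NA` with a flag in that case.

Bimodality is quantified with Hartigan's dip statistic on one mean rate per
cell in the window: consecutive per-frame estimates of one cell are strongly
autocorrelated (the smoother ties them together), so pooling them would
violate the independence assumption of the Monte-Carlo null and can fake
multimodality out of per-cell clustering; one value per cell restores a
valid test. The dip itself is the smallest
sup-norm distance between the empirical CDF and any unimodal CDF (convex up
to its mode, concave after, nondecreasing, an atom at the mode allowed). No
installed package provides the dip, so it is implemented from the
definition: the mode can be placed at a data point without loss of
generality, and for each candidate mode the minimal band half-width splits
into two one-sided minimax convex/concave fitting problems solved by convex
hulls of the band mid-points, plus a monotonicity constraint across the mode
that is enforced by an active-line iteration when it binds. The two side
deviations are monotone in the mode index, so the optimum is found by binary
search and certified; the implementation agrees with an exhaustive
brute-force oracle (mode enumeration, triple-loop chord feasibility,
bisection) to 1e-10 on random small-sample suites, and with the closed forms
`D({0,1}) = 1/4` and `D = 1/(2n)` for equally spaced samples.

The dip's p-value is Monte Carlo: the add-one-corrected fraction of
`uniform(0,1)` samples of the same size whose dip reaches the observed value
(10,000 draws by default, seeded). The uniform is the standard calibration
null because the dip is invariant under strictly monotone transformations.
A Monte-Carlo null was chosen over interpolated critical-value tables for
reproducibility at arbitrary `n`.

# The synthetic community and lineage generator

The generator exists so that every statistical claim of the pipeline can be
exercised against known ground truth. It is fixture machinery that emulates
the experiment's qualitative dynamics; it is not a calibrated model of the
organisms.

**Batch environment** (`simulate_environment()`): a minimal Monod
consumer-resource system integrated with fixed-step RK4 at `dt = 0.01` h.
The degrader consumes a chitin oligomer (half-saturation 0.05 a.u.),
excretes a fraction (0.4) of its consumption as a single by-product standing
in for acetate, and — once chitin falls below 0.1% of its initial value and
a 3 h diauxic lag has passed — switches to consuming that by-product (hard
switch, chosen over smooth blending for testability). The cross-feeder
consumes the by-product continuously. Carbon is conserved exactly
(`C + A + D/yield_deg + F/yield_cf` is constant to integration precision),
chitin is non-increasing, and the co-culture by-product curve never exceeds
the mono-culture curve. Two phenomenological ingredients are needed to
reproduce the experiment's observed patterns:

* a stationary-phase cap on the batch degrader (Hill-type shutdown around
  0.45 a.u.): without it Monod uptake drives the by-product to zero well
  before the late observation window, whereas the measured mono-culture
  acetate stays high at 36 h while degrader growth still stops around 25 h.
  The cap produces both: a pronounced mono-culture secondary (diauxic)
  growth phase followed by arrest, with residual by-product left over;
* a facilitation factor (default 0.11) multiplying the primary-phase
  degrader forcing in co-culture runs, emulating the observed ~11% early
  growth advantage of degrader cells fed by a co-culture. The mechanism is
  not resolved by a single-metabolite model, so the boost is applied to the
  reported device-cell forcing only, leaving the batch carbon ledger
  identical across conditions (which is what keeps the by-product ordering
  invariant exact).

Defaults were tuned once, from the forward dynamics alone, to the
experiment's stated timeline: chitin exhaustion ~21.6 h, degrader growth
ceasing ~25–27 h, cross-feeder growth prolonged relative to the degrader.
One known limitation: with a single by-product and no production after
chitin exhaustion, co-culture cross-feeder growth ends ~27 h rather than
~40 h; the prolonged-growth ordering is reproduced, the absolute endpoint is
not.

**Lineages** (`simulate_channel()`, `generate_study()`): the mother cell
grows as `dL/dt = s * r_true(t) * L` with a per-cell lognormal rate
multiplier (`sd` 0.15), where `r_true` interpolates the environment's
realized species growth rate. Division is a threshold rule ("sizer", 4 µm
with 10% lognormal noise) — chosen over an adder for analytic transparency —
and symmetric: at the division frame the cell id ends and two children start
at the next frame with exactly half the true length each. One child
continues as the mother line; the other is a daughter, censored after 10
frames (washout). Observed length is true length times per-frame lognormal
noise (`cv` 0.05, the segmentation-noise scale used throughout the tests).
A true per-frame rate sidecar is recorded for every cell so downstream
recovery error is directly measurable. `generate_study()` assembles the
full 2 (conditions) x 2 (species) x 4 (replicates) x 12 (channels) design
and applies a lognormal per-replicate scaling (`sd` 0.05) of the forcing as
the "day" random effect.

Late-season bimodality is injected, not emergent: in the
cross-feeder-on-mono-culture arm each cell present after 30 h draws a slow
mode (rate multiplier 0.05) with probability 0.5, else stays fast. This is a
fixture for testing the dip machinery against a known two-mode truth, not a
biological model of dormancy.

What passing tests on these data do and do not show: the generator produces
exponential growth with multiplicative noise, drawn from smooth forcing
functions — real segmentation errors (merged cells, missed divisions,
pixel-level bias), asymmetric division, and cell death are absent, so the
pipeline's robustness to those failure modes is only partially probed (the
robust smoother's outlier resistance is tested directly instead).

# Problem sizes and determinism

The default synthetic study (4 replicates x 2 conditions x 2 species x 12
channels, 481 frames) yields roughly 140k observation rows from ~7000 cells,
and is the size used by the end-to-end tests and the acceptance script; the
heterogeneity windows pool 1000–2500 rate estimates (50–90 cells) per arm,
and dip p-values use 10,000 null draws. Every stochastic step takes an explicit
seed, and identical configurations reproduce byte-identical tables.

# Session info

```{r}
sessionInfo()
```
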