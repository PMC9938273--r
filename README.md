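# crossfeed

Single-cell growth dynamics in cross-feeding microbial communities, measured
in mother-machine microfluidics fed by a changing batch-culture environment.

## The problem

A chitin-degrading bacterium and a cross-feeder that lives on its excreted
by-products (such as acetate) interact through the environment they share:
early on the cross-feeder can help the degrader, later both compete for the
same leftover metabolites. To resolve *when* the interaction flips sign, a
mother-machine device is fed from a batch culture containing either the
degrader alone or the full community, and single cells are imaged every
5 minutes for ~40 h. The raw product of segmentation and tracking is a
lineage table: one row per cell per frame with a length in µm.

`crossfeed` is the analysis layer for such data:

* **Elongation rates** — cell length grows as `L(t) = L(0)·e^{rt}`; the
  instantaneous rate `r(t)` (h⁻¹) is estimated per cell by natural-log
  transform, robust local quadratic smoothing over 60 frames (5 h; tricube
  weights with bisquare reweighting, the `rloess` estimator), then
  least-squares slopes over sliding 7-frame (30 min) windows. Windows whose
  linear fit has residual sum of squares `χ² > 10⁻⁴` are removed.
* **Biomass** — cells wash out of the channels, so produced biomass is
  reconstructed from rates: `B_T = exp(Δt · Σ_{i≤T} ⟨r_i⟩)` with `⟨r_i⟩`
  the mean passing rate in a channel at frame `i` and `Δt = 1/12` h.
* **Condition contrasts** — per-timepoint replicate mean rates, binned into
  20-h phases, compared between mono- and co-culture feeding with the
  random-intercept model `rate ~ condition + (1 | replicate)` (REML,
  Satterthwaite p-values), plus percent differences with delta-method SEs;
  Welch t-tests for plate-assay comparisons.
* **Heterogeneity** — cv and variance of pooled late-window rates, and
  Hartigan's dip test for bimodality (exact dip statistic, implemented here
  from the definition, with a seeded Monte-Carlo uniform null).
* **Synthetic data** — a Monod consumer–resource simulator of the feeding
  batch culture (primary chitin phase, by-product secretion, diauxic reuptake
  in mono-culture, continuous cross-feeder consumption in co-culture) and a
  lineage simulator with division, mother retention, daughter washout and
  multiplicative measurement noise, recording true rates for ground-truth
  validation.
* **Assay arithmetic** — chitinase activity in Units/ml from plate
  fluorescence and acetate-per-OD normalisation.

## A worked example

Simulate a small study (2 replicates, 6 channels per arm), estimate rates,
and test the phase-by-condition interaction:

```r
library(crossfeed)

params  <- environment_params()
mono    <- simulate_environment(params, include_crossfeeder = FALSE)
co      <- simulate_environment(params, include_crossfeeder = TRUE)
study   <- generate_study(mono, co, lineage_params(n_channels = 6),
                          n_replicates = 2, seed = 42)
rates   <- estimate_growth_rates(study)
effects <- phase_rate_effects(rates, c(0, 20, 40))
effects[, c("species", "phase", "difference", "std_error", "p_value")]
```

```
# A tibble: 4 × 5
  species     phase   difference std_error  p_value
  <chr>       <chr>        <dbl>     <dbl>    <dbl>
1 crossfeeder [0,20)    -0.00404   0.00402 3.15e- 1
2 crossfeeder [20,40)   -0.151     0.00714 1.12e-81
3 degrader    [0,20)     0.0143    0.0206  4.87e- 1
4 degrader    [20,40)   -0.0201    0.00689 3.67e- 3
```

`difference` is co-culture minus mono-culture (h⁻¹). The cross-feeder's
second-phase contrast is strongly negative: only mono-culture leftovers let
it keep growing late, because in co-culture its own batch population has
exhausted the by-product pool. The degrader's secondary (diauxic) phase is
likewise a mono-culture phenomenon (negative late contrast); its early
facilitation by the cross-feeder is positive as expected but not yet
significant at this toy size — the default 4-replicate, 12-channel study
resolves it clearly.

Late-window bimodality of the cross-feeder on mono-culture:

```r
cells <- cell_mean_rates(rates, c(34, 36), by = c("species", "condition"))
v <- cells$mean_r[cells$species == "crossfeeder" & cells$condition == "mono"]
dip_test(v, n_null_draws = 2000, seed = 1)
```

```
# A tibble: 1 × 4
      D p_value     n n_null_draws
  <dbl>   <dbl> <int>        <int>
1 0.127 0.00400    20         2000
```

The slow/fast split injected after 30 h in this arm is picked up as a
significant dip even from 20 cells; the full-size study pushes the p-value
to the Monte-Carlo floor.

A command-line front end with subcommands `simulate`, `estimate`, `biomass`,
`compare`, `heterogeneity`, `assays` and `run` is installed at
`inst/cli/crossfeed.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/crossfeed.R", package = "crossfeed"))')" \
    run --seed 1 --output-dir out/
```

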