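test_that("phase binning uses half-open intervals with boundary to the right", {
  d <- tibble::tibble(time = c(0, 10, 19.999, 20, 30, 39.999, 40, -1))
  binned <- bin_phases(d, c(0, 20, 40))
  expect_identical(as.character(binned$phase),
                   c("[0,20)", "[0,20)", "[0,20)", "[20,40)", "[20,40)",
                     "[20,40)"))
  expect_identical(attr(binned, "dropped"), 2L)  # t = 40 and t = -1
  expect_error(bin_phases(d, c(0, 0, 40)), "increasing")
})

test_that("phase group sizes on the default study approach the design size", {
  rates <- default_rates()
  mr <- mean_rate_per_timepoint(rates, "replicate")
  binned <- bin_phases(mr, c(0, 20, 40))
  counts <- table(binned$species, binned$condition, binned$phase)
  # 4 replicates x 240 frames = 960 per group, minus slope-window edge frames
  expect_true(all(counts >= 940 & counts <= 970))
})

test_that("identical conditions give a zero contrast", {
  y <- rep(c(1, 2, 3, 4), times = 4)
  cond <- rep(c("a", "b"), each = 8)
  repl <- rep(rep(c("r1", "r2"), each = 4), 2)
  eff <- fit_random_intercept(y, cond, repl)
  expect_equal(eff$difference, 0, tolerance = 1e-10)
})

test_that("with zero replicate variance the mixed model reduces to OLS", {
  set.seed(1)
  # replicate means constructed identical: variance component estimated 0
  base <- rnorm(20)
  y <- c(base, base + 0.5)
  cond <- rep(c("a", "b"), each = 20)
  repl <- rep(rep(c("r1", "r2"), each = 10), 2)
  eff <- fit_random_intercept(y, cond, repl)
  ols <- summary(stats::lm(y ~ cond))$coefficients
  expect_true(eff$singular)
  expect_equal(eff$difference, ols[2, 1], tolerance = 1e-8)
  expect_equal(eff$std_error, ols[2, 2], tolerance = 1e-8)
})

test_that("balanced-design REML matches the ANOVA closed form", {
  # deterministic balanced two-way layout: 4 replicates x 2 conditions x 3 obs
  reps <- paste0("r", 1:4)
  conds <- c("a", "b")
  m <- 3
  rep_eff <- c(-0.6, -0.1, 0.2, 0.5)
  cond_eff <- c(a = 0, b = 0.8)
  noise <- c( 0.12, -0.08,  0.03, -0.21,  0.17,  0.05,
              0.02, -0.14,  0.09,  0.11, -0.19,  0.07,
             -0.05,  0.16, -0.11,  0.20, -0.02, -0.09,
              0.04,  0.13, -0.17, -0.03,  0.08,  0.01)
  d <- expand.grid(obs = 1:m, condition = conds, replicate = reps,
                   stringsAsFactors = FALSE)
  d$y <- 2 + cond_eff[d$condition] + rep_eff[match(d$replicate, reps)] + noise
  eff <- fit_random_intercept(d$y, d$condition, d$replicate)

  # ANOVA estimators: in a balanced design they coincide with REML
  fit <- stats::lm(y ~ condition + replicate, data = d)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  rep_means <- tapply(d$y, d$replicate, mean)
  ms_rep <- length(conds) * m * stats::var(rep_means)
  sigma_rep2 <- (ms_rep - mse) / (length(conds) * m)
  expect_equal(eff$var_residual, mse, tolerance = 1e-6)
  expect_equal(eff$var_replicate, sigma_rep2, tolerance = 1e-6)
  cell_means <- tapply(d$y, d$condition, mean)
  expect_equal(eff$difference, unname(cell_means["b"] - cell_means["a"]),
               tolerance = 1e-6)
})

test_that("the mixed model covers a known injected effect", {
  # scaled-down calibration: 200 simulated balanced 4-replicate designs
  set.seed(7)
  hits <- 0L
  n_sim <- 200L
  for (s in seq_len(n_sim)) {
    rep_eff <- rnorm(4, 0, 0.3)
    d <- expand.grid(obs = 1:10, condition = c("a", "b"),
                     replicate = paste0("r", 1:4), stringsAsFactors = FALSE)
    d$y <- 1 + 0.4 * (d$condition == "b") +
      rep_eff[match(d$replicate, paste0("r", 1:4))] + rnorm(nrow(d), 0, 0.5)
    eff <- suppressMessages(
      fit_random_intercept(d$y, d$condition, d$replicate)
    )
    if (abs(eff$difference - 0.4) <= 2 * eff$std_error) hits <- hits + 1L
  }
  # nominal 2-SE coverage is ~95%; with 200 draws the observed rate carries
  # binomial noise (sd ~1.5%), so allow 2 such deviations below nominal
  expect_gte(hits / n_sim, 0.92)
})

test_that("percent differences scale correctly and guard the baseline", {
  pd <- percent_difference(0.09, 0.021, 0.81)
  expect_equal(pd$percent, 100 * 0.09 / 0.81, tolerance = 1e-12)
  expect_equal(pd$percent_se, 100 * 0.021 / 0.81, tolerance = 1e-12)
  expect_equal(percent_difference(0, 0.01, 0.5)$percent, 0)
  expect_equal(percent_difference(0.2, 0.05, 0.4)$percent,
               percent_difference(0.4, 0.1, 0.8)$percent)
  expect_error(percent_difference(0.1, 0.01, 0), "baseline")
})

test_that("welch_t matches the direct formula and is antisymmetric", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  w <- welch_t(a, b)
  se2 <- stats::var(a) / 4 + stats::var(b) / 4
  t_direct <- (mean(a) - mean(b)) / sqrt(se2)
  df_direct <- se2^2 /
    ((stats::var(a) / 4)^2 / 3 + (stats::var(b) / 4)^2 / 3)
  expect_equal(w$t, t_direct, tolerance = 1e-12)
  expect_equal(w$df, df_direct, tolerance = 1e-12)
  w2 <- welch_t(b, a)
  expect_equal(w2$t, -w$t, tolerance = 1e-12)
  expect_equal(w2$p_value, w$p_value, tolerance = 1e-12)
  # identical samples: the t = 0 convention
  wz <- welch_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(wz$t, 0)
  expect_equal(wz$p_value, 1)
  wi <- welch_t(c(1, 1, 1), c(2, 2, 2))
  expect_true(wi$infinite_t)
  # one-sided option
  wg <- welch_t(b, a, alternative = "greater")
  expect_lt(wg$p_value, welch_t(b, a)$p_value)
})

test_that("heterogeneity summaries match hand arithmetic and flag sign issues", {
  rates <- tibble::tibble(
    cell_id = "a", frame = 1:2, time = c(34.5, 35.5),
    r = c(0.1, 0.3), chi2 = 0, pass_qc = TRUE
  )
  h <- heterogeneity_summary(rates, c(34, 36))
  expect_equal(h$var, 0.02, tolerance = 1e-12)
  expect_equal(h$cv, sqrt(0.02) / 0.2, tolerance = 1e-12)
  expect_identical(h$n, 2L)

  const <- rates
  const$r <- c(0.5, 0.5)
  hc <- heterogeneity_summary(const, c(34, 36))
  expect_equal(hc$cv, 0)
  expect_equal(hc$var, 0)

  neg <- rates
  neg$r <- c(-0.2, -0.1)
  hn <- heterogeneity_summary(neg, c(34, 36))
  expect_true(is.na(hn$cv))
  expect_identical(hn$cv_flag, "non-positive mean")
  expect_error(heterogeneity_summary(rates, c(10, 12)), "window")
})
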