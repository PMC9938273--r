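cfg <- smoothing_config()

test_that("local quadratic smoothing reproduces quadratics and constants", {
  t <- seq(0, 10, by = 1 / 12)
  y <- 0.5 + 0.2 * t - 0.01 * t^2
  expect_lt(max(abs(smooth_log_length(t, exp(y), cfg) - y)), 1e-10)
  expect_lt(max(abs(smooth_log_length(t, rep(2, length(t)), cfg) - log(2))),
            1e-10)
})

test_that("robust smoothing resists a displaced point better than non-robust", {
  t <- seq(0, 10, by = 1 / 12)
  y <- 0.1 * t
  y[60] <- y[60] + 1
  dev_robust <- max(abs(smooth_log_length(t, exp(y), cfg) - 0.1 * t))
  dev_plain <- max(abs(
    smooth_log_length(t, exp(y), smoothing_config(robust_iterations = 0)) -
      0.1 * t
  ))
  expect_lt(dev_robust, dev_plain)
  expect_lt(dev_robust, 1e-6)
})

test_that("smoothing rejects invalid input", {
  expect_error(smooth_log_length(1:5, c(1, 2, -1, 2, 1), cfg), "row 3")
  expect_error(smooth_log_length(1:2, c(1, 2), cfg), "too short")
  expect_error(smooth_log_length(c(1, 1, 2), c(1, 2, 3), cfg), "increasing")
})

test_that("sliding slopes recover exact lines with zero chi-squared", {
  t <- seq(0, 10, by = 1 / 12)
  sl <- sliding_slopes(t, 0.5 * t + 1, cfg)
  expect_lt(max(abs(sl$r - 0.5), na.rm = TRUE), 1e-12)
  expect_lt(max(sl$chi2, na.rm = TRUE), 1e-24)
  slc <- sliding_slopes(t, rep(2, length(t)), cfg)
  expect_lt(max(abs(slc$r), na.rm = TRUE), 1e-12)
  # edges carry no estimate
  expect_true(all(is.na(sl$r[1:3])) && all(is.na(sl$r[length(t) - 0:2])))
})

test_that("sliding slopes match the normal-equations oracle", {
  # the worked 7-point series
  tt <- (0:6) / 12
  vv <- c(0, .05, .10, .15, .20, .25, .35)
  X <- cbind(1, tt)
  beta <- solve(t(X) %*% X, t(X) %*% vv)
  rss <- sum((vv - X %*% beta)^2)
  sl <- sliding_slopes(tt, vv, cfg)
  expect_equal(sl$r[4], beta[2], tolerance = 1e-12)
  expect_equal(sl$chi2[4], rss, tolerance = 1e-12)

  # 100 seeded random series vs the same oracle at every interior window
  set.seed(2024)
  for (k in 1:100) {
    n <- sample(7:100, 1)
    t <- cumsum(runif(n, 0.5, 1.5)) / 12
    y <- cumsum(rnorm(n, 0.02, 0.05))
    sl <- sliding_slopes(t, y, cfg)
    centers <- seq(4L, n - 3L)
    for (i in centers[sample.int(length(centers), min(5, length(centers)))]) {
      idx <- (i - 3):(i + 3)
      X <- cbind(1, t[idx])
      beta <- solve(t(X) %*% X, t(X) %*% y[idx])
      expect_lt(abs(sl$r[i] - beta[2]), 1e-12)
      expect_lt(abs(sl$chi2[i] - sum((y[idx] - X %*% beta)^2)), 1e-12)
    }
  }
})

test_that("the chi-squared filter applies the documented threshold", {
  flags <- apply_qc(c(0.5, 0.5, 0.5, NA), c(2e-4, 1e-4, 0, 1),
                    smoothing_config(chi2_threshold = 1e-4))
  expect_identical(flags, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("length rescaling and time rescaling act as expected on estimates", {
  t <- seq(0, 10, by = 1 / 12)
  y <- exp(0.3 * t + 0.05 * sin(t))
  base <- sliding_slopes(t, smooth_log_length(t, y, cfg), cfg)
  scaled <- sliding_slopes(t, smooth_log_length(t, 3.7 * y, cfg), cfg)
  expect_equal(scaled$r, base$r, tolerance = 1e-10)
  expect_equal(scaled$chi2, base$chi2, tolerance = 1e-10)
  stretched <- sliding_slopes(2 * t, smooth_log_length(2 * t, y, cfg), cfg)
  expect_equal(stretched$r, base$r / 2, tolerance = 1e-10)
})

test_that("noiseless exponential cells are recovered near machine precision", {
  tab <- exponential_table(0.5)
  est <- estimate_growth_rates(tab, cfg)
  ok <- est$pass_qc
  expect_gt(sum(ok), 400)
  expect_lt(max(abs(est$r[ok] - 0.5)), 1e-6)
  expect_lt(max(est$chi2[ok]), 1e-12)
})

test_that("estimation is deterministic and skips too-short cells", {
  st <- small_study()
  sub <- as.data.frame(st)[st$channel_id %in% unique(st$channel_id)[1], ]
  a <- estimate_growth_rates(sub, cfg)
  b <- estimate_growth_rates(sub, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  short <- exponential_table(0.2, n_frames = 5L)
  expect_error(estimate_growth_rates(short, cfg), "slope window")
})

test_that("large gaps split cells into separately smoothed segments", {
  tab <- exponential_table(0.4, n_frames = 100L)
  # remove a 10-frame block in the middle
  tab <- tab[tab$frame < 45 | tab$frame > 55, ]
  est <- estimate_growth_rates(tab, cfg)
  # no estimate may bridge the gap: frames just after the gap are edges again
  after_gap <- est[est$frame %in% 56:58, ]
  expect_true(all(is.na(after_gap$r)))
  ok <- est$pass_qc
  expect_lt(max(abs(est$r[ok] - 0.4)), 1e-6)
})

test_that("rate recovery on the noisy small study is accurate", {
  st <- small_study()
  est <- estimate_growth_rates(st, cfg)
  tr <- attr(st, "truth")
  m <- dplyr::inner_join(
    tibble::as_tibble(est)[est$pass_qc, c("cell_id", "frame", "r")],
    tr[, c("cell_id", "frame", "r_true")],
    by = c("cell_id", "frame")
  )
  expect_gt(nrow(m), 1000)
  expect_lt(sqrt(mean((m$r - m$r_true)^2)), 0.05)
  # mid-exponential bias: degrader cells between 5 and 15 h
  lab <- dplyr::distinct(tibble::as_tibble(st)[, c("cell_id", "species")])
  mm <- dplyr::inner_join(m, lab, by = "cell_id")
  mm <- dplyr::inner_join(
    mm, dplyr::distinct(tibble::as_tibble(st)[, c("cell_id", "frame", "time")]),
    by = c("cell_id", "frame")
  )
  mid <- mm$species == "degrader" & mm$time > 5 & mm$time < 15
  expect_lt(abs(mean(mm$r[mid] - mm$r_true[mid])), 0.02)
})
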