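test_that("no resources means no growth for either species", {
  p <- environment_params(chitin_oligomer_0 = 0)
  env <- simulate_environment(p, include_crossfeeder = TRUE)
  expect_true(all(env$r_deg == 0))
  expect_true(all(env$r_cf == 0))
})

test_that("without secretion the cross-feeder never grows", {
  p <- environment_params(secretion_fraction = 0)
  env <- simulate_environment(p, include_crossfeeder = TRUE)
  expect_true(all(env$r_cf == 0))
  expect_equal(env$crossfeeder_density,
               rep(p$crossfeeder_0, nrow(env)))
})

test_that("carbon is conserved and chitin never increases", {
  e <- test_environments()
  p <- e$params
  for (env in list(e$mono, e$co)) {
    total <- env$chitin + env$byproduct +
      env$degrader_density / p$yield_deg +
      env$crossfeeder_density / p$yield_cf
    expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
    expect_true(all(diff(env$chitin) <= 1e-12))
    expect_true(all(env$chitin >= 0 & env$byproduct >= 0))
    expect_true(all(env$r_deg >= 0 & env$r_cf >= 0))
  }
})

test_that("the cross-feeder keeps co-culture by-product below mono-culture", {
  e <- test_environments()
  expect_true(all(e$co$byproduct <= e$mono$byproduct + 1e-9))
})

test_that("the secondary growth phase is a mono-culture phenomenon", {
  # late-window degrader growth must be larger when no cross-feeder consumed
  # the excreted by-product
  e <- test_environments()
  dt <- e$params$dt
  late_m <- e$mono$time_h >= 20
  late_c <- e$co$time_h >= 20
  int_mono <- sum(e$mono$r_deg[late_m]) * dt
  int_co <- sum(e$co$r_deg[late_c]) * dt
  expect_gt(int_mono, int_co)
})

test_that("forcing functions interpolate, clamp and stay non-negative", {
  e <- test_environments()
  env <- e$mono
  f <- growth_rate_forcing(env, "degrader")
  i <- c(5L, 100L, 2000L)
  expect_equal(f(env$time_h[i]), env$r_deg[i])
  # midway between grid nodes: linear interpolation
  mid <- (env$time_h[10] + env$time_h[11]) / 2
  expect_equal(f(mid), (env$r_deg[10] + env$r_deg[11]) / 2)
  # clamping beyond the simulated range
  expect_equal(f(max(env$time_h) + 1), env$r_deg[nrow(env)])
  expect_equal(f(-5), env$r_deg[1])
  expect_error(growth_rate_forcing(env, "plankton"), "arg")
})

test_that("parameter validation rejects bad inputs", {
  expect_error(environment_params(secretion_fraction = 1.2), "secretion")
  expect_error(environment_params(dt = 0), "dt")
  expect_error(environment_params(mu_max_deg = -1), "non-negative")
})

test_that("environment CSV round-trips", {
  e <- test_environments()
  path <- withr::local_tempfile(fileext = ".csv")
  write_environment(e$co, path)
  back <- read_environment(path)
  expect_equal(back$r_cf, e$co$r_cf, tolerance = 1e-12)
  expect_equal(back$byproduct, e$co$byproduct, tolerance = 1e-12)
})
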