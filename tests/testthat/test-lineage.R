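noiseless_params <- function(...) {
  lineage_params(length_noise_cv = 0, growth_noise_sd = 0, division_cv = 0, ...)
}

test_that("noise-free exponential growth gives exact per-frame log increments", {
  p <- noiseless_params(duration = 4)
  tab <- simulate_channel(function(t) rep(0.6, length(t)), p, seed = 7)
  one <- tab[tab$cell_id == tab$cell_id[1], ]
  expect_equal(diff(log(one$length)), rep(0.6 / 12, nrow(one) - 1),
               tolerance = 1e-12)
})

test_that("zero forcing yields a single non-dividing constant cell", {
  p <- noiseless_params(duration = 4)
  tab <- simulate_channel(function(t) rep(0, length(t)), p, seed = 7)
  expect_equal(nrow(attr(tab, "divisions")), 0L)
  expect_equal(length(unique(tab$cell_id)), 1L)
  expect_equal(length(unique(tab$length)), 1L)
})

test_that("division conserves true length and respects lineage ordering", {
  p <- noiseless_params(duration = 6)
  tab <- simulate_channel(function(t) rep(0.7, length(t)), p, seed = 3)
  div <- attr(tab, "divisions")
  expect_gt(nrow(div), 0)
  expect_equal(2 * div$child_length, div$pre_division_length, tolerance = 0)
  for (i in seq_len(nrow(div))) {
    children <- strsplit(div$children[i], ";")[[1]]
    parent_last <- max(tab$frame[tab$cell_id == div$parent_id[i]])
    child_first <- min(tab$frame[tab$cell_id %in% children])
    expect_identical(child_first, parent_last + 1L)
  }
})

test_that("channels are reproducible under the seed and vary across seeds", {
  p <- lineage_params(duration = 4)
  f <- function(t) rep(0.5, length(t))
  a <- simulate_channel(f, p, seed = 3)
  b <- simulate_channel(f, p, seed = 3)
  c2 <- simulate_channel(f, p, seed = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("daughters are censored after the retention window", {
  p <- noiseless_params(duration = 8, daughter_retention = 10L)
  tab <- simulate_channel(function(t) rep(0.5, length(t)), p, seed = 1)
  div <- attr(tab, "divisions")
  daughters <- vapply(strsplit(div$children, ";"), `[`, "", 2L)
  # daughters that never divide have at most retention frames
  div_parents <- unique(div$parent_id)
  for (d in setdiff(daughters, div_parents)) {
    expect_lte(sum(tab$cell_id == d), 10L)
  }
})

test_that("the study table covers the full factorial design", {
  st <- small_study()
  labs <- unique(as.data.frame(st)[c("replicate_id", "condition", "species")])
  expect_identical(nrow(labs), 2L * 2L * 2L)
  expect_identical(length(unique(st$channel_id)), 2L * 2L * 2L * 2L)
  # truth sidecar aligns with the table rows
  tr <- attr(st, "truth")
  expect_setequal(unique(tr$cell_id), unique(st$cell_id))
})

test_that("without replicate noise, replicate-level growth is exchangeable", {
  e <- test_environments()
  p0 <- lineage_params(n_channels = 4L, replicate_sd = 0,
                       length_noise_cv = 0, growth_noise_sd = 0,
                       division_cv = 0, bimodal_fraction = 0)
  st <- generate_study(e$mono, e$co, p0, n_replicates = 3L, seed = 9)
  tr <- attr(st, "truth")
  per_rep <- tapply(tr$r_true[tr$species == "degrader" & tr$condition == "mono"],
                    tr$replicate_id[tr$species == "degrader" & tr$condition == "mono"],
                    mean)
  # identical forcing and no per-cell noise: replicate means agree closely
  expect_lt(diff(range(per_rep)) / mean(per_rep), 0.02)
})

test_that("the bimodal arm shows two true-rate modes in the late window", {
  st <- small_study()
  tr <- attr(st, "truth")
  w <- tr$species == "crossfeeder" & tr$condition == "mono" &
    tr$frame >= 34 * 12 & tr$frame < 36 * 12
  v <- tr$r_true[w]
  slow <- v[v < 0.1]
  fast <- v[v >= 0.1]
  expect_gt(length(slow), 5)
  expect_gt(length(fast), 5)
  expect_gt(min(fast) / max(slow), 3)
})
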