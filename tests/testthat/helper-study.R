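# Shared simulation fixtures, built once per test run and cached.

.cf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cf_cache)) {
    assign(key, force(expr), envir = .cf_cache)
  }
  get(key, envir = .cf_cache)
}

test_environments <- function() {
  cached("envs", {
    p <- environment_params()
    list(
      params = p,
      mono = simulate_environment(p, include_crossfeeder = FALSE),
      co = simulate_environment(p, include_crossfeeder = TRUE)
    )
  })
}

# small study: 2 replicates x 2 channels, all four arms
small_study <- function() {
  cached("small_study", {
    e <- test_environments()
    generate_study(e$mono, e$co, lineage_params(n_channels = 2L),
                   n_replicates = 2L, seed = 42)
  })
}

# the full default synthetic study (4 replicates x 12 channels)
default_study <- function() {
  cached("default_study", {
    e <- test_environments()
    generate_study(e$mono, e$co, lineage_params(), n_replicates = 4L, seed = 1)
  })
}

default_rates <- function() {
  cached("default_rates", estimate_growth_rates(default_study()))
}

# a noiseless single-cell exponential trajectory table
exponential_table <- function(r, n_frames = 480L, l0 = 2) {
  t <- (seq_len(n_frames) - 1L) / 12
  tibble::tibble(
    replicate_id = "R1", condition = "mono", species = "degrader",
    channel_id = "C1", cell_id = "cell1", parent_id = NA_character_,
    frame = seq_len(n_frames) - 1L, time = t, length = l0 * exp(r * t)
  )
}
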