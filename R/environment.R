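#' Parameters of the feeding batch-culture environment
#'
#' Bundles the parameters of the consumer-resource model that emulates the
#' batch culture feeding the microfluidic device: a degrader consumes a chitin
#' oligomer (Monod kinetics), excretes a fraction of its consumption as a
#' metabolic by-product (standing in for acetate), and -- once the chitin is
#' exhausted and a diauxic lag has elapsed -- switches to consuming that
#' by-product. A cross-feeder, when present, consumes the by-product
#' continuously.
#'
#' Concentrations and densities are in arbitrary units (a.u.); rates in 1/h.
#'
#' @param chitin_oligomer_0 initial chitin-oligomer concentration (a.u.).
#' @param degrader_0,crossfeeder_0 initial species densities (a.u.).
#' @param mu_max_deg,mu_max_cf maximum specific growth rates (1/h).
#' @param K_chitin,K_byproduct Monod half-saturation constants (a.u.).
#' @param yield_deg,yield_cf biomass produced per unit resource consumed.
#' @param secretion_fraction fraction of the degrader's chitin consumption
#'   excreted as by-product, in `[0, 1]`.
#' @param diauxic_lag delay (h) between chitin exhaustion and the degrader
#'   switching to by-product consumption.
#' @param facilitation phenomenological facilitation of degrader cells by the
#'   cross-feeder: the primary-phase (chitin) term of the reported degrader
#'   forcing `r_deg` is multiplied by `(1 + facilitation)` in co-culture runs.
#'   It models the observed growth advantage of device cells fed by a
#'   co-culture without altering the batch carbon ledger, whose mechanism the
#'   model does not resolve.
#' @param degrader_capacity stationary-phase cap on the batch degrader biomass
#'   (a.u.); uptake scales with `1 - (D / degrader_capacity)^4`, a sharp
#'   Hill-type shutdown so growth stays near-maximal until the cap is
#'   approached. Use `Inf` to disable.
#' @param duration total simulated time (h).
#' @param dt integration step (h) of the fixed-step RK4 integrator.
#'
#' @return A list of class `"cf_env_params"`.
#' @seealso [simulate_environment()], [growth_rate_forcing()]
#' @export
environment_params <- function(chitin_oligomer_0 = 1,
                               degrader_0 = 1e-7,
                               crossfeeder_0 = 0.05,
                               mu_max_deg = 0.75,
                               mu_max_cf = 0.45,
                               K_chitin = 0.05,
                               K_byproduct = 0.1,
                               yield_deg = 0.5,
                               yield_cf = 0.5,
                               secretion_fraction = 0.4,
                               diauxic_lag = 3,
                               facilitation = 0.11,
                               degrader_capacity = 0.45,
                               duration = 40,
                               dt = 0.01) {
  p <- list(
    chitin_oligomer_0 = chitin_oligomer_0,
    degrader_0 = degrader_0,
    crossfeeder_0 = crossfeeder_0,
    mu_max_deg = mu_max_deg,
    mu_max_cf = mu_max_cf,
    K_chitin = K_chitin,
    K_byproduct = K_byproduct,
    yield_deg = yield_deg,
    yield_cf = yield_cf,
    secretion_fraction = secretion_fraction,
    diauxic_lag = diauxic_lag,
    facilitation = facilitation,
    degrader_capacity = degrader_capacity,
    duration = duration,
    dt = dt
  )
  validate_environment_params(p)
  structure(p, class = "cf_env_params")
}

validate_environment_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num)) {
    stop("all environment parameters must be scalar numerics", call. = FALSE)
  }
  nonneg <- c(
    "chitin_oligomer_0", "degrader_0", "crossfeeder_0", "mu_max_deg",
    "mu_max_cf", "K_chitin", "K_byproduct", "yield_deg", "yield_cf",
    "diauxic_lag", "facilitation"
  )
  bad <- nonneg[vapply(nonneg, function(f) p[[f]] < 0, logical(1))]
  if (length(bad)) {
    stop("environment parameters must be non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$secretion_fraction < 0 || p$secretion_fraction > 1) {
    stop("secretion_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (p$degrader_capacity <= 0) {
    stop("degrader_capacity must be positive (Inf to disable)", call. = FALSE)
  }
  if (p$dt <= 0 || p$dt > p$duration) {
    stop("dt must satisfy 0 < dt <= duration", call. = FALSE)
  }
  invisible(p)
}

# Derivatives of the consumer-resource state c(C, A, D, F).
# Of the degrader's chitin uptake, secretion_fraction is excreted as
# by-product and the rest assimilated with yield_deg, so the realized
# chitin-phase growth rate is mu_max_deg * monod * cap. switch_on gates the
# degrader's diauxic by-product uptake. Carbon ledger:
# C + A + D/yield_deg + F/yield_cf is conserved exactly.
cf_env_deriv <- function(state, p, switch_on, include_crossfeeder) {
  C <- state[1]; A <- state[2]; D <- state[3]; F <- state[4]
  cap <- if (is.finite(p$degrader_capacity)) {
    max(0, 1 - (D / p$degrader_capacity)^4)
  } else 1
  monod_C <- if (C > 0) C / (p$K_chitin + C) else 0
  up_C <- if ((1 - p$secretion_fraction) > 0) {
    p$mu_max_deg * monod_C * cap * D /
      (p$yield_deg * (1 - p$secretion_fraction))
  } else 0
  monod_A <- if (A > 0) A / (p$K_byproduct + A) else 0
  up_A_deg <- if (switch_on) {
    p$mu_max_deg * monod_A * cap * D / p$yield_deg
  } else 0
  up_A_cf <- if (include_crossfeeder) {
    p$mu_max_cf * monod_A * F / p$yield_cf
  } else 0
  s <- p$secretion_fraction
  c(
    C = -up_C,
    A = s * up_C - up_A_deg - up_A_cf,
    D = p$yield_deg * ((1 - s) * up_C + up_A_deg),
    F = p$yield_cf * up_A_cf
  )
}

#' Simulate the feeding batch-culture environment
#'
#' Forward-integrates the degrader / cross-feeder consumer-resource system
#' with a fixed-step fourth-order Runge-Kutta scheme and returns the resource,
#' density and realized per-capita growth-rate series on the integration grid.
#' The degrader's by-product (diauxic) uptake switches on once the chitin
#' concentration falls below `1e-3 * chitin_oligomer_0` and `diauxic_lag`
#' hours have elapsed since that crossing.
#'
#' The run is deterministic given `params`; `seed` is reserved for optional
#' parameter jitter and currently unused.
#'
#' @param params an [environment_params()] object.
#' @param include_crossfeeder simulate the co-culture (`TRUE`) or the degrader
#'   mono-culture (`FALSE`, cross-feeder density frozen at its inoculum).
#' @param seed reserved; unused.
#'
#' @return A tibble of class `"cf_env"` with columns `time_h`, `chitin`,
#'   `byproduct`, `degrader_density`, `crossfeeder_density`, `r_deg`, `r_cf`.
#'   `r_cf` is the growth rate a cross-feeder cell would realize in this
#'   environment; it is reported for mono-culture runs too, because
#'   cross-feeder channels in the device can be fed by a mono-culture batch.
#' @export
simulate_environment <- function(params, include_crossfeeder = TRUE,
                                 seed = NULL) {
  validate_environment_params(params)
  p <- params
  n_steps <- ceiling(p$duration / p$dt)
  times <- seq(0, by = p$dt, length.out = n_steps + 1L)

  state <- c(
    C = p$chitin_oligomer_0, A = 0,
    D = p$degrader_0, F = p$crossfeeder_0
  )
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 4L)
  out[1L, ] <- state
  chitin_threshold <- 1e-3 * p$chitin_oligomer_0
  crossing_time <- if (p$chitin_oligomer_0 <= 0) 0 else NA_real_

  for (k in seq_len(n_steps)) {
    t_k <- times[k]
    switch_on <- !is.na(crossing_time) && t_k >= crossing_time + p$diauxic_lag
    h <- p$dt
    k1 <- cf_env_deriv(state, p, switch_on, include_crossfeeder)
    k2 <- cf_env_deriv(state + h / 2 * k1, p, switch_on, include_crossfeeder)
    k3 <- cf_env_deriv(state + h / 2 * k2, p, switch_on, include_crossfeeder)
    k4 <- cf_env_deriv(state + h * k3, p, switch_on, include_crossfeeder)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    state <- pmax(state, 0)
    if (any(!is.finite(state))) {
      stop(sprintf(
        "environment integration produced non-finite state at t = %.3f h",
        times[k + 1L]
      ), call. = FALSE)
    }
    if (is.na(crossing_time) && state[1] < chitin_threshold) {
      crossing_time <- times[k + 1L]
    }
    out[k + 1L, ] <- state
  }

  C <- out[, 1]; A <- out[, 2]; D <- out[, 3]; F <- out[, 4]
  cap <- if (is.finite(p$degrader_capacity)) {
    pmax(0, 1 - (D / p$degrader_capacity)^4)
  } else rep(1, length(D))
  switch_vec <- !is.na(crossing_time) & times >= crossing_time + p$diauxic_lag
  boost <- if (include_crossfeeder && p$crossfeeder_0 > 0) {
    1 + p$facilitation
  } else 1
  r_deg <- p$mu_max_deg * cap *
    (boost * C / (p$K_chitin + C) +
       ifelse(switch_vec, A / (p$K_byproduct + A), 0))
  r_cf <- p$mu_max_cf * A / (p$K_byproduct + A)

  env <- tibble::tibble(
    time_h = times,
    chitin = C,
    byproduct = A,
    degrader_density = D,
    crossfeeder_density = F,
    r_deg = pmax(r_deg, 0),
    r_cf = pmax(r_cf, 0)
  )
  attr(env, "params") <- p
  attr(env, "include_crossfeeder") <- include_crossfeeder
  attr(env, "chitin_crossing_time") <- crossing_time
  class(env) <- c("cf_env", class(env))
  env
}

#' @export
print.cf_env <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<cf_env> %s, %.1f h at dt = %g h (%d points)\n",
    if (isTRUE(attr(x, "include_crossfeeder"))) "co-culture" else "mono-culture",
    max(x$time_h), p$dt, nrow(x)
  ))
  cross <- attr(x, "chitin_crossing_time")
  if (!is.na(cross)) cat(sprintf("  chitin exhausted at %.2f h\n", cross))
  NextMethod()
}

#' Growth-rate forcing function for one species
#'
#' Returns a function `r_true(t)` interpolating the realized growth-rate
#' series of the requested species linearly over the environment time grid,
#' clamped at the endpoints (queries outside the simulated range return the
#' boundary values) and truncated below at zero.
#'
#' @param env a `"cf_env"` trajectory from [simulate_environment()].
#' @param species `"degrader"` or `"crossfeeder"`.
#' @return A function of time (h) returning growth rates (1/h).
#' @export
growth_rate_forcing <- function(env, species = c("degrader", "crossfeeder")) {
  species <- match.arg(species)
  col <- if (species == "degrader") "r_deg" else "r_cf"
  f <- stats::approxfun(env$time_h, env[[col]], rule = 2)
  function(t) pmax(f(t), 0)
}

#' Write / read an environment trajectory as CSV
#'
#' @param env a `"cf_env"` tibble.
#' @param path file path.
#' @return `write_environment()` returns `env` invisibly; `read_environment()`
#'   returns a tibble with the environment columns.
#' @export
write_environment <- function(env, path) {
  readr::write_csv(as.data.frame(env), path)
  invisible(env)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  cols <- c("time_h", "chitin", "byproduct", "degrader_density",
            "crossfeeder_density", "r_deg", "r_cf")
  x <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop("environment CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x[cols]
}
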