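#' Hartigan's dip statistic
#'
#' Computes the dip of a sample: the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF (convex up to the mode, concave after,
#' nondecreasing). Large values indicate multimodality; for any sample of
#' size n, `1/(2n) <= D <= 0.25`.
#'
#' The minimisation is exact: modes are placed at data points (the optimal
#' unimodal CDF may carry an atom at its mode), each candidate mode is scored
#' by the minimax convex/concave band fit on its two sides via convex hulls,
#' and the monotonicity constraint across the mode is enforced by an
#' active-constraint iteration when it binds. Ties are handled by stable
#' sorting.
#'
#' @param x numeric sample, `length(x) >= 2`, finite.
#' @return The dip statistic `D` (dimensionless).
#' @examples
#' dip_statistic(c(0, 1))              # 0.25, the n = 2 upper bound
#' dip_statistic(seq(0, 1, by = 0.1))  # equally spaced: the 1/(2n) bound
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("dip requires at least 2 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("dip requires finite values", call. = FALSE)
  x <- sort(x)
  if (anyDuplicated(x)) {
    # stable-order limit: separate tied steps by a negligible increment
    scale <- max(diff(range(x)), 1)
    x <- x + seq_along(x) * (1e-10 * scale / length(x))
  }
  .dip_cpp(x)
}

#' Monte-Carlo p-value for the dip statistic
#'
#' Estimates `P(D >= d_obs)` under the uniform(0, 1) null by simulation:
#' `n_null_draws` samples of size `n` are drawn, and the add-one corrected
#' fraction `(k + 1) / (B + 1)` with dip at least `d_obs` is returned. The
#' dip is invariant under strictly monotone transformations, so the uniform
#' is the standard calibration null for the test.
#'
#' @param d_obs observed dip.
#' @param n sample size the dip was computed from.
#' @param n_null_draws number of null draws `B`.
#' @param seed integer seed for the null draws.
#' @return p-value in `(0, 1]`.
#' @export
dip_pvalue <- function(d_obs, n, n_null_draws = 10000L, seed = 1L) {
  stopifnot(n >= 2L, n_null_draws >= 1L, is.finite(d_obs))
  set.seed(as.integer(seed))
  k <- .dip_null_count_cpp(as.integer(n), as.integer(n_null_draws), d_obs)
  (k + 1) / (n_null_draws + 1)
}

#' Dip test for unimodality
#'
#' Convenience wrapper combining [dip_statistic()] and [dip_pvalue()].
#'
#' @param x numeric sample.
#' @param n_null_draws,seed passed to [dip_pvalue()].
#' @return A tibble with `D`, `p_value`, `n`, `n_null_draws`.
#' @export
dip_test <- function(x, n_null_draws = 10000L, seed = 1L) {
  d <- dip_statistic(x)
  tibble::tibble(
    D = d,
    p_value = dip_pvalue(d, length(x), n_null_draws, seed),
    n = length(x),
    n_null_draws = as.integer(n_null_draws)
  )
}

#' Growth-rate heterogeneity in a time window
#'
#' Pools all QC-passing instantaneous rates in a time window and summarises
#' their spread: coefficient of variation (sd / mean), sample variance
#' (n - 1 denominator) and count. When the mean is not positive the cv's
#' sign is ambiguous and it is flagged rather than silently reported.
#'
#' @param rates a `"cf_rates"` table from [estimate_growth_rates()].
#' @param window two-element numeric, time window in hours (closed left,
#'   open right).
#' @param by optional character vector of grouping columns (e.g.
#'   `c("species", "condition")`).
#' @return A tibble with `cv`, `var`, `n`, `window_start`, `window_end`,
#'   `cv_flag` (NA mean or sign-ambiguous), plus grouping columns.
#' @export
heterogeneity_summary <- function(rates, window = c(34, 36), by = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  sel <- rates$pass_qc & !is.na(rates$r) &
    rates$time >= window[1] & rates$time < window[2]
  d <- tibble::as_tibble(rates)[sel, , drop = FALSE]
  if (nrow(d) == 0L) stop("no QC-passing rates in the window", call. = FALSE)
  summarise_one <- function(v) {
    m <- mean(v)
    tibble::tibble(
      cv = if (m > 0) stats::sd(v) / m else NA_real_,
      var = stats::var(v),
      n = length(v),
      window_start = window[1], window_end = window[2],
      cv_flag = if (m > 0) NA_character_ else "non-positive mean"
    )
  }
  if (is.null(by)) {
    summarise_one(d$r)
  } else {
    d |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::reframe(summarise_one(.data$r))
  }
}


#' Per-cell mean rates in a time window
#'
#' Summarises each cell by the mean of its QC-passing instantaneous rates
#' inside a window. This is the recommended sample for the dip test: pooled
#' per-frame rates are strongly autocorrelated within a cell (the smoother
#' ties neighbouring frames together), which violates the independence
#' assumption of the Monte-Carlo null; one value per cell restores it.
#'
#' @param rates a `"cf_rates"` table.
#' @param window two-element time window (h), closed left, open right.
#' @param by optional character vector of grouping columns retained in the
#'   output (e.g. `c("species", "condition")`).
#' @return A tibble with one row per cell: grouping columns, `cell_id`,
#'   `mean_r`, `n_points`.
#' @export
cell_mean_rates <- function(rates, window = c(34, 36), by = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  sel <- rates$pass_qc & !is.na(rates$r) &
    rates$time >= window[1] & rates$time < window[2]
  d <- tibble::as_tibble(rates)[sel, , drop = FALSE]
  if (nrow(d) == 0L) stop("no QC-passing rates in the window", call. = FALSE)
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "cell_id")))) |>
    dplyr::summarise(
      mean_r = mean(.data$r), n_points = dplyr::n(), .groups = "drop"
    )
}
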