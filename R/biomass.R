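#' Per-timepoint mean growth rates
#'
#' Averages QC-passing instantaneous rates over all cells present in a group
#' (mother-machine channel, or replicate) at each frame. Frames at which no
#' cell passes QC contribute a mean rate of 0 (no growth assumed where
#' nothing can be measured); their count is recorded in `attr(, "gaps")`.
#'
#' @param rates a `"cf_rates"` table from [estimate_growth_rates()].
#' @param grouping `"channel"` or `"replicate"`; either way the grouping is
#'   also split by `condition` and `species` when those columns are present.
#' @return A tibble with the grouping columns, `frame`, `time` and
#'   `mean_rate`, dense over the frame range of each group.
#' @export
mean_rate_per_timepoint <- function(rates, grouping = c("channel", "replicate")) {
  grouping <- match.arg(grouping)
  key <- if (grouping == "channel") "channel_id" else "replicate_id"
  if (!key %in% names(rates)) {
    stop(sprintf("rates table has no '%s' column", key), call. = FALSE)
  }
  extra <- intersect(c("replicate_id", "condition", "species"), names(rates))
  keys <- unique(c(extra, key))
  d <- tibble::as_tibble(rates)
  dt <- stats::median(diff(sort(unique(d$time))))
  means <- d |>
    dplyr::filter(.data$pass_qc, !is.na(.data$r)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "frame")))) |>
    dplyr::summarise(mean_rate = mean(.data$r), .groups = "drop")
  # dense frame grid per group; QC-empty frames carried as 0
  grid <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe(frame = seq(min(.data$frame), max(.data$frame)))
  out <- grid |>
    dplyr::left_join(means, by = c(keys, "frame")) |>
    dplyr::mutate(
      gap = is.na(.data$mean_rate),
      mean_rate = dplyr::coalesce(.data$mean_rate, 0),
      time = .data$frame * dt
    )
  gaps <- sum(out$gap)
  out$gap <- NULL
  attr(out, "gaps") <- gaps
  attr(out, "delta_t") <- dt
  out
}

#' Accumulated biomass from mean rates
#'
#' Converts a per-timepoint mean-rate series into the estimated fold biomass
#' produced up to each time point,
#' `B_T = exp(delta_t * sum_{i=1}^{T} mean_rate_i)`,
#' with `B_0 = 1`. The construction deliberately uses the mean rate over
#' cells, ignoring between-cell rate variation, so that biomass accumulation
#' can be estimated although cells are continuously washed out of the
#' channels.
#'
#' @param mean_rates numeric vector of per-timepoint mean rates (1/h), or a
#'   tibble from [mean_rate_per_timepoint()] (grouped accumulation).
#' @param delta_t frame interval (h); when `mean_rates` is a tibble the
#'   interval recorded there is used, with a warning if the median spacing
#'   deviates from `delta_t` by more than 1%.
#' @return For a numeric input, a numeric vector `B_T` aligned with the
#'   input. For a tibble, the tibble with a `biomass` column added per group.
#' @export
accumulate_biomass <- function(mean_rates, delta_t = 1 / 12) {
  if (delta_t <= 0) stop("delta_t must be positive", call. = FALSE)
  if (is.numeric(mean_rates)) {
    if (any(!is.finite(mean_rates))) {
      stop("non-finite mean rate", call. = FALSE)
    }
    return(exp(delta_t * cumsum(mean_rates)))
  }
  d <- tibble::as_tibble(mean_rates)
  stopifnot(all(c("frame", "mean_rate") %in% names(d)))
  if (any(!is.finite(d$mean_rate))) stop("non-finite mean rate", call. = FALSE)
  dt <- attr(mean_rates, "delta_t")
  if (is.null(dt)) dt <- delta_t
  if (abs(dt - delta_t) > 0.01 * delta_t) {
    warning(sprintf(
      "median frame spacing %.4g h deviates >1%% from delta_t = %.4g h; using %.4g",
      dt, delta_t, dt
    ), call. = FALSE)
  }
  keys <- setdiff(names(d), c("frame", "time", "mean_rate"))
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(biomass = exp(dt * cumsum(.data$mean_rate))) |>
    dplyr::ungroup()
}

#' Channel-level biomass series for a whole study
#'
#' Convenience composition of [mean_rate_per_timepoint()] and
#' [accumulate_biomass()].
#'
#' @inheritParams mean_rate_per_timepoint
#' @return Tibble with group labels, `frame`, `time`, `mean_rate`, `biomass`.
#' @export
channel_biomass <- function(rates, grouping = c("channel", "replicate")) {
  mr <- mean_rate_per_timepoint(rates, grouping)
  accumulate_biomass(mr, attr(mr, "delta_t"))
}
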