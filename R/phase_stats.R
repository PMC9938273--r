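#' Bin a per-timepoint series into growth phases
#'
#' Assigns each observation to the half-open interval `[b_k, b_{k+1})` of a
#' strictly increasing boundary vector; a boundary time itself belongs to the
#' right-hand bin. Times outside all bins are dropped, with the dropped count
#' in `attr(, "dropped")`.
#'
#' @param series tibble with a `time` column (h), e.g. from
#'   [mean_rate_per_timepoint()].
#' @param boundaries increasing numeric vector of phase boundaries (h).
#' @return The input rows inside the bins, with a `phase` factor labelled
#'   `"[b_k,b_{k+1})"`.
#' @export
bin_phases <- function(series, boundaries = c(0, 20, 40)) {
  if (any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  d <- tibble::as_tibble(series)
  idx <- findInterval(d$time, boundaries, rightmost.closed = FALSE)
  inside <- idx >= 1L & idx <= length(boundaries) - 1L
  labs <- sprintf("[%g,%g)", utils::head(boundaries, -1), boundaries[-1])
  out <- d[inside, , drop = FALSE]
  out$phase <- factor(labs[idx[inside]], levels = labs)
  attr(out, "dropped") <- sum(!inside)
  out
}

#' Random-intercept condition contrast
#'
#' Fits the linear mixed model `value ~ condition + (1 | replicate)` by REML
#' (the "day of the experiment" as a random intercept) and returns the fixed
#' condition contrast with a Satterthwaite-approximation p-value. With a
#' replicate variance estimated as zero the fit is singular and reduces
#' exactly to ordinary least squares; this is reported, not an error.
#'
#' @param values numeric response (e.g. per-timepoint mean rates or log
#'   biomass).
#' @param condition two-level factor (or coercible); the contrast is the
#'   second level minus the first (reference) level.
#' @param replicate factor of replicate ("day") labels; >= 2 levels required.
#' @return A tibble (class `"cf_phase_effect"`) with `difference` (level 2 -
#'   level 1), `std_error`, `df`, `p_value`, `n_per_group` (list column),
#'   `singular`, `level_1`, `level_2`, and the REML variance components
#'   `var_replicate`, `var_residual`.
#' @export
fit_random_intercept <- function(values, condition, replicate) {
  condition <- droplevels(as.factor(condition))
  replicate <- droplevels(as.factor(replicate))
  if (nlevels(condition) != 2L) {
    stop("condition must have exactly 2 levels", call. = FALSE)
  }
  if (nlevels(replicate) < 2L) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  cross <- table(replicate, condition)
  if (any(rowSums(cross > 0) < 2L)) {
    warning("some replicate contains only one condition; ",
            "the contrast is estimated by pooling across replicates",
            call. = FALSE)
  }
  d <- data.frame(y = values, condition = condition, replicate = replicate)
  fit <- suppressMessages(lmerTest::lmer(
    y ~ condition + (1 | replicate), data = d, REML = TRUE
  ))
  co <- stats::coef(summary(fit))
  row <- grep("^condition", rownames(co))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble::tibble(
    difference = co[row, "Estimate"],
    std_error = co[row, "Std. Error"],
    df = co[row, "df"],
    p_value = co[row, "Pr(>|t|)"],
    n_per_group = list(as.vector(table(condition))),
    singular = lme4::isSingular(fit),
    level_1 = levels(condition)[1],
    level_2 = levels(condition)[2],
    var_replicate = vc$vcov[vc$grp == "replicate"],
    var_residual = vc$vcov[vc$grp == "Residual"]
  )
}

#' Percent difference with delta-method standard error
#'
#' Expresses a fixed-effect difference as a percentage of a baseline mean:
#' `100 * difference / baseline`, with the standard error propagated as
#' `100 * SE / baseline` (the baseline treated as fixed).
#'
#' @param difference,std_error contrast estimate and its SE (e.g. from
#'   [fit_random_intercept()]).
#' @param baseline_mean the reference-group mean; must be non-zero.
#' @return A tibble with `percent` and `percent_se`.
#' @export
percent_difference <- function(difference, std_error, baseline_mean) {
  if (!is.finite(baseline_mean) || baseline_mean == 0) {
    stop("baseline mean is zero or non-finite: percent difference undefined",
         call. = FALSE)
  }
  tibble::tibble(
    percent = 100 * difference / baseline_mean,
    percent_se = 100 * std_error / abs(baseline_mean)
  )
}

#' Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, as used for plate-assay comparisons. When both samples are
#' constant with equal means the convention `t = 0, p = 1` applies; constant
#' samples with different means give an infinite t, flagged in the result.
#'
#' @param sample_a,sample_b numeric samples, each of length >= 2.
#' @param alternative `"two.sided"` (default), `"greater"` (mean of a >
#'   mean of b) or `"less"`.
#' @return A tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `infinite_t` flag.
#' @export
welch_t <- function(sample_a, sample_b,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    ma <- mean(sample_a); mb <- mean(sample_b)
    if (ma == mb) {
      return(tibble::tibble(
        t = 0, df = NA_real_, p_value = 1, mean_a = ma, mean_b = mb,
        infinite_t = FALSE
      ))
    }
    p <- switch(alternative,
      two.sided = 0,
      greater = as.numeric(ma < mb),
      less = as.numeric(ma > mb)
    )
    return(tibble::tibble(
      t = sign(ma - mb) * Inf, df = NA_real_, p_value = p,
      mean_a = ma, mean_b = mb, infinite_t = TRUE
    ))
  }
  tt <- stats::t.test(sample_a, sample_b, alternative = alternative,
                      var.equal = FALSE)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(sample_a),
    mean_b = mean(sample_b),
    infinite_t = FALSE
  )
}

#' Phase-binned condition contrasts for growth rates
#'
#' The study's central inference: per-timepoint replicate mean rates are
#' binned into growth phases, and within each species and phase the
#' co-culture vs mono-culture contrast is estimated with the random-intercept
#' model (replicate day as random effect). Percent differences are reported
#' against each direction's baseline: `percent_co_vs_mono` uses the
#' mono-culture phase mean as baseline and `percent_mono_vs_co` the
#' co-culture mean.
#'
#' @param rates a `"cf_rates"` table for the full study.
#' @param boundaries phase boundaries in h (default `c(0, 20, 40)`).
#' @return Tibble with one row per species and phase: the mixed-model
#'   contrast (co - mono), its SE, df, p-value, group means and sizes, and
#'   both percent differences.
#' @export
phase_rate_effects <- function(rates, boundaries = c(0, 20, 40)) {
  mr <- mean_rate_per_timepoint(rates, grouping = "replicate")
  binned <- bin_phases(mr, boundaries)
  binned$condition <- factor(binned$condition, levels = c("mono", "co"))
  res <- list()
  for (sp in unique(binned$species)) {
    for (ph in levels(binned$phase)) {
      d <- binned[binned$species == sp & binned$phase == ph, ]
      if (nrow(d) == 0L) next
      eff <- fit_random_intercept(d$mean_rate, d$condition, d$replicate_id)
      m_mono <- mean(d$mean_rate[d$condition == "mono"])
      m_co <- mean(d$mean_rate[d$condition == "co"])
      res[[length(res) + 1L]] <- tibble::tibble(
        species = sp, phase = ph,
        difference = eff$difference,   # co - mono
        std_error = eff$std_error, df = eff$df, p_value = eff$p_value,
        mean_mono = m_mono, mean_co = m_co,
        n_mono = sum(d$condition == "mono"), n_co = sum(d$condition == "co"),
        percent_co_vs_mono = 100 * (m_co - m_mono) / m_mono,
        percent_mono_vs_co = 100 * (m_mono - m_co) / m_co,
        singular = eff$singular
      )
    }
  }
  dplyr::bind_rows(res)
}

#' Phase condition contrasts for accumulated biomass
#'
#' Per-channel log fold biomass at the end of each phase window is compared
#' between conditions with the random-intercept model. Working on
#' `log(B_T)` keeps the response linear in the summed rates; the percent
#' difference is reported as `100 * (exp(|contrast|) - 1)` toward the larger
#' condition.
#'
#' @param rates a `"cf_rates"` table for the full study.
#' @param at_times times (h) at which biomass is compared (phase ends).
#' @return Tibble with one row per species and time point.
#' @export
biomass_effects <- function(rates, at_times = c(20, 40)) {
  bio <- channel_biomass(rates, grouping = "channel")
  res <- list()
  for (sp in unique(bio$species)) {
    for (tt in at_times) {
      d <- bio |>
        dplyr::filter(.data$species == sp, .data$time <= tt) |>
        dplyr::group_by(
          .data$replicate_id, .data$condition, .data$channel_id
        ) |>
        dplyr::slice_max(.data$time, n = 1) |>
        dplyr::ungroup()
      if (nrow(d) == 0L) next
      d$condition <- factor(d$condition, levels = c("mono", "co"))
      eff <- fit_random_intercept(log(d$biomass), d$condition, d$replicate_id)
      res[[length(res) + 1L]] <- tibble::tibble(
        species = sp, at_time = tt,
        log_difference = eff$difference,   # co - mono in log fold units
        std_error = eff$std_error, df = eff$df, p_value = eff$p_value,
        n_mono = sum(d$condition == "mono"), n_co = sum(d$condition == "co"),
        percent_more = 100 * (exp(abs(eff$difference)) - 1),
        favours = ifelse(eff$difference > 0, "co", "mono"),
        singular = eff$singular
      )
    }
  }
  dplyr::bind_rows(res)
}
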