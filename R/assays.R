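#' Chitinase activity in Units/ml from plate fluorescence
#'
#' Converts fluorometric chitinase-kit readings to enzymatic activity:
#' \deqn{Units/ml = \frac{(FLU - FLU_{blank}) \times 1.9 \times 0.3 \times DF}
#'   {FLU_{standard} \times time \times V_{enz}}}
#' The constants 1.9 and 0.3 are the kit protocol's volume/conversion
#' factors, applied verbatim. Below-blank readings give negative activities;
#' they are returned but flagged.
#'
#' @param flu measured fluorescence (FLU).
#' @param flu_blank blank fluorescence.
#' @param flu_standard standard fluorescence; must be positive.
#' @param df dilution factor (>= 1).
#' @param time incubation time in minutes; must be positive.
#' @param v_enz enzyme (sample) volume in ml; must be positive.
#' @return A tibble with `units_per_ml` and `below_blank` flag (vectorised).
#' @examples
#' # worked example: 1000 FLU over blank, 40 min, 10 ul sample
#' chitinase_units_per_ml(2000, 1000, 1000, df = 1, time = 40, v_enz = 0.01)
#' @export
chitinase_units_per_ml <- function(flu, flu_blank, flu_standard, df = 1,
                                   time = 40, v_enz = 0.01) {
  if (any(flu_standard <= 0)) stop("flu_standard must be > 0", call. = FALSE)
  if (any(time <= 0)) stop("time must be > 0", call. = FALSE)
  if (any(v_enz <= 0)) stop("v_enz must be > 0", call. = FALSE)
  if (any(df < 1)) stop("dilution factor must be >= 1", call. = FALSE)
  u <- ((flu - flu_blank) * 1.9 * 0.3 * df) / (flu_standard * time * v_enz)
  tibble::tibble(units_per_ml = u, below_blank = flu < flu_blank)
}

#' Acetate level normalised per optical density
#'
#' @param acetate acetate assay reading (fluorescence/absorbance units).
#' @param od600 optical density at 600 nm; must be positive.
#' @return Numeric vector, acetate per OD.
#' @export
acetate_per_od <- function(acetate, od600) {
  if (any(!is.finite(od600)) || any(od600 <= 0)) {
    stop("od600 must be positive", call. = FALSE)
  }
  acetate / od600
}

#' Chitinase activity per OD, optionally log-scaled
#'
#' @param units_per_ml chitinase activity (Units/ml).
#' @param od600 optical density; must be positive.
#' @param log_scale return `log10` of the per-OD activity.
#' @return Numeric vector.
#' @export
chitinase_per_od <- function(units_per_ml, od600, log_scale = FALSE) {
  if (any(!is.finite(od600)) || any(od600 <= 0)) {
    stop("od600 must be positive", call. = FALSE)
  }
  v <- units_per_ml / od600
  if (log_scale) log10(v) else v
}
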