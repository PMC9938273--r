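#' Parameters of the mother-machine lineage simulator
#'
#' @param birth_length initial mother-cell length (µm).
#' @param division_length mean division threshold (µm); a cell divides at the
#'   first frame where its true length reaches its own noisy threshold
#'   `division_length * exp(division_cv * z)`, `z ~ N(0, 1)`.
#' @param division_cv lognormal noise scale on the division threshold.
#' @param length_noise_cv multiplicative length-measurement noise: observed
#'   length = true length * `exp(length_noise_cv * z)` per frame.
#' @param growth_noise_sd per-cell growth-rate scaling: each cell draws a
#'   multiplier `s ~ lognormal(0, growth_noise_sd)` applied to the forcing.
#' @param bimodal_fraction probability that a cell in a bimodal-flagged arm
#'   is assigned the slow mode once `bimodal_onset` has passed.
#' @param bimodal_onset time (h) after which the slow/fast mode is assigned.
#' @param slow_multiplier growth-rate multiplier of the slow mode.
#' @param daughter_retention number of frames a newborn daughter is tracked
#'   before being censored (washout from the open channel end).
#' @param replicate_sd lognormal s.d. of the per-replicate ("day") random
#'   scaling of the forcing used by [generate_study()].
#' @param n_channels mother-machine channels per replicate, condition and
#'   species in [generate_study()].
#' @param duration simulated duration (h).
#' @param frame_interval imaging interval (h); 1/12 h = 5 min.
#'
#' @return A list of class `"cf_lineage_params"`.
#' @export
lineage_params <- function(birth_length = 2,
                           division_length = 4,
                           division_cv = 0.1,
                           length_noise_cv = 0.05,
                           growth_noise_sd = 0.15,
                           bimodal_fraction = 0.5,
                           bimodal_onset = 30,
                           slow_multiplier = 0.05,
                           daughter_retention = 10L,
                           replicate_sd = 0.05,
                           n_channels = 12L,
                           duration = 40,
                           frame_interval = 1 / 12) {
  p <- list(
    birth_length = birth_length,
    division_length = division_length,
    division_cv = division_cv,
    length_noise_cv = length_noise_cv,
    growth_noise_sd = growth_noise_sd,
    bimodal_fraction = bimodal_fraction,
    bimodal_onset = bimodal_onset,
    slow_multiplier = slow_multiplier,
    daughter_retention = as.integer(daughter_retention),
    replicate_sd = replicate_sd,
    n_channels = as.integer(n_channels),
    duration = duration,
    frame_interval = frame_interval
  )
  if (!(p$birth_length > 0 && p$birth_length < p$division_length)) {
    stop("need 0 < birth_length < division_length", call. = FALSE)
  }
  stopifnot(
    p$division_cv >= 0, p$length_noise_cv >= 0, p$growth_noise_sd >= 0,
    p$bimodal_fraction >= 0, p$bimodal_fraction <= 1,
    p$slow_multiplier >= 0, p$daughter_retention >= 1,
    p$replicate_sd >= 0, p$n_channels >= 1, p$frame_interval > 0
  )
  if (p$duration < p$frame_interval) {
    stop("duration shorter than one frame interval: no frames to simulate",
         call. = FALSE)
  }
  structure(p, class = "cf_lineage_params")
}

# One simulated cell: grows exponentially under the (possibly replicate- and
# mode-scaled) forcing, divides on reaching its threshold. Used for both the
# mother line (open-ended) and daughters (censored after retention frames).
# Returns per-frame true lengths and the frame at which division occurred
# (NA if never).

#' Simulate one mother-machine channel
#'
#' Simulates the mother cell at the closed end of one channel, growing as
#' `dL/dt = s * r_true(t) * L` with a per-cell lognormal rate multiplier `s`.
#' On reaching its noisy division threshold at a frame, the cell's lineage row
#' ends: two children start at the next frame with exactly half the
#' pre-division true length each. One child continues as the new mother; the
#' other is tracked as a daughter for `daughter_retention` frames and then
#' censored (washout). Observed lengths carry multiplicative lognormal
#' measurement noise; true lengths and true per-frame rates are recorded in a
#' sidecar table.
#'
#' @param r_true forcing function of time (h) returning rates (1/h), e.g.
#'   from [growth_rate_forcing()].
#' @param params a [lineage_params()] object.
#' @param replicate_id,condition,species,channel_id labels stamped on rows.
#' @param seed integer seed; the run is fully reproducible given it.
#' @param bimodal apply the late-phase slow/fast mode assignment to this
#'   channel (used for the cross-feeder-on-mono-culture arm).
#' @param rate_scale extra multiplier on the forcing (replicate day effect).
#'
#' @return A tibble of class `"cf_trajectories"` with columns `replicate_id`,
#'   `condition`, `species`, `channel_id`, `cell_id`, `parent_id`, `frame`,
#'   `time`, `length`, and a sidecar tibble in `attr(, "truth")` with
#'   `cell_id`, `frame`, `r_true`, `length_true`, plus a division record in
#'   `attr(, "divisions")`.
#' @export
simulate_channel <- function(r_true, params,
                             replicate_id = "R1", condition = "mono",
                             species = "degrader", channel_id = "C1",
                             seed = 1L, bimodal = FALSE, rate_scale = 1) {
  stopifnot(is.function(r_true))
  p <- params
  n_frames <- floor(p$duration / p$frame_interval) + 1L
  if (n_frames < 2L) {
    stop("duration/frame_interval gives fewer than two frames", call. = FALSE)
  }
  times <- (seq_len(n_frames) - 1L) * p$frame_interval
  set.seed(as.integer(seed))

  draw_multiplier <- function() exp(stats::rnorm(1L, 0, p$growth_noise_sd))
  draw_threshold <- function() {
    p$division_length * exp(stats::rnorm(1L, 0, p$division_cv))
  }
  r_grid <- r_true(times)
  # incr[f] = trapezoidal forcing integral from 0-based frame f-1 to f
  incr <- c(NA_real_, (r_grid[-n_frames] + r_grid[-1L]) / 2 * p$frame_interval)

  rows <- list()
  truths <- list()
  divisions <- list()
  n_cells <- 0L

  new_cell <- function(parent, first_frame, birth_length, is_mother,
                       grow_in = FALSE, mode = NA_real_) {
    n_cells <<- n_cells + 1L
    list(
      id = sprintf("%s_c%04d", channel_id, n_cells),
      parent = parent, first_frame = first_frame,
      birth_length = birth_length, is_mother = is_mother,
      grow_in = grow_in, s = draw_multiplier(),
      threshold = draw_threshold(), mode = mode
    )
  }

  queue <- list(new_cell(NA_character_, 0L, p$birth_length, TRUE))

  while (length(queue) > 0L) {
    cell <- queue[[1L]]
    queue <- queue[-1L]
    ff <- cell$first_frame                   # 0-based
    last <- if (cell$is_mother) n_frames - 1L else {
      min(n_frames - 1L, ff + p$daughter_retention - 1L)
    }
    len <- numeric(0)
    rate <- numeric(0)
    L <- cell$birth_length
    mode_mult <- cell$mode
    div_frame <- NA_integer_
    L_pre <- NA_real_
    for (f in ff:last) {
      if (bimodal && is.na(mode_mult) && times[f + 1L] >= p$bimodal_onset) {
        mode_mult <- if (stats::runif(1L) < p$bimodal_fraction) {
          p$slow_multiplier
        } else 1
      }
      m <- if (is.na(mode_mult)) 1 else mode_mult
      if (f > ff || cell$grow_in) {
        L <- L * exp(cell$s * m * rate_scale * incr[f + 1L])
      }
      len <- c(len, L)
      rate <- c(rate, cell$s * m * rate_scale * r_grid[f + 1L])
      if (L >= cell$threshold && f < last) {
        div_frame <- f
        L_pre <- L
        break
      }
    }
    frames <- seq.int(ff, by = 1L, length.out = length(len))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = cell$id, parent_id = cell$parent,
      frame = as.integer(frames), time = times[frames + 1L], length_true = len
    )
    truths[[length(truths) + 1L]] <- tibble::tibble(
      cell_id = cell$id, frame = as.integer(frames), r_true = rate,
      length_true = len
    )
    if (!is.na(div_frame)) {
      half <- L_pre / 2
      child_a <- new_cell(cell$id, div_frame + 1L, half, cell$is_mother,
                          grow_in = TRUE, mode = mode_mult)
      child_b <- new_cell(cell$id, div_frame + 1L, half, FALSE,
                          grow_in = TRUE, mode = mode_mult)
      divisions[[length(divisions) + 1L]] <- tibble::tibble(
        parent_id = cell$id, frame = as.integer(div_frame),
        time = times[div_frame + 1L], pre_division_length = L_pre,
        child_length = half,
        children = paste(child_a$id, child_b$id, sep = ";")
      )
      queue <- c(queue, list(child_a), list(child_b))
    }
  }

  out <- dplyr::bind_rows(rows)
  noise <- if (p$length_noise_cv > 0) {
    exp(stats::rnorm(nrow(out), 0, p$length_noise_cv))
  } else rep(1, nrow(out))
  out <- tibble::tibble(
    replicate_id = replicate_id, condition = condition, species = species,
    channel_id = channel_id,
    cell_id = out$cell_id, parent_id = out$parent_id,
    frame = out$frame, time = out$time,
    length = out$length_true * noise
  )
  out <- dplyr::arrange(out, .data$cell_id, .data$frame)
  truth <- dplyr::arrange(dplyr::bind_rows(truths), .data$cell_id, .data$frame)
  attr(out, "truth") <- truth
  attr(out, "divisions") <- if (length(divisions)) {
    dplyr::bind_rows(divisions)
  } else {
    tibble::tibble(
      parent_id = character(), frame = integer(), time = numeric(),
      pre_division_length = numeric(), child_length = numeric(),
      children = character()
    )
  }
  class(out) <- c("cf_trajectories", class(out))
  out
}

#' Generate the full synthetic mother-machine study
#'
#' Builds the 2 x 2 study design of the experiment: degrader and cross-feeder
#' channels, each fed by either the degrader mono-culture or the full
#' co-culture batch environment, over `n_replicates` replicate days. A
#' lognormal per-replicate scaling of the forcing creates the "day" random
#' effect. The cross-feeder-on-mono-culture arm receives the late-phase
#' slow/fast mode assignment (`bimodal_fraction` of cells slow after
#' `bimodal_onset`), emulating the bimodal late-season growth of that arm.
#'
#' @param env_mono,env_co environment trajectories from
#'   [simulate_environment()] for the mono- and co-culture batch.
#' @param params a [lineage_params()] object.
#' @param n_replicates number of replicate days.
#' @param seed integer master seed; channel seeds are derived from it.
#' @return A `"cf_trajectories"` tibble over all channels, with the combined
#'   truth sidecar in `attr(, "truth")` (also carrying the label columns).
#' @export
generate_study <- function(env_mono, env_co, params, n_replicates = 4L,
                           seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  p <- params
  forcings <- list(
    mono = list(
      degrader = growth_rate_forcing(env_mono, "degrader"),
      crossfeeder = growth_rate_forcing(env_mono, "crossfeeder")
    ),
    co = list(
      degrader = growth_rate_forcing(env_co, "degrader"),
      crossfeeder = growth_rate_forcing(env_co, "crossfeeder")
    )
  )
  set.seed(as.integer(seed))
  rep_scale <- exp(stats::rnorm(n_replicates, 0, p$replicate_sd))
  arm_seeds <- sample.int(.Machine$integer.max - 1L,
                          n_replicates * 4L * p$n_channels)
  tabs <- list()
  truths <- list()
  k <- 0L
  for (r in seq_len(n_replicates)) {
    rep_id <- sprintf("R%d", r)
    for (condition in c("mono", "co")) {
      for (species in c("degrader", "crossfeeder")) {
        bimodal <- species == "crossfeeder" && condition == "mono"
        for (ch in seq_len(p$n_channels)) {
          k <- k + 1L
          ch_id <- sprintf("%s_%s_%s_ch%02d", rep_id, condition, species, ch)
          tab <- simulate_channel(
            forcings[[condition]][[species]], p,
            replicate_id = rep_id, condition = condition, species = species,
            channel_id = ch_id, seed = arm_seeds[k], bimodal = bimodal,
            rate_scale = rep_scale[r]
          )
          truth <- attr(tab, "truth")
          truth$replicate_id <- rep_id
          truth$condition <- condition
          truth$species <- species
          truth$channel_id <- ch_id
          tabs[[k]] <- tab
          truths[[k]] <- truth
        }
      }
    }
  }
  out <- dplyr::bind_rows(tabs)
  attr(out, "truth") <- dplyr::bind_rows(truths)
  attr(out, "params") <- p
  class(out) <- c("cf_trajectories", class(out))
  out
}

#' @export
print.cf_trajectories <- function(x, ...) {
  cat(sprintf(
    "<cf_trajectories> %d rows, %d cells, %d channels\n",
    nrow(x), dplyr::n_distinct(x$cell_id), dplyr::n_distinct(x$channel_id)
  ))
  NextMethod()
}
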