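trajectory_columns <- c(
  "replicate_id", "condition", "species", "channel_id", "cell_id",
  "parent_id", "frame", "time", "length"
)

#' Read and validate a lineage trajectory table
#'
#' Reads a CSV with exactly the trajectory schema (one row per cell per
#' frame) and enforces the table invariants: positive lengths, strictly
#' increasing times within each cell, no duplicated (cell, frame) pairs.
#' Violations are reported with the offending row numbers.
#'
#' @param path CSV path.
#' @return A validated `"cf_trajectories"` tibble.
#' @export
read_trajectories <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(trajectory_columns, header)
  if (length(missing)) {
    stop("trajectory CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         replicate_id = readr::col_character(),
                         condition = readr::col_character(),
                         species = readr::col_character(),
                         channel_id = readr::col_character(),
                         cell_id = readr::col_character(),
                         parent_id = readr::col_character(),
                         frame = readr::col_integer(),
                         time = readr::col_double(),
                         length = readr::col_double()
                       ))
  x <- x[trajectory_columns]
  validate_trajectories(x)
}

#' @rdname read_trajectories
#' @param table an in-memory trajectory table to validate.
#' @export
validate_trajectories <- function(table) {
  x <- tibble::as_tibble(table)
  bad_len <- which(!is.finite(x$length) | x$length <= 0)
  if (length(bad_len)) {
    stop(sprintf("non-positive length at row %s",
                 paste(utils::head(bad_len, 5), collapse = ", ")),
         call. = FALSE)
  }
  dup <- duplicated(x[c("cell_id", "frame")])
  if (any(dup)) {
    stop(sprintf("duplicated (cell_id, frame) at row %s",
                 paste(utils::head(which(dup), 5), collapse = ", ")),
         call. = FALSE)
  }
  ord <- order(x$cell_id, x$frame)
  xo <- x[ord, ]
  same_cell <- xo$cell_id[-1] == xo$cell_id[-nrow(xo)]
  nonmono <- same_cell & diff(xo$time) <= 0
  if (any(nonmono)) {
    stop(sprintf("non-monotone time within cell at row %s",
                 paste(utils::head(ord[which(nonmono) + 1L], 5), collapse = ", ")),
         call. = FALSE)
  }
  if (!inherits(x, "cf_trajectories")) {
    class(x) <- c("cf_trajectories", class(x))
  }
  x
}

#' Write a trajectory table (and optional truth sidecar) as CSV
#'
#' @param table a `"cf_trajectories"` tibble.
#' @param path output CSV path.
#' @param truth_path optional path for the simulator's true-rate sidecar
#'   (columns `cell_id`, `frame`, `r_true`, `length_true`).
#' @return `table`, invisibly.
#' @export
write_trajectories <- function(table, path, truth_path = NULL) {
  readr::write_csv(as.data.frame(table)[trajectory_columns], path)
  truth <- attr(table, "truth")
  if (!is.null(truth_path)) {
    if (is.null(truth)) stop("table carries no truth sidecar", call. = FALSE)
    readr::write_csv(as.data.frame(truth), truth_path)
  }
  invisible(table)
}

#' Default pipeline configuration
#'
#' All tunables of the pipeline in one list: smoothing/QC settings
#' ([smoothing_config()]), the synthetic community and lineage parameters
#' ([environment_params()], [lineage_params()]), phase boundaries, biomass
#' grouping, heterogeneity window, dip draws and the master seed.
#'
#' @return A nested list, YAML-serialisable.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    smoothing = unclass(smoothing_config()),
    environment = unclass(environment_params()),
    lineage = unclass(lineage_params()),
    n_replicates = 4L,
    phases = c(0, 20, 40),
    biomass_grouping = "channel",
    biomass_times = c(20, 40),
    heterogeneity_window = c(34, 36),
    dip_draws = 10000L
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (k2 in names(user[[k]])) cfg[[k]][[k2]] <- user[[k]][[k2]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full analysis pipeline on synthetic or provided data
#'
#' Simulates the mono- and co-culture batch environments and the
#' mother-machine study (unless a trajectory table is supplied), estimates
#' single-cell elongation rates, accumulates biomass, fits the phase-binned
#' condition contrasts and the biomass contrasts, and summarises late-window
#' growth-rate heterogeneity with the dip test. Deterministic given the
#' configuration (including its seed).
#'
#' @param config configuration list ([default_pipeline_config()]).
#' @param trajectories optional `"cf_trajectories"` table; when given, the
#'   simulation stage is skipped.
#' @param output_dir optional directory; when given, writes
#'   `trajectories.csv` (synthetic runs), `rates.csv`, `biomass.csv`,
#'   `effects.csv`, `biomass_effects.csv`, `heterogeneity.csv` and
#'   `manifest.json` there.
#' @return A list with elements `trajectories`, `rates`, `biomass`,
#'   `rate_effects`, `biomass_effects`, `heterogeneity`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         trajectories = NULL, output_dir = NULL) {
  stage <- "configuration"
  result <- tryCatch({
    smooth_cfg <- do.call(smoothing_config, config$smoothing)
    synthetic <- is.null(trajectories)
    if (synthetic) {
      stage <- "environment simulation"
      env_par <- do.call(environment_params, config$environment)
      env_mono <- simulate_environment(env_par, include_crossfeeder = FALSE)
      env_co <- simulate_environment(env_par, include_crossfeeder = TRUE)
      stage <- "lineage simulation"
      lin_par <- do.call(lineage_params, config$lineage)
      trajectories <- generate_study(
        env_mono, env_co, lin_par,
        n_replicates = config$n_replicates, seed = config$seed
      )
    } else {
      trajectories <- validate_trajectories(trajectories)
    }
    stage <- "growth-rate estimation"
    rates <- estimate_growth_rates(trajectories, smooth_cfg)
    stage <- "biomass accumulation"
    biomass <- channel_biomass(rates, grouping = config$biomass_grouping)
    stage <- "phase contrasts"
    rate_effects <- phase_rate_effects(rates, config$phases)
    bio_effects <- biomass_effects(rates, config$biomass_times)
    stage <- "heterogeneity"
    het_groups <- intersect(c("species", "condition"), names(rates))
    het <- heterogeneity_summary(
      rates, config$heterogeneity_window, by = het_groups
    )
    het$D <- NA_real_
    het$dip_p <- NA_real_
    het$n_cells <- NA_integer_
    cm <- cell_mean_rates(rates, config$heterogeneity_window, by = het_groups)
    for (i in seq_len(nrow(het))) {
      sel <- rep(TRUE, nrow(cm))
      for (g in het_groups) sel <- sel & cm[[g]] == het[[g]][i]
      v <- cm$mean_r[sel]
      if (length(v) >= 2) {
        het$D[i] <- dip_statistic(v)
        het$dip_p[i] <- dip_pvalue(het$D[i], length(v),
                                   config$dip_draws, seed = config$seed + i)
        het$n_cells[i] <- length(v)
      }
    }
    stage <- "manifest"
    est_log <- attr(rates, "log")
    manifest <- list(
      seed = config$seed,
      synthetic = synthetic,
      n_rows = nrow(trajectories),
      n_cells = dplyr::n_distinct(trajectories$cell_id),
      n_channels = dplyr::n_distinct(trajectories$channel_id),
      cells_in = est_log$cells_in,
      cells_or_segments_skipped = est_log$cells_or_segments_skipped,
      points_removed_qc = est_log$points_removed_qc,
      points_no_estimate = est_log$points_no_estimate,
      config = config
    )
    list(
      trajectories = trajectories, rates = rates, biomass = biomass,
      rate_effects = rate_effects, biomass_effects = bio_effects,
      heterogeneity = het, manifest = manifest
    )
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) readr::write_csv(as.data.frame(x), file.path(output_dir, f))
    if (result$manifest$synthetic) {
      write_trajectories(result$trajectories,
                         file.path(output_dir, "trajectories.csv"),
                         file.path(output_dir, "true_rates.csv"))
    }
    wr(result$rates, "rates.csv")
    wr(result$biomass, "biomass.csv")
    wr(result$rate_effects, "effects.csv")
    wr(result$biomass_effects, "biomass_effects.csv")
    het_out <- result$heterogeneity
    wr(het_out, "heterogeneity.csv")
    jsonlite::write_json(result$manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
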