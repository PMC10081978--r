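kinematics_cols <- c("participant", "trial", "mode", "cycle_ms",
                     "load_left", "load_right", "t_s",
                     "xL_m", "yL_m", "xR_m", "yR_m")
velocity_cols <- c("vxL_m_s", "vyL_m_s", "vxR_m_s", "vyR_m_s")

#' Write and read trial kinematics
#'
#' Long tidy CSV interchange format for two-hand trials (the on-disk
#' stand-in for the robot's native binary recordings): one row per sample,
#' fixed header `participant, trial, mode, cycle_ms, load_left, load_right,
#' t_s, xL_m, yL_m, xR_m, yR_m` with optional velocity columns
#' `vxL_m_s..vyR_m_s`. Units are metres and seconds on disk; RFC-4180,
#' UTF-8, `"."` decimal.
#'
#' `read_kinematics()` validates the header, requires strictly increasing
#' uniform timestamps within each trial (rows are sorted by `t_s` first, so
#' shuffled files load identically) and rejects non-finite positions with
#' the offending row number. Velocities are taken from the file when
#' present, otherwise derived by central differences.
#'
#' @param experiment A manifest tibble with a `kinematics` list-column
#'   ([generate_experiment()]), or any data frame already in the long format.
#' @param path CSV file path.
#' @return `read_kinematics()` returns a manifest tibble with one row per
#'   trial and a `kinematics` list-column; `write_kinematics()` returns
#'   `path` invisibly.
#' @export
write_kinematics <- function(experiment, path) {
  if ("kinematics" %in% names(experiment)) {
    long <- purrr::map_dfr(seq_len(nrow(experiment)), function(i) {
      kin <- experiment$kinematics[[i]]
      dplyr::bind_cols(
        experiment[rep(i, nrow(kin)),
                   c("participant", "trial", "mode", "cycle_ms",
                     "load_left", "load_right")],
        kin)
    })
  } else {
    long <- experiment
  }
  miss <- setdiff(kinematics_cols, names(long))
  if (length(miss) > 0) {
    stop("missing kinematics column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- c(kinematics_cols, intersect(velocity_cols, names(long)))
  readr::write_csv(long[, keep], path)
  invisible(path)
}

#' @rdname write_kinematics
#' @export
read_kinematics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(hdr[seq_along(kinematics_cols)], kinematics_cols)) {
    miss <- setdiff(kinematics_cols, hdr)
    stop("malformed kinematics header",
         if (length(miss) > 0)
           paste0("; missing column(s): ", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  long <- readr::read_csv(path, show_col_types = FALSE)
  pos <- as.matrix(long[, c("xL_m", "yL_m", "xR_m", "yR_m")])
  bad <- which(!is.finite(pos), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite position at data row %d", bad[1, 1]),
         call. = FALSE)
  }
  has_vel <- all(velocity_cols %in% names(long))
  long <- dplyr::arrange(long, .data$participant, .data$mode, .data$trial,
                         .data$t_s)
  groups <- dplyr::group_by(long, .data$participant, .data$mode, .data$trial,
                            .data$cycle_ms, .data$load_left, .data$load_right)
  out <- dplyr::group_modify(groups, function(g, key) {
    dt <- diff(g$t_s)
    if (any(dt <= 0)) {
      stop("timestamps not strictly increasing within a trial", call. = FALSE)
    }
    if (max(dt) - min(dt) > 1e-9) {
      stop("non-uniform sampling step within a trial", call. = FALSE)
    }
    if (!has_vel) {
      fs <- 1 / stats::median(dt)
      g$vxL_m_s <- central_diff(g$xL_m, fs)
      g$vyL_m_s <- central_diff(g$yL_m, fs)
      g$vxR_m_s <- central_diff(g$xR_m, fs)
      g$vyR_m_s <- central_diff(g$yR_m, fs)
    }
    tibble::tibble(kinematics = list(
      g[, c("t_s", "xL_m", "yL_m", "xR_m", "yR_m", velocity_cols)]))
  })
  dplyr::ungroup(out)
}

central_diff <- function(x, fs) {
  n <- length(x)
  v <- numeric(n)
  if (n >= 3) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  v
}

#' Write and read trial summaries
#'
#' One row per trial: the manifest metadata plus `mean_crp_deg`,
#' `sd_crp_deg`, `deviation_deg`, `excluded`, `n_samples` (degrees in the
#' summary outputs, matching how results are reported).
#'
#' @param summaries Trial-summary tibble.
#' @param path CSV file path.
#' @return `read_trial_summaries()` returns the tibble;
#'   `write_trial_summaries()` returns `path` invisibly.
#' @export
write_trial_summaries <- function(summaries, path) {
  readr::write_csv(summaries, path)
  invisible(path)
}

#' @rdname write_trial_summaries
#' @export
read_trial_summaries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Run configuration
#'
#' A run is fully described by a YAML configuration: master seed, number of
#' participants, the design table (modes, cycling frequencies, loads,
#' repetitions), the load-to-dynamics calibration, the analysis parameters
#' (window, transition detector) and the statistics settings. Every pipeline
#' output directory receives a verbatim echo of the configuration it was
#' produced from, so a run can be reproduced from its own outputs.
#'
#' @param seed Master seed.
#' @param participants Number of participants.
#' @param design List: `modes`, `cycle_ms`, `loads`, `reps`.
#' @param dynamics Load-to-dynamics mapping (see
#'   [default_dynamics_mapping()]).
#' @param analysis List: `window_start_s`, `window_end_s`,
#'   `transition_window_s`, `transition_step_s`, `transition_threshold_deg`,
#'   `duration_s`, `fs`, `noise_sd_m`.
#' @param stats List: `responses` (subset of `c("mean","sd")`), `conf_level`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, participants = 2,
                       design = list(modes = c("in_phase", "anti_phase"),
                                     cycle_ms = c(750, 1200),
                                     loads = load_types(),
                                     reps = 5),
                       dynamics = default_dynamics_mapping(),
                       analysis = list(window_start_s = 12, window_end_s = 42,
                                       transition_window_s = 3,
                                       transition_step_s = 0.5,
                                       transition_threshold_deg = 90,
                                       duration_s = 45, fs = 1000,
                                       noise_sd_m = 5e-4),
                       stats = list(responses = c("mean", "sd"),
                                    conf_level = 0.95)) {
  structure(list(seed = seed, participants = participants, design = design,
                 dynamics = dynamics, analysis = analysis, stats = stats),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  # yaml serializes named atomic vectors as plain sequences, losing the
  # load-type names; write them as maps instead
  out$dynamics$omega_pull <- as.list(out$dynamics$omega_pull)
  out$dynamics$q_increment <- as.list(out$dynamics$q_increment)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` object (for `write_run_config()`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- run_config()
  for (nm in names(raw)) {
    if (nm %in% c("design", "dynamics", "analysis", "stats")) {
      for (k in names(raw[[nm]])) base[[nm]][[k]] <- raw[[nm]][[k]]
    } else {
      base[[nm]] <- raw[[nm]]
    }
  }
  # yaml flattens named vectors to lists; restore
  base$dynamics$omega_pull <- unlist(base$dynamics$omega_pull)
  base$dynamics$q_increment <- unlist(base$dynamics$q_increment)
  base
}
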