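#' Pipeline stages: simulate, analyse, compare
#'
#' The three stages of a reproducible run, each writing tidy CSV outputs
#' plus an echoed configuration and a row-count log so that rows out can be
#' reconciled with rows in minus logged exclusions. A thin command-line
#' wrapper over these functions ships at
#' `system.file("cli", "coordphase.R", package = "coordphase")`.
#'
#' * `pipeline_simulate()`: generate the synthetic experiment and write
#'   `kinematics.csv` + `manifest.csv`.
#' * `pipeline_analyze()`: read kinematics, run the CRP pipeline, write
#'   `trial_summaries.csv`.
#' * `pipeline_stats()`: read summaries, fit the per-stratum mixed models,
#'   write `model_<response>.csv`, `contrasts_<response>.csv` and a
#'   human-readable `report.txt`.
#' * `run_pipeline()`: all three in sequence under one output directory.
#'
#' @param config A [run_config()] object (or path to its YAML file).
#' @param out_dir Output directory (created if absent).
#' @return Each stage returns (invisibly) a list of the paths it wrote;
#'   `run_pipeline()` returns the combined list.
#' @export
pipeline_simulate <- function(config, out_dir) {
  config <- ensure_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis
  exper <- generate_experiment(
    n_participants = config$participants, seed = config$seed,
    duration_s = an$duration_s, fs = an$fs, noise_sd_m = an$noise_sd_m,
    modes = config$design$modes, cycle_ms = config$design$cycle_ms,
    loads = config$design$loads, reps = config$design$reps,
    mapping = config$dynamics)
  kin_path <- file.path(out_dir, "kinematics.csv")
  man_path <- file.path(out_dir, "manifest.csv")
  write_kinematics(exper, kin_path)
  manifest <- exper[, setdiff(names(exper), "kinematics")]
  readr::write_csv(manifest, man_path)
  echo_config(config, out_dir)
  log_stage(out_dir, "simulate",
            sprintf("trials=%d samples_per_trial=%d",
                    nrow(manifest), round(an$duration_s * an$fs)))
  invisible(list(kinematics = kin_path, manifest = man_path))
}

#' @rdname pipeline_simulate
#' @param kinematics_path Path to a kinematics CSV (defaults to the one in
#'   `out_dir`).
#' @export
pipeline_analyze <- function(config, out_dir,
                             kinematics_path = file.path(out_dir,
                                                         "kinematics.csv")) {
  config <- ensure_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis
  trials <- read_kinematics(kinematics_path)
  sums <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    summarize_trial(trials$kinematics[[i]], mode = trials$mode[i],
                    window = c(an$window_start_s, an$window_end_s),
                    transition_window_s = an$transition_window_s,
                    transition_step_s = an$transition_step_s,
                    transition_threshold_deg = an$transition_threshold_deg)
  })
  out <- dplyr::bind_cols(
    trials[, c("participant", "mode", "trial", "cycle_ms",
               "load_left", "load_right")], sums)
  sum_path <- file.path(out_dir, "trial_summaries.csv")
  write_trial_summaries(out, sum_path)
  echo_config(config, out_dir)
  log_stage(out_dir, "analyze",
            sprintf("trials_in=%d trials_out=%d flagged=%d",
                    nrow(trials), nrow(out), sum(out$excluded)))
  invisible(list(summaries = sum_path))
}

#' @rdname pipeline_simulate
#' @param summaries_path Path to a trial-summary CSV (defaults to the one in
#'   `out_dir`).
#' @export
pipeline_stats <- function(config, out_dir,
                           summaries_path = file.path(out_dir,
                                                      "trial_summaries.csv")) {
  config <- ensure_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sums <- read_trial_summaries(summaries_path)
  if (length(unique(sums$participant)) < 2) {
    stop("at least 2 participants are required for the mixed-effects stage",
         call. = FALSE)
  }
  tab <- build_condition_table(sums)
  paths <- list()
  report <- c("coordphase condition comparison", "")
  for (resp in config$stats$responses) {
    models <- purrr::map_dfr(unique(tab$stratum), function(s) {
      fit <- fit_lme(tab[tab$stratum == s, ], resp)
      dplyr::mutate(tidy(fit), stratum = s, response = resp,
                    n_obs = fit$n_obs, .before = 1)
    })
    contrasts <- purrr::map_dfr(unique(tab$stratum), function(s) {
      fit <- fit_lme(tab[tab$stratum == s, ], resp)
      pw <- pairwise_emm(fit, conf_level = config$stats$conf_level)
      dplyr::mutate(pw$contrasts, stratum = s, response = resp, .before = 1)
    })
    mp <- file.path(out_dir, sprintf("model_%s.csv", resp))
    cp <- file.path(out_dir, sprintf("contrasts_%s.csv", resp))
    readr::write_csv(models, mp)
    readr::write_csv(contrasts, cp)
    paths[[paste0("model_", resp)]] <- mp
    paths[[paste0("contrasts_", resp)]] <- cp
    nsig <- sum(contrasts$p_adj < 0.05)
    report <- c(report,
                sprintf("response %s: %d strata, %d contrasts, %d Tukey-significant at 0.05",
                        resp, length(unique(tab$stratum)), nrow(contrasts),
                        nsig))
  }
  rp <- file.path(out_dir, "report.txt")
  writeLines(report, rp)
  paths$report <- rp
  echo_config(config, out_dir)
  log_stage(out_dir, "stats",
            sprintf("rows_in=%d rows_used=%d excluded=%d",
                    nrow(sums), nrow(tab), sum(sums$excluded)))
  invisible(paths)
}

#' @rdname pipeline_simulate
#' @export
run_pipeline <- function(config, out_dir) {
  config <- ensure_config(config)
  p1 <- pipeline_simulate(config, out_dir)
  p2 <- pipeline_analyze(config, out_dir)
  p3 <- pipeline_stats(config, out_dir)
  invisible(c(p1, p2, p3))
}

ensure_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config") && is.list(config)) {
    class(config) <- "run_config"
  }
  stopifnot(inherits(config, "run_config"))
  config
}

echo_config <- function(config, out_dir) {
  write_run_config(config, file.path(out_dir, "config_echo.yaml"))
}

log_stage <- function(out_dir, stage, details) {
  line <- sprintf("[coordphase %s] stage=%s %s",
                  as.character(utils::packageVersion("coordphase")),
                  stage, details)
  cat(line, "\n", sep = "", file = file.path(out_dir, "run_log.txt"),
      append = TRUE)
}
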