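#' Pool trial summaries into the condition table
#'
#' Drops excluded (phase-transitioned) trials, builds the 9-level ordered
#' load-condition factor `"left/right"` with reference level `"none/none"`,
#' and labels each row's analysis stratum (mode x cycling frequency, the four
#' strata analysed separately).
#'
#' @param summaries Trial-summary tibble with columns `participant`, `trial`,
#'   `mode`, `cycle_ms`, `load_left`, `load_right`, `mean_crp_deg`,
#'   `sd_crp_deg`, `deviation_deg`, `excluded`.
#' @return A tibble with the retained rows plus `load_condition` (factor,
#'   9 levels, reference `none/none`) and `stratum` (e.g.
#'   `"in_phase_750"`). The number of dropped trials is reported via a
#'   message; an empty input after exclusion raises a warning.
#' @export
build_condition_table <- function(summaries) {
  need <- c("participant", "trial", "mode", "cycle_ms", "load_left",
            "load_right", "mean_crp_deg", "sd_crp_deg", "deviation_deg",
            "excluded")
  miss <- setdiff(need, names(summaries))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  check_load(summaries$load_left, "load_left")
  check_load(summaries$load_right, "load_right")
  key <- paste(summaries$participant, summaries$mode, summaries$trial)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, mode, trial) keys in summaries",
         call. = FALSE)
  }
  n_drop <- sum(summaries$excluded)
  if (n_drop > 0) {
    message(sprintf("dropping %d excluded trial(s) (phase transition)", n_drop))
  }
  out <- summaries[!summaries$excluded, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("all trials excluded: empty condition table", call. = FALSE)
  }
  lv <- as.vector(outer(load_types(), load_types(),
                        function(l, r) paste(l, r, sep = "/")))
  lv <- c("none/none", setdiff(lv, "none/none"))
  out$load_condition <- factor(paste(out$load_left, out$load_right, sep = "/"),
                               levels = lv)
  out$stratum <- paste(out$mode, out$cycle_ms, sep = "_")
  tibble::as_tibble(out)
}

one_stratum <- function(table) {
  if (!"stratum" %in% names(table)) {
    stop("`table` must come from build_condition_table()", call. = FALSE)
  }
  s <- unique(table$stratum)
  if (length(s) != 1) {
    stop("`table` must contain a single stratum (mode x cycle_ms); got: ",
         paste(s, collapse = ", "), call. = FALSE)
  }
  s
}

#' Mixed-effects comparison of load conditions within one stratum
#'
#' Fits the linear mixed model
#' `response ~ load_condition + (1 | trial) + (1 | participant)`
#' by REML, where the response is the per-trial mean CRP (`"mean"`) or its
#' SD (`"sd"`), the reference level is the unloaded `none/none` condition
#' (so the intercept estimates the null matched condition), and trial index
#' and participant enter as crossed random intercepts. Per-coefficient
#' p-values are Wald chi-square tests (\eqn{(\beta/SE)^2} on 1 df), the
#' chi-square-based convention of the reported tables.
#'
#' A singular fit (trial variance estimated at the boundary) triggers a
#' logged downgrade to a participant-only random intercept; non-convergence
#' is reported as an error, never silently ignored.
#'
#' @param table Condition table restricted to one stratum (see
#'   [build_condition_table()]).
#' @param response `"mean"` (mean CRP, degrees) or `"sd"` (SD of CRP).
#' @return An object of class `coord_lme`: list with elements `fit` (the
#'   `lmerMod`), `response`, `stratum`, `downgraded` (logical), `n_obs`.
#'   Use [tidy()]/[glance()] for the table view and [pairwise_emm()] for
#'   Tukey contrasts.
#' @examples
#' \donttest{
#' tab <- simulate_condition_table(n_participants = 6, seed = 1)
#' fit <- fit_lme(tab[tab$stratum == tab$stratum[1], ], "mean")
#' tidy(fit)
#' }
#' @export
fit_lme <- function(table, response = c("mean", "sd")) {
  response <- match.arg(response)
  stratum <- one_stratum(table)
  if (length(unique(table$participant)) < 2) {
    stop("at least 2 participants are required to fit the mixed model",
         call. = FALSE)
  }
  present <- table(droplevels_keep(table$load_condition))
  if (length(present) < 9 || any(present == 0)) {
    stop("all 9 load-condition levels must be present in the stratum",
         call. = FALSE)
  }
  df <- data.frame(
    y = if (response == "mean") table$mean_crp_deg else table$sd_crp_deg,
    load_condition = table$load_condition,
    participant = factor(table$participant),
    trial = factor(table$trial)
  )
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lmerTest::lmer(
    y ~ load_condition + (1 | trial) + (1 | participant),
    data = df, REML = TRUE, control = ctrl)
  downgraded <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    message("singular fit (trial variance at boundary); ",
            "refitting with participant-only random intercept")
    fit <- lmerTest::lmer(y ~ load_condition + (1 | participant),
                          data = df, REML = TRUE, control = ctrl)
    downgraded <- TRUE
  }
  conv <- fit@optinfo$conv$lme4
  if (!is.null(conv$code) && conv$code != 0) {
    stop("mixed model did not converge for stratum ", stratum, call. = FALSE)
  }
  structure(
    list(fit = fit, response = response, stratum = stratum,
         downgraded = downgraded, n_obs = nrow(df)),
    class = "coord_lme")
}

droplevels_keep <- function(f) factor(f, levels = levels(f))

#' @export
print.coord_lme <- function(x, ...) {
  cat(sprintf("<coord_lme> response: %s CRP (deg), stratum: %s, n = %d%s\n",
              if (x$response == "mean") "mean" else "SD of",
              x$stratum, x$n_obs,
              if (x$downgraded) " (participant-only random intercept)" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy a fitted load-condition model
#'
#' `tidy()` returns the fixed-effect table (one row per coefficient:
#' `term`, `estimate`, `std_error`, `statistic` = Wald chi-square,
#' `p_value`) followed by the random-effect and residual SDs
#' (`effect = "random"`). `glance()` returns a one-row model overview.
#'
#' @param x A `coord_lme` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy coord_lme
#' @export
tidy.coord_lme <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  chisq <- (sm[, "Estimate"] / sm[, "Std. Error"])^2
  fixed <- tibble::tibble(
    effect = "fixed",
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = chisq,
    p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  )
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  rand <- tibble::tibble(
    effect = "random",
    term = paste0("sd_", ifelse(vc$grp == "Residual", "Residual", vc$grp)),
    estimate = vc$sdcor,
    std_error = NA_real_,
    statistic = NA_real_,
    p_value = NA_real_
  )
  dplyr::bind_rows(fixed, rand)
}

#' @rdname tidy.coord_lme
#' @method glance coord_lme
#' @export
glance.coord_lme <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    response = x$response,
    stratum = x$stratum,
    n_obs = x$n_obs,
    sigma_residual = vc$sdcor[vc$grp == "Residual"],
    reml_criterion = lme4::REMLcrit(x$fit),
    downgraded = x$downgraded
  )
}

#' Tukey-adjusted pairwise condition contrasts
#'
#' Estimated marginal means per load condition and all 36 pairwise
#' differences with Tukey-adjusted p-values and confidence intervals
#' (Satterthwaite degrees of freedom). Raw (unadjusted) p-values are
#' included for reference; the Tukey p is never smaller.
#'
#' @param model A `coord_lme` object from [fit_lme()].
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A list with two tibbles: `emmeans` (`load_condition`, `emmean`,
#'   `se`, `lower`, `upper`) and `contrasts` (`contrast`, `estimate`, `se`,
#'   `lower`, `upper`, `p_value` raw, `p_adj` Tukey).
#' @export
pairwise_emm <- function(model, conf_level = 0.95) {
  stopifnot(inherits(model, "coord_lme"))
  em <- emmeans::emmeans(model$fit, ~load_condition,
                         lmer.df = "satterthwaite")
  if (any(!is.finite(summary(em)$SE))) {
    stop("degenerate variance in stratum ", model$stratum, call. = FALSE)
  }
  ems <- as.data.frame(summary(em, level = conf_level))
  prs_t <- as.data.frame(summary(emmeans::contrast(em, "pairwise"),
                                 adjust = "tukey", infer = c(TRUE, TRUE),
                                 level = conf_level))
  prs_r <- as.data.frame(summary(emmeans::contrast(em, "pairwise"),
                                 adjust = "none"))
  list(
    emmeans = tibble::tibble(
      load_condition = as.character(ems$load_condition),
      emmean = ems$emmean, se = ems$SE,
      lower = ems$lower.CL, upper = ems$upper.CL),
    contrasts = tibble::tibble(
      contrast = as.character(prs_t$contrast),
      estimate = prs_t$estimate, se = prs_t$SE,
      lower = prs_t$lower.CL, upper = prs_t$upper.CL,
      p_value = prs_r$p.value, p_adj = prs_t$p.value)
  )
}

#' Check for learning effects across trials
#'
#' Adds the (numeric) trial index as a fixed slope to the load-condition
#' model -- `response ~ load_condition + trial_index + (1 | participant)` --
#' and reports whether performance drifted across the session.
#'
#' @inheritParams fit_lme
#' @param alpha Significance level for the drift test (default 0.05).
#' @return A one-row tibble: `slope_per_trial` (deg/trial), `se`, `lower`,
#'   `upper` (95% CI), `p_value` (Wald chi-square) and `significant`.
#' @export
learning_effect_check <- function(table, response = c("mean", "sd"),
                                  alpha = 0.05) {
  response <- match.arg(response)
  one_stratum(table)
  if (length(unique(table$participant)) < 2) {
    stop("at least 2 participants are required", call. = FALSE)
  }
  df <- data.frame(
    y = if (response == "mean") table$mean_crp_deg else table$sd_crp_deg,
    load_condition = table$load_condition,
    trial_index = as.numeric(table$trial),
    participant = factor(table$participant)
  )
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lmerTest::lmer(y ~ load_condition + trial_index + (1 | participant),
                        data = df, REML = TRUE, control = ctrl)
  sm <- summary(fit)$coefficients["trial_index", ]
  est <- sm[["Estimate"]]; se <- sm[["Std. Error"]]
  chisq <- (est / se)^2
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  tibble::tibble(
    slope_per_trial = est, se = se,
    lower = est - stats::qnorm(0.975) * se,
    upper = est + stats::qnorm(0.975) * se,
    p_value = p, significant = p < alpha
  )
}

#' Classify handedness from the laterality quotient
#'
#' Edinburgh Handedness Inventory convention: LQ in \[-100, -61\] is
#' left-handed, \[-60, 60\] mixed, \[61, 100\] right-handed (boundaries
#' inclusive).
#'
#' @param lq Laterality quotient(s), each in \[-100, 100\].
#' @return Character vector: `"left"`, `"mixed"` or `"right"`.
#' @examples
#' classify_handedness(c(-80, 0, 61))
#' @export
classify_handedness <- function(lq) {
  stopifnot(is.numeric(lq))
  if (any(!is.finite(lq)) || any(lq < -100) || any(lq > 100)) {
    stop("`lq` must lie in [-100, 100]", call. = FALSE)
  }
  out <- rep("mixed", length(lq))
  out[lq <= -61] <- "left"
  out[lq >= 61] <- "right"
  out
}

#' Simulate a condition table at the summary level
#'
#' Draws per-trial mean-CRP (and SD-CRP) observations directly at the
#' summary level -- participant random intercepts plus residual noise around
#' condition means -- bypassing the kinematic simulation. Used for power and
#' calibration checks of the statistical stage (parameter recovery,
#' family-wise error under the null), where the quantity of interest is the
#' model's behaviour, not the phase dynamics.
#'
#' @param n_participants Number of participants.
#' @param seed RNG seed.
#' @param mode,cycle_ms Stratum labels (single values).
#' @param reps Trials per load condition per participant (default 5).
#' @param condition_offsets_deg Named numeric: additive offsets (degrees) for
#'   specific `"left/right"` condition labels; unnamed conditions get 0.
#' @param baseline_deg Grand mean of the response (degrees, default 6).
#' @param participant_sd_deg SD of participant random intercepts (default
#'   1.3).
#' @param trial_sd_deg SD of trial-index random intercepts (default 0).
#' @param residual_sd_deg Residual SD (default 2.2).
#' @param trend_deg_per_trial Linear drift across the session (deg/trial,
#'   default 0; used for learning-effect power checks).
#' @return A condition table as from [build_condition_table()] (the SD
#'   response is drawn with the same structure at half the scale).
#' @export
simulate_condition_table <- function(n_participants, seed,
                                     mode = "in_phase", cycle_ms = 750,
                                     reps = 5,
                                     condition_offsets_deg = c(),
                                     baseline_deg = 6,
                                     participant_sd_deg = 1.3,
                                     trial_sd_deg = 0,
                                     residual_sd_deg = 2.2,
                                     trend_deg_per_trial = 0) {
  lv <- as.vector(outer(load_types(), load_types(),
                        function(l, r) paste(l, r, sep = "/")))
  lv <- c("none/none", setdiff(lv, "none/none"))
  offs <- stats::setNames(rep(0, 9), lv)
  if (length(condition_offsets_deg) > 0) {
    bad <- setdiff(names(condition_offsets_deg), lv)
    if (length(bad) > 0) stop("unknown condition label(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    offs[names(condition_offsets_deg)] <- condition_offsets_deg
  }
  n_trials <- 9 * reps
  withr::with_seed(seed, {
    rows <- tidyr::expand_grid(
      participant = seq_len(n_participants),
      load_condition = lv,
      rep = seq_len(reps)
    )
    rows <- rows[order(rows$participant), ]
    # randomised trial order within participant
    rows$trial <- as.vector(vapply(seq_len(n_participants), function(p)
      sample.int(n_trials), integer(n_trials)))
    u_p <- stats::rnorm(n_participants, 0, participant_sd_deg)
    u_t <- stats::rnorm(n_trials, 0, trial_sd_deg)
    mu <- baseline_deg + offs[rows$load_condition] +
      u_p[rows$participant] + u_t[rows$trial] +
      trend_deg_per_trial * rows$trial
    rows$mean_crp_deg <- mu + stats::rnorm(nrow(rows), 0, residual_sd_deg)
    rows$sd_crp_deg <- abs(baseline_deg / 2 + offs[rows$load_condition] / 2 +
      u_p[rows$participant] / 2 + stats::rnorm(nrow(rows), 0,
                                               residual_sd_deg / 2))
  })
  parts <- strsplit(rows$load_condition, "/", fixed = TRUE)
  rows$load_left <- vapply(parts, `[[`, "", 1)
  rows$load_right <- vapply(parts, `[[`, "", 2)
  rows$mode <- mode
  rows$cycle_ms <- cycle_ms
  rows$deviation_deg <- abs(rows$mean_crp_deg -
                              if (mode == "anti_phase") 180 else 0)
  rows$excluded <- FALSE
  build_condition_table(rows[, c("participant", "trial", "mode", "cycle_ms",
                                 "load_left", "load_right", "mean_crp_deg",
                                 "sd_crp_deg", "deviation_deg", "excluded")])
}
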