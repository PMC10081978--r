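#' Amplitude-centre a kinematic signal
#'
#' Removes the midrange so the trace oscillates symmetrically about zero:
#' \eqn{x_c = x - \min(x) - (\max(x) - \min(x))/2}, after which
#' \eqn{\max(x_c) = -\min(x_c)}. Centring about the midrange (rather than the
#' mean) is the convention for amplitude-centring rhythmic kinematics before
#' the Hilbert transform, and leaves a symmetric sinusoid unchanged.
#'
#' @param x Numeric position trace (length >= 2, non-constant).
#' @return Centred numeric vector.
#' @examples
#' center_signal(c(0, 1, 2)) # -1 0 1
#' @export
center_signal <- function(x) {
  if (!is.numeric(x) || length(x) < 2 || !all(is.finite(x))) {
    stop("`x` must be finite numeric of length >= 2", call. = FALSE)
  }
  r <- range(x)
  if (r[1] == r[2]) {
    stop("constant trace: zero amplitude, cannot centre", call. = FALSE)
  }
  x - r[1] - (r[2] - r[1]) / 2
}

#' Analytic signal via the discrete Hilbert transform
#'
#' Constructs the analytic signal \eqn{\zeta(t) = x(t) + iH(t)} in the
#' frequency domain: the FFT of `x` has its negative-frequency half zeroed
#' and its positive-frequency half doubled (DC and Nyquist bins unchanged),
#' and the inverse transform's imaginary part is the Hilbert transform `H`.
#'
#' @param x Centred numeric trace (length >= 4; >= 64 recommended for usable
#'   edge behaviour).
#' @return A tibble with columns `x` (the input) and `h` (its Hilbert
#'   transform).
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' a <- analytic_signal(cos(2 * pi * t))
#' # h approximates sin(2 pi t) away from the edges
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  n <- length(x)
  if (n < 4) stop("trace too short for the Hilbert transform (length < 4)",
                  call. = FALSE)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * w, inverse = TRUE) / n
  tibble::tibble(x = x, h = Im(z))
}

#' Instantaneous phase angle of an analytic signal
#'
#' Per-sample angle of \eqn{\zeta = x + iH} by the four-quadrant arctangent
#' `atan2(h, x)`, unwrapped so that jumps larger than \eqn{\pi} are folded
#' into a continuous phase. Samples where both components are (numerically)
#' zero carry the previous sample's angle forward, with a message noting how
#' many were patched.
#'
#' @param x,h Real and imaginary parts of the analytic signal (equal length).
#' @param t_s Optional time vector (s) carried into the result.
#' @return A tibble with columns `t_s` (if supplied) and `phase_rad`
#'   (unwrapped, radians).
#' @export
phase_angle <- function(x, h, t_s = NULL) {
  stopifnot(is.numeric(x), is.numeric(h), length(x) == length(h))
  mag <- abs(x) + abs(h)
  zero <- mag < .Machine$double.eps * max(mag, 1)
  ang <- atan2(h, x)
  if (any(zero)) {
    idx <- which(zero)
    message(sprintf("phase_angle: %d zero-amplitude sample(s); propagating previous angle",
                    length(idx)))
    for (i in idx) ang[i] <- if (i == 1) 0 else ang[i - 1]
  }
  ang <- as.numeric(signal::unwrap(ang))
  if (is.null(t_s)) {
    tibble::tibble(phase_rad = ang)
  } else {
    stopifnot(length(t_s) == length(ang))
    tibble::tibble(t_s = t_s, phase_rad = ang)
  }
}

#' Continuous relative phase of two position traces
#'
#' The per-sample phase difference between two hands computed from their
#' analytic signals:
#' \deqn{CRP = \mathrm{atan2}(H_1 x_2 - H_2 x_1,\; x_1 x_2 + H_1 H_2),}
#' with subscript 1 the right hand and 2 the left, then folded to
#' \eqn{[0^\circ, 180^\circ]} by taking the absolute value of the angle
#' wrapped to \eqn{(-180^\circ, 180^\circ]}. 0 deg is fully in-phase motion,
#' 180 deg fully anti-phase; the lead/lag sign is discarded by the fold.
#' Both traces are amplitude-centred internally. Samples where both the
#' numerator and denominator are numerically zero (amplitude dropout) are
#' returned as `NA` and skipped by the trial summaries.
#'
#' @param x1 Right-hand position trace (raw; centred internally).
#' @param x2 Left-hand position trace.
#' @return Numeric vector of folded CRP values in degrees, in
#'   \eqn{[0, 180]} (or `NA` at dropout samples).
#' @examples
#' t <- seq(0, 30, by = 1e-3)
#' crp(sin(2 * pi * t), sin(2 * pi * t - pi))[5000] # ~180
#' @export
crp <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  a1 <- analytic_signal(center_signal(x1))
  a2 <- analytic_signal(center_signal(x2))
  num <- a1$h * a2$x - a2$h * a1$x
  den <- a1$x * a2$x + a1$h * a2$h
  mag <- abs(num) + abs(den)
  dropout <- mag < .Machine$double.eps * max(mag, 1)
  ang <- atan2(num, den)          # already in (-pi, pi]
  out <- abs(ang) * 180 / pi      # fold to [0, 180]
  out[dropout] <- NA_real_
  out
}

#' Restrict a trial to the analysis window
#'
#' Keeps samples with `start_s <= t_s < end_s` (half-open), the steady-state
#' portion of each trial analysed throughout the package (default 12--42 s,
#' i.e. exactly 30 000 samples at 1000 Hz).
#'
#' @param trial A data frame with a `t_s` column.
#' @param start_s,end_s Window bounds (s).
#' @return The windowed data frame.
#' @export
extract_window <- function(trial, start_s = 12, end_s = 42) {
  stopifnot(is.data.frame(trial), "t_s" %in% names(trial),
            start_s < end_s)
  # trial duration counts the final sample's full step
  step <- if (nrow(trial) > 1) trial$t_s[2] - trial$t_s[1] else 0
  if (max(trial$t_s) + step < end_s - 1e-9) {
    stop(sprintf("trial ends at %.3f s, before the analysis window end %.3f s",
                 max(trial$t_s) + step, end_s), call. = FALSE)
  }
  trial[trial$t_s >= start_s & trial$t_s < end_s, , drop = FALSE]
}

#' Detect a sustained phase transition
#'
#' A trial is flagged when its coordination pattern crossed into the basin of
#' the opposite mode and stayed there: the moving average of the folded CRP
#' (window `window_s`, step `step_s`) deviates from the intended phase by
#' more than `threshold_deg` in at least one window. Brief single-sample
#' excursions do not trigger the flag. Flagged trials are excluded from the
#' statistical analysis, keeping it a steady-state comparison.
#'
#' @param crp_deg Folded CRP samples (degrees).
#' @param t_s Matching time vector (s).
#' @param intended_deg Intended phase: 0 (in-phase) or 180 (anti-phase).
#' @param window_s Moving-average width (s, default 3).
#' @param step_s Step between window starts (s, default 0.5).
#' @param threshold_deg Deviation threshold (degrees, default 90: the basin
#'   boundary between the two modes).
#' @return Logical scalar; `FALSE` (with a warning) when the series is
#'   shorter than one moving window.
#' @export
detect_phase_transition <- function(crp_deg, t_s, intended_deg,
                                    window_s = 3, step_s = 0.5,
                                    threshold_deg = 90) {
  stopifnot(length(crp_deg) == length(t_s),
            intended_deg %in% c(0, 180))
  span <- max(t_s) - min(t_s)
  if (span < window_s) {
    warning("series shorter than one moving window; no transition detectable",
            call. = FALSE)
    return(FALSE)
  }
  starts <- seq(min(t_s), max(t_s) - window_s, by = step_s)
  for (s in starts) {
    idx <- t_s >= s & t_s < s + window_s
    m <- mean(crp_deg[idx], na.rm = TRUE)
    if (is.finite(m) && abs(m - intended_deg) > threshold_deg) return(TRUE)
  }
  FALSE
}

#' Summarise one trial's continuous relative phase
#'
#' The full measurement pipeline for a single trial: amplitude centring,
#' analytic signals, folded CRP, analysis window, phase-transition check,
#' then the trial's mean CRP and SD of CRP (arithmetic moments of the folded
#' samples, degrees) and its absolute deviation from the intended phase.
#' Flagged (transitioned) trials still carry their summaries but are marked
#' `excluded`.
#'
#' @param trial Kinematics data frame with columns `t_s`, `yR_m`, `yL_m`
#'   (right/left-hand oscillation-axis positions).
#' @param mode `"in_phase"` (intended 0 deg) or `"anti_phase"` (180 deg).
#' @param window Analysis window `c(start_s, end_s)` (default `c(12, 42)`).
#' @param transition_window_s,transition_step_s,transition_threshold_deg
#'   Parameters of [detect_phase_transition()].
#'
#' @return One-row tibble: `mean_crp_deg`, `sd_crp_deg`, `deviation_deg`,
#'   `excluded`, `n_samples`.
#' @export
summarize_trial <- function(trial, mode,
                            window = c(12, 42),
                            transition_window_s = 3,
                            transition_step_s = 0.5,
                            transition_threshold_deg = 90) {
  mode <- match.arg_vec(mode, c("in_phase", "anti_phase"))
  stopifnot(is.data.frame(trial),
            all(c("t_s", "yL_m", "yR_m") %in% names(trial)))
  intended <- if (mode == "anti_phase") 180 else 0
  series <- tibble::tibble(
    t_s = trial$t_s,
    crp_deg = crp(trial$yR_m, trial$yL_m)
  )
  win <- extract_window(series, window[1], window[2])
  vals <- win$crp_deg[!is.na(win$crp_deg)]
  excluded <- detect_phase_transition(
    win$crp_deg, win$t_s, intended,
    window_s = transition_window_s, step_s = transition_step_s,
    threshold_deg = transition_threshold_deg)
  m <- mean(vals)
  tibble::tibble(
    mean_crp_deg = m,
    sd_crp_deg = stats::sd(vals),
    deviation_deg = abs(m - intended),
    excluded = excluded,
    n_samples = length(vals)
  )
}

#' Summarise every trial of a generated experiment
#'
#' Maps [summarize_trial()] over the `kinematics` list-column of a
#' [generate_experiment()] result, returning one row per trial with the
#' manifest metadata attached.
#'
#' @param experiment Manifest tibble with a `kinematics` list-column and a
#'   `mode` column.
#' @inheritParams summarize_trial
#' @return Trial-summary tibble.
#' @export
summarize_trials <- function(experiment, window = c(12, 42), ...) {
  stopifnot(is.data.frame(experiment), "kinematics" %in% names(experiment),
            "mode" %in% names(experiment))
  sums <- purrr::map_dfr(seq_len(nrow(experiment)), function(i) {
    summarize_trial(experiment$kinematics[[i]], mode = experiment$mode[i],
                    window = window, ...)
  })
  meta <- experiment[, setdiff(names(experiment), "kinematics"), drop = FALSE]
  dplyr::bind_cols(meta, sums)
}
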