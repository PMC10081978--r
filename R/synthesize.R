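#' Load types and the default load-to-dynamics mapping
#'
#' Each arm can be loaded with no force field, a viscous (velocity-dependent)
#' field, or an elastic (position-dependent) field; the nine ordered
#' (left, right) pairs are the load conditions of the task. At the phase
#' level a load pair acts through an effective detuning \eqn{\Delta\omega}
#' (difference of the per-load eigenfrequency pulls) and a phase-noise
#' intensity `Q`.
#'
#' `default_dynamics_mapping()` returns the calibration shipped with the
#' package: eigenfrequency pulls 0 / -0.35 / -0.15 rad/s for none / viscous /
#' elastic, `delta_omega = pull(left) - pull(right)` (so matched pairs are
#' untuned and swapping arms flips the sign); baseline noise `q_base = 0.02`
#' rad^2/s plus per-arm increments +0.01 (viscous) and +0.02 (elastic), all
#' doubled in the anti-phase mode where coordination is intrinsically less
#' stable.
#'
#' @return A list with elements `omega_pull` (named numeric, rad/s),
#'   `q_base`, `q_increment` (named numeric, rad^2/s) and
#'   `q_antiphase_factor`.
#' @export
default_dynamics_mapping <- function() {
  list(
    omega_pull = c(none = 0, viscous = -0.35, elastic = -0.15),
    q_base = 0.02,
    q_increment = c(none = 0, viscous = 0.01, elastic = 0.02),
    q_antiphase_factor = 2
  )
}

load_types <- function() c("none", "viscous", "elastic")

check_load <- function(load, arg = deparse(substitute(load))) {
  load <- as.character(load)
  bad <- setdiff(unique(load), load_types())
  if (length(bad) > 0) {
    stop(sprintf("unknown load type(s) in `%s`: %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  load
}

#' Map a load condition to its phase-level dynamics
#'
#' Translates an ordered (left, right) load pair and coordination mode into
#' the effective detuning and phase-noise intensity that drive the stochastic
#' relative-phase simulation. Vectorised over all arguments.
#'
#' @param load_left,load_right Load on each arm: `"none"`, `"viscous"` or
#'   `"elastic"`.
#' @param mode Coordination mode, `"in_phase"` or `"anti_phase"`.
#' @param mapping Calibration list as produced by
#'   [default_dynamics_mapping()].
#'
#' @return A tibble with columns `delta_omega` (rad/s) and `q` (rad^2/s),
#'   one row per input condition.
#' @examples
#' condition_dynamics("viscous", "none", "in_phase")
#' condition_dynamics("none", "viscous", "in_phase") # sign flipped
#' @export
condition_dynamics <- function(load_left, load_right, mode = "in_phase",
                               mapping = default_dynamics_mapping()) {
  load_left <- check_load(load_left, "load_left")
  load_right <- check_load(load_right, "load_right")
  mode <- match.arg_vec(mode, c("in_phase", "anti_phase"))
  stopifnot(all(c("omega_pull", "q_base", "q_increment",
                  "q_antiphase_factor") %in% names(mapping)))
  if (!all(load_types() %in% names(mapping$omega_pull)) ||
      !all(load_types() %in% names(mapping$q_increment))) {
    stop("`mapping` must define omega_pull and q_increment for all of ",
         "none/viscous/elastic", call. = FALSE)
  }
  n <- max(length(load_left), length(load_right), length(mode))
  load_left <- rep_len(load_left, n)
  load_right <- rep_len(load_right, n)
  mode <- rep_len(mode, n)
  dw <- unname(mapping$omega_pull[load_left] - mapping$omega_pull[load_right])
  q <- mapping$q_base + unname(mapping$q_increment[load_left]) +
    unname(mapping$q_increment[load_right])
  q <- ifelse(mode == "anti_phase", q * mapping$q_antiphase_factor, q)
  tibble::tibble(delta_omega = dw, q = q)
}

match.arg_vec <- function(x, choices) {
  x <- as.character(x)
  bad <- setdiff(unique(x), choices)
  if (length(bad) > 0) {
    stop(sprintf("invalid value(s): %s (expected one of %s)",
                 paste(bad, collapse = ", "),
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Orthogonal force-field annotation
#'
#' Computes the robot force applied to a hand under a load condition. The
#' force is always orthogonal to the driving vector:
#' \deqn{F = k \begin{pmatrix} 0 & -1 \\ 1 & 0 \end{pmatrix} u,}
#' where `u` is the instantaneous velocity (viscous field, gain `k = -15`)
#' or the displacement from the start position (elastic field, gain
#' `k = +15`). With no load the force is zero. The force is an annotation of
#' what the robot would apply; it is not fed back into the synthesised
#' kinematics (load effects on behaviour enter through
#' [condition_dynamics()]).
#'
#' Note the gains are quoted as 15 N/m for both fields although a
#' velocity-dependent gain is dimensionally N s/m; the magnitude and signs
#' follow the task's published convention.
#'
#' @param trace Two-column numeric matrix or data frame: per-sample velocity
#'   (m/s, viscous) or displacement from start (m, elastic).
#' @param load `"none"`, `"viscous"` or `"elastic"`.
#' @param gain_viscous,gain_elastic Field gains (default -15, +15).
#'
#' @return A tibble with columns `fx`, `fy` (N), one row per sample. The dot
#'   product of each force with its driving vector is exactly zero.
#' @examples
#' force_field(cbind(1, 0), "viscous") # (0, -15)
#' @export
force_field <- function(trace, load, gain_viscous = -15, gain_elastic = 15) {
  load <- check_load(load, "load")
  stopifnot(length(load) == 1)
  m <- as.matrix(trace)
  if (ncol(m) != 2 || !is.numeric(m) || !all(is.finite(m))) {
    stop("`trace` must be a finite numeric 2-column matrix/data frame",
         call. = FALSE)
  }
  k <- switch(load, none = 0, viscous = gain_viscous, elastic = gain_elastic)
  # rotation by +90 degrees: (u, v) -> (-v, u), then scaled by k
  tibble::tibble(fx = -k * m[, 2], fy = k * m[, 1])
}

#' Render a relative-phase trajectory into two-hand kinematics
#'
#' Converts a simulated relative-phase trajectory into robot-style per-hand
#' position and velocity traces. The common rhythm is
#' \eqn{\theta(t) = 2\pi t / T} with period `cycle_ms`; the left hand moves
#' as \eqn{y_L = (A/2)\sin\theta} and the right hand as
#' \eqn{y_R = (A/2)\sin(\theta - \phi(t))}, so the instantaneous phase lead
#' of the left hand over the right equals \eqn{\phi(t)}. Oscillation is along
#' the y axis (targets above/below the start position); x is constant with
#' the hands laterally separated. Velocities are the analytic derivatives of
#' the noiseless positions; optional white measurement noise (default SD
#' 0.5 mm, the spatial resolution scale of the recording device) is added to
#' positions only.
#'
#' @param phi A data frame with columns `t_s`, `phi_rad` as returned by
#'   [simulate_phase()], or a numeric vector of phase values (rad) sampled at
#'   `fs`.
#' @param cycle_ms Movement period (ms); the task uses 750 (fast) and 1200
#'   (slow).
#' @param amplitude_cm Peak-to-peak excursion (cm, default 10).
#' @param fs Sampling rate (Hz); required when `phi` is a bare vector,
#'   otherwise inferred from `t_s`.
#' @param noise_sd_m SD of additive position noise (m, default 5e-4; set 0
#'   for noiseless traces).
#' @param hand_offset_m Lateral half-separation of the hands (m, default
#'   0.15).
#' @param seed Optional seed for the measurement noise.
#'
#' @return A tibble with columns `t_s`, `xL_m`, `yL_m`, `xR_m`, `yR_m`,
#'   `vxL_m_s`, `vyL_m_s`, `vxR_m_s`, `vyR_m_s`.
#' @examples
#' ph <- simulate_phase(hkb_params(1, 1), Q = 0, phi0 = 0,
#'                      fs = 500, duration_s = 2)
#' kin <- synthesize_kinematics(ph, cycle_ms = 750, noise_sd_m = 0)
#' all.equal(kin$yL_m, kin$yR_m) # in-phase: identical traces
#' @export
synthesize_kinematics <- function(phi, cycle_ms, amplitude_cm = 10,
                                  fs = NULL, noise_sd_m = 5e-4,
                                  hand_offset_m = 0.15, seed = NULL) {
  if (is.data.frame(phi)) {
    stopifnot(all(c("t_s", "phi_rad") %in% names(phi)))
    t <- phi$t_s
    ph <- phi$phi_rad
  } else {
    stopifnot(is.numeric(phi))
    if (is.null(fs)) stop("`fs` is required when `phi` is a bare vector",
                          call. = FALSE)
    ph <- phi
    t <- (seq_along(ph) - 1L) / fs
  }
  stopifnot(is.numeric(cycle_ms), length(cycle_ms) == 1, cycle_ms > 0,
            is.numeric(amplitude_cm), amplitude_cm > 0,
            is.numeric(noise_sd_m), noise_sd_m >= 0)
  n <- length(ph)
  if (n < 2) stop("phase trajectory too short", call. = FALSE)
  A2 <- amplitude_cm / 100 / 2           # half peak-to-peak, metres
  omega <- 2 * pi / (cycle_ms / 1000)    # rad/s
  theta <- omega * t
  yL <- A2 * sin(theta)
  yR <- A2 * sin(theta - ph)
  # analytic derivatives; phi treated as slowly varying relative to theta,
  # its numerical derivative is included for exactness
  dphi <- c(diff(ph), 0) / c(diff(t), Inf)
  dphi[n] <- dphi[n - 1L]
  vyL <- A2 * omega * cos(theta)
  vyR <- A2 * (omega - dphi) * cos(theta - ph)
  if (noise_sd_m > 0) {
    gen <- function() list(l = stats::rnorm(n, 0, noise_sd_m),
                           r = stats::rnorm(n, 0, noise_sd_m))
    eps <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
    yL <- yL + eps$l
    yR <- yR + eps$r
  }
  tibble::tibble(
    t_s = t,
    xL_m = -hand_offset_m, yL_m = yL,
    xR_m = hand_offset_m, yR_m = yR,
    vxL_m_s = 0, vyL_m_s = vyL,
    vxR_m_s = 0, vyR_m_s = vyR
  )
}

#' Lay out the factorial experiment design
#'
#' Builds the trial manifest for a full experiment: per participant and per
#' coordination mode, 9 load conditions x 2 cycling frequencies x `reps`
#' repetitions (= 90 trials at the default `reps = 5`) in a seeded random
#' order. Per-participant random effects -- a baseline phase offset (SD 2
#' degrees) and a noise multiplier (1 +/- 0.2, truncated positive) -- are
#' drawn once per participant. Each trial receives its own derived RNG seed
#' so that trials can be generated independently and reproducibly.
#'
#' @param n_participants Number of simulated participants (>= 1).
#' @param seed Master seed; the manifest and all downstream trials are fully
#'   determined by it.
#' @param modes Coordination modes included (default both).
#' @param cycle_ms Cycling periods included (ms, default `c(750, 1200)`).
#' @param loads Per-arm load types crossed into ordered pairs (default all
#'   three).
#' @param reps Repetitions per (load pair x cycle) cell (default 5).
#' @param participant_offset_sd_deg SD of the per-participant baseline phase
#'   offset (degrees, default 2).
#' @param participant_noise_mult_sd SD of the per-participant noise
#'   multiplier around 1 (default 0.2).
#' @param mapping Load-to-dynamics calibration, see
#'   [default_dynamics_mapping()].
#'
#' @return A tibble with one row per trial: `participant`, `mode`, `trial`
#'   (index within participant x mode), `cycle_ms`, `load_left`,
#'   `load_right`, `delta_omega`, `q` (after the participant's noise
#'   multiplier), `phi_offset_rad`, `trial_seed`.
#' @examples
#' d <- experiment_design(1, seed = 1)
#' nrow(d) # 180
#' @export
experiment_design <- function(n_participants, seed,
                              modes = c("in_phase", "anti_phase"),
                              cycle_ms = c(750, 1200),
                              loads = load_types(),
                              reps = 5,
                              participant_offset_sd_deg = 2,
                              participant_noise_mult_sd = 0.2,
                              mapping = default_dynamics_mapping()) {
  stopifnot(n_participants >= 1, reps >= 1, length(cycle_ms) >= 1)
  modes <- match.arg_vec(modes, c("in_phase", "anti_phase"))
  loads <- check_load(loads, "loads")
  cells <- tidyr::expand_grid(
    load_left = loads, load_right = loads, cycle_ms = cycle_ms,
    rep = seq_len(reps)
  )
  withr::with_seed(seed, {
    design <- purrr::map_dfr(seq_len(n_participants), function(pid) {
      offset <- stats::rnorm(1, 0, participant_offset_sd_deg * pi / 180)
      mult <- abs(stats::rnorm(1, 1, participant_noise_mult_sd))
      purrr::map_dfr(modes, function(md) {
        ord <- sample.int(nrow(cells))
        trials <- cells[ord, ]
        trials$participant <- pid
        trials$mode <- md
        trials$trial <- seq_len(nrow(trials))
        trials$phi_offset_rad <- offset
        trials$noise_mult <- mult
        trials
      })
    })
    dyn <- condition_dynamics(design$load_left, design$load_right,
                              design$mode, mapping)
    design$delta_omega <- dyn$delta_omega
    design$q <- dyn$q * design$noise_mult^2
    design$trial_seed <- sample.int(.Machine$integer.max, nrow(design))
    design[, c("participant", "mode", "trial", "cycle_ms", "load_left",
               "load_right", "delta_omega", "q", "phi_offset_rad",
               "trial_seed")]
  })
}

#' Generate one synthetic trial
#'
#' Simulates the stochastic relative-phase trajectory for one manifest row
#' (intended phase 0 for in-phase, pi for anti-phase, plus the participant's
#' baseline offset added to the rendered phase) and renders it into two-hand
#' kinematics.
#'
#' @param trial_row One row of an [experiment_design()] manifest (data frame
#'   or list with the manifest columns).
#' @param params An [hkb_params()] object giving the coupling strengths; the
#'   detuning is taken from the manifest row.
#' @param duration_s Trial length (s, default 45; must cover the 12--42 s
#'   analysis window).
#' @param fs Sampling rate (Hz, default 1000).
#' @param amplitude_cm Peak-to-peak excursion (cm, default 10).
#' @param noise_sd_m Measurement noise SD (m, default 5e-4).
#'
#' @return A kinematics tibble as from [synthesize_kinematics()].
#' @export
generate_trial <- function(trial_row, params = hkb_params(),
                           duration_s = 45, fs = 1000,
                           amplitude_cm = 10, noise_sd_m = 5e-4) {
  tr <- as.list(trial_row)
  if (duration_s < 42) {
    stop("`duration_s` must be >= 42 s so the 12-42 s analysis window exists",
         call. = FALSE)
  }
  p <- hkb_params(params$a, params$b, delta_omega = tr$delta_omega)
  phi0 <- if (tr$mode == "anti_phase") pi else 0
  ph <- simulate_phase(p, Q = tr$q, phi0 = phi0, fs = fs,
                       duration_s = duration_s, seed = tr$trial_seed)
  ph$phi_rad <- ph$phi_rad + (tr$phi_offset_rad %||% 0)
  synthesize_kinematics(ph, cycle_ms = tr$cycle_ms,
                        amplitude_cm = amplitude_cm,
                        noise_sd_m = noise_sd_m,
                        seed = tr$trial_seed + 1L)
}

#' Generate a full synthetic experiment
#'
#' Runs [experiment_design()] and [generate_trial()] for every trial,
#' returning the manifest with a `kinematics` list-column. For large designs
#' prefer [run_experiment()], which summarises trials as they are generated
#' instead of holding all traces in memory.
#'
#' @inheritParams experiment_design
#' @inheritParams generate_trial
#' @param ... Passed to [experiment_design()].
#'
#' @return The manifest tibble with an added `kinematics` list-column.
#' @export
generate_experiment <- function(n_participants, seed,
                                params = hkb_params(),
                                duration_s = 45, fs = 1000,
                                amplitude_cm = 10, noise_sd_m = 5e-4, ...) {
  design <- experiment_design(n_participants, seed, ...)
  design$kinematics <- purrr::map(seq_len(nrow(design)), function(i) {
    generate_trial(design[i, ], params = params, duration_s = duration_s,
                   fs = fs, amplitude_cm = amplitude_cm,
                   noise_sd_m = noise_sd_m)
  })
  design
}

#' Generate and summarise an experiment without storing kinematics
#'
#' Streams the synthetic experiment through the measurement pipeline: each
#' trial is generated, reduced to its continuous-relative-phase summary, and
#' discarded. This is the memory-safe path for full-scale designs.
#'
#' @inheritParams generate_experiment
#' @param window Analysis window `c(start_s, end_s)` (default `c(12, 42)`).
#'
#' @return A trial-summary tibble, one row per trial (see
#'   [summarize_trial()]), with the manifest metadata columns attached.
#' @export
run_experiment <- function(n_participants, seed,
                           params = hkb_params(),
                           duration_s = 45, fs = 1000,
                           amplitude_cm = 10, noise_sd_m = 5e-4,
                           window = c(12, 42), ...) {
  design <- experiment_design(n_participants, seed, ...)
  sums <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    kin <- generate_trial(design[i, ], params = params,
                          duration_s = duration_s, fs = fs,
                          amplitude_cm = amplitude_cm,
                          noise_sd_m = noise_sd_m)
    summarize_trial(kin, mode = design$mode[i], window = window)
  })
  dplyr::bind_cols(
    design[, c("participant", "mode", "trial", "cycle_ms",
               "load_left", "load_right", "delta_omega", "q")],
    sums
  )
}
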