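# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own code paths: derivatives by central differences,
# roots by base-R uniroot on a sign-change scan.

`%||%` <- function(a, b) if (is.null(a)) b else a

fd_deriv <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

fd_second <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# all roots of f on [lo, hi] by dense sign-change scan + uniroot
scan_roots <- function(f, lo = -pi, hi = pi, n = 1e5, tol = 1e-12) {
  xs <- seq(lo, hi, length.out = n)
  fs <- f(xs)
  roots <- xs[abs(fs) < 1e-13]
  ch <- which(fs[-1] * fs[-n] < 0)
  for (i in ch) {
    roots <- c(roots, stats::uniroot(f, c(xs[i], xs[i + 1]),
                                     tol = tol)$root)
  }
  sort(unique(round(roots, 9)))
}

# empirical Kolmogorov-Smirnov distance against a numeric CDF function
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# smooth band-limited random signal: sum of 3 sinusoids (0.5-2 Hz, random
# phases and amplitudes) plus small white noise
random_band_signal <- function(t) {
  f <- stats::runif(3, 0.5, 2)
  ph <- stats::runif(3, 0, 2 * pi)
  amp <- stats::runif(3, 0.2, 1)
  rowSums(sapply(1:3, function(k) amp[k] * sin(2 * pi * f[k] * t + ph[k]))) +
    stats::rnorm(length(t), 0, 0.01)
}

# render a constant-relative-phase two-hand trial directly from sinusoids
sinusoid_trial <- function(phi_deg, cycle_ms = 750, duration_s = 45,
                           fs = 1000, amp_m = 0.05) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  th <- 2 * pi * t / (cycle_ms / 1000)
  tibble::tibble(
    t_s = t,
    xL_m = -0.15, yL_m = amp_m * sin(th),
    xR_m = 0.15, yR_m = amp_m * sin(th - phi_deg * pi / 180)
  )
}

# minimal valid trial-summary frame for the stats stage
make_summaries <- function(n_participants = 5, reps = 5,
                           modes = c("in_phase", "anti_phase"),
                           cycles = c(750, 1200)) {
  loads <- c("none", "viscous", "elastic")
  g <- tidyr::expand_grid(
    participant = seq_len(n_participants), mode = modes, cycle_ms = cycles,
    load_left = loads, load_right = loads, rep = seq_len(reps))
  g <- dplyr::group_by(g, participant, mode)
  g <- dplyr::mutate(g, trial = dplyr::row_number())
  g <- dplyr::ungroup(g)
  g$mean_crp_deg <- ifelse(g$mode == "anti_phase", 170, 6)
  g$sd_crp_deg <- 3
  g$deviation_deg <- abs(g$mean_crp_deg - ifelse(g$mode == "anti_phase",
                                                 180, 0))
  g$excluded <- FALSE
  g[, c("participant", "trial", "mode", "cycle_ms", "load_left",
        "load_right", "mean_crp_deg", "sd_crp_deg", "deviation_deg",
        "excluded")]
}
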