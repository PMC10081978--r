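test_that("amplitude centring removes the midrange exactly", {
  expect_equal(center_signal(c(0, 1, 2)), c(-1, 0, 1))
  t <- seq(0, 10, by = 1e-3)
  s <- sin(2 * pi * t[-length(t)]) # whole cycles, already symmetric
  expect_equal(center_signal(s), s, tolerance = 1e-12)
  expect_equal(center_signal(s + 5), s, tolerance = 1e-12)
  cen <- center_signal(c(0.3, 2.1, -1.4, 0.9))
  expect_equal(max(cen), -min(cen))
  expect_error(center_signal(rep(1, 10)), "constant")
  expect_error(center_signal(3), "length")
})

test_that("the analytic signal reproduces closed-form quadrature pairs", {
  t <- (0:(30 * 1000 - 1)) / 1000
  interior <- t >= 1 & t <= 29
  ac <- analytic_signal(cos(2 * pi * t))
  expect_lt(max(abs(ac$h - sin(2 * pi * t))[interior]), 0.01)
  as_ <- analytic_signal(sin(2 * pi * 1.5 * t))
  expect_lt(max(abs(as_$h + cos(2 * pi * 1.5 * t))[interior]), 0.01)
  # exact linearity in the amplitude
  x <- sin(2 * pi * t[1:2000])
  expect_equal(analytic_signal(2.5 * x)$h, 2.5 * analytic_signal(x)$h)
  expect_error(analytic_signal(c(1, 2, 3)), "length")
})

test_that("phase angles recover the generating angle and unwrap cleanly", {
  expect_equal(phase_angle(1, 0)$phase_rad, 0)
  expect_equal(phase_angle(0, 1)$phase_rad, pi / 2)
  expect_equal(phase_angle(-1, 0)$phase_rad, pi)
  th <- seq(0, 40, by = 0.01) # many wraps
  pa <- phase_angle(cos(th), sin(th))
  expect_equal(pa$phase_rad, th, tolerance = 1e-9)
  slope <- diff(pa$phase_rad) / 0.01
  expect_equal(mean(slope), 1, tolerance = 1e-9)
  # positive scaling leaves the angle untouched
  expect_equal(phase_angle(3 * cos(th), 3 * sin(th))$phase_rad, pa$phase_rad)
  # zero-amplitude samples propagate the previous angle
  expect_message(pz <- phase_angle(c(1, 0, 1), c(0, 0, 0)), "zero-amplitude")
  expect_equal(pz$phase_rad, c(0, 0, 0))
})

test_that("CRP hits its definitional values for canonical lags", {
  t <- (0:(45 * 1000 - 1)) / 1000
  x <- 0.05 * sin(2 * pi * t)
  interior <- t >= 12.5 & t < 41.5
  expect_lt(max(abs(crp(x, x)[interior])), 0.5)
  expect_lt(max(abs(crp(x, -x)[interior] - 180)), 0.5)
  lag <- 0.05 * sin(2 * pi * t - pi / 2)
  expect_lt(max(abs(crp(x, lag)[interior] - 90)), 0.5)
})

test_that("CRP is symmetric under hand swap and amplitude-invariant", {
  t <- (0:(20 * 500 - 1)) / 500
  x1 <- sin(2 * pi * 1.2 * t + 0.3)
  x2 <- sin(2 * pi * 1.2 * t - 0.8)
  expect_equal(crp(x1, x2), crp(x2, x1), tolerance = 1e-9)
  expect_equal(crp(3.7 * x1, x2), crp(x1, x2), tolerance = 1e-9)
  expect_equal(crp(x1, 0.01 * x2), crp(x1, x2), tolerance = 1e-9)
})

test_that("the analysis window is half-open and exact", {
  trial <- sinusoid_trial(0, duration_s = 45)
  win <- extract_window(trial)
  expect_equal(nrow(win), 30000)
  expect_gte(min(win$t_s), 12)
  expect_lt(max(win$t_s), 42)
  expect_equal(nrow(extract_window(trial, 0, 45)), nrow(trial))
  short <- sinusoid_trial(0, duration_s = 40)
  expect_error(extract_window(short), "40")
})

test_that("sustained basin crossings are flagged, transients are not", {
  t <- seq(12, 42, by = 0.01)
  expect_false(detect_phase_transition(rep(175, length(t)), t, 180))
  ramp <- ifelse(t < 27, 180, 5)
  expect_true(detect_phase_transition(ramp, t, 180))
  spike <- rep(178, length(t)); spike[1500] <- 0
  expect_false(detect_phase_transition(spike, t, 180))
  drop0 <- rep(3, length(t))
  expect_false(detect_phase_transition(drop0, t, 0))
  expect_warning(out <- detect_phase_transition(rep(10, 5), seq(0, 1, length.out = 5), 0),
                 "shorter")
  expect_false(out)
})

test_that("trial summaries recover constructed phase relations", {
  s0 <- summarize_trial(sinusoid_trial(0), "in_phase")
  expect_lt(s0$mean_crp_deg, 0.5)
  expect_lt(s0$sd_crp_deg, 0.5)
  expect_false(s0$excluded)
  expect_equal(s0$n_samples, 30000)

  s170 <- summarize_trial(sinusoid_trial(170), "anti_phase")
  expect_equal(s170$mean_crp_deg, 170, tolerance = 0.5)
  expect_equal(s170$deviation_deg, 10, tolerance = 0.5)

  # a rendered anti-phase trial that settles into in-phase is flagged
  ph <- simulate_phase(hkb_params(1, 1), Q = 0, phi0 = 1.5, fs = 1000,
                       duration_s = 45)
  kin <- synthesize_kinematics(ph, cycle_ms = 750, noise_sd_m = 0)
  str <- summarize_trial(kin, "anti_phase")
  expect_true(str$excluded)
})

test_that("the pipeline round-trips noiseless synthesized trials within 1 degree RMS", {
  p <- hkb_params(1, 1, delta_omega = 0.4)
  for (start in c(0.35, pi - 0.3)) {
    ph <- simulate_phase(p, Q = 0, phi0 = start, fs = 1000, duration_s = 45)
    kin <- synthesize_kinematics(ph, cycle_ms = 1200, noise_sd_m = 0)
    measured <- crp(kin$yR_m, kin$yL_m)
    truth <- abs(((ph$phi_rad * 180 / pi + 180) %% 360) - 180)
    sel <- ph$t_s >= 12.5 & ph$t_s < 41.5
    rms <- sqrt(mean((measured[sel] - truth[sel])^2))
    expect_lt(rms, 1)
  }
})

test_that("simulated variability near the anti-phase attractor matches the small-noise oracle", {
  p <- hkb_params(1, 1)
  pred_deg <- sqrt(0.005 / 6) * 180 / pi # sqrt(Q / 2 curvature(pi))
  res <- vapply(1:20, function(i) {
    ph <- simulate_phase(p, Q = 0.005, phi0 = pi, fs = 1000,
                         duration_s = 45, seed = 100 + i)
    win <- ph[ph$t_s >= 12 & ph$t_s < 42, ]
    kin <- synthesize_kinematics(ph, cycle_ms = 750, noise_sd_m = 0)
    c(phase = sd(win$phi_rad) * 180 / pi,
      measured = summarize_trial(kin, "anti_phase")$sd_crp_deg)
  }, numeric(2))
  # the phase trajectory itself obeys the Ornstein-Uhlenbeck prediction
  expect_equal(mean(res["phase", ]), pred_deg, tolerance = 0.25)
  # the Hilbert measurement low-passes fast phase jitter, so the measured
  # SD is attenuated relative to the generating process, never inflated
  expect_lt(mean(res["measured", ]), mean(res["phase", ]))
  expect_gt(mean(res["measured", ]), 0.3 * pred_deg)
})

test_that("summarize_trials maps over a generated experiment", {
  ex <- generate_experiment(1, seed = 8, modes = "in_phase", cycle_ms = 750,
                            loads = c("none", "viscous"), reps = 1)
  sums <- summarize_trials(ex)
  expect_equal(nrow(sums), 4)
  expect_true(all(c("mean_crp_deg", "sd_crp_deg", "deviation_deg",
                    "excluded", "load_left") %in% names(sums)))
})
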