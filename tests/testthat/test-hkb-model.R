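test_that("potential and curvature take their closed-form values", {
  p <- hkb_params(1, 1)
  expect_equal(hkb_potential(0, p), -2)
  expect_equal(hkb_potential(pi, p), 0)
  expect_equal(hkb_potential(pi / 2, p), 1)
  expect_equal(hkb_curvature(0, p), 5)
  expect_equal(hkb_curvature(pi, p), 3)
  expect_equal(hkb_drift(0, p), 0)
  expect_equal(hkb_drift(pi, p), 0, tolerance = 1e-14)
})

test_that("drift is the negative gradient of the potential", {
  for (pars in list(hkb_params(1, 1), hkb_params(0.7, 0.2, 0.3),
                    hkb_params(2, 0.05, -0.8))) {
    grid <- seq(-pi, pi, length.out = 100)
    num <- -fd_deriv(function(x) hkb_potential(x, pars), grid)
    expect_equal(hkb_drift(grid, pars), num, tolerance = 1e-6)
  }
})

test_that("curvature matches the second central difference of the potential", {
  pars <- hkb_params(1.3, 0.6, 0.2)
  grid <- seq(-pi, pi, length.out = 80)
  num <- fd_second(function(x) hkb_potential(x, pars), grid)
  expect_equal(hkb_curvature(grid, pars), num, tolerance = 1e-6)
})

test_that("with no detuning the potential is even and 2*pi-periodic", {
  pars <- hkb_params(0.9, 0.4)
  grid <- seq(-pi, pi, length.out = 64)
  expect_equal(hkb_potential(grid, pars), hkb_potential(-grid, pars))
  expect_equal(hkb_potential(grid, pars), hkb_potential(grid + 2 * pi, pars),
               tolerance = 1e-12)
})

test_that("fixed points match an independent uniroot scan oracle", {
  # symmetric landscape: stable 0 and pi, unstable at +/- acos(-1/4)
  p <- hkb_params(1, 1)
  fps <- hkb_fixed_points(p)
  oracle <- scan_roots(function(x) hkb_drift(x, p))
  oracle <- oracle[oracle > -pi + 1e-9] # (-pi, pi]: -pi duplicates pi
  expect_equal(fps$phi_star, oracle, tolerance = 1e-8)
  expect_equal(sort(fps$phi_star[fps$stable]), c(0, pi), tolerance = 1e-8)
  expect_equal(sort(abs(fps$phi_star[!fps$stable])),
               rep(acos(-1 / 4), 2), tolerance = 1e-8)
  # fixed-point set symmetric about 0 (pi maps to itself mod 2*pi)
  wrapped <- ((-fps$phi_star + pi) %% (2 * pi)) - pi
  wrapped[wrapped <= -pi + 1e-9] <- pi
  expect_equal(sort(wrapped), sort(fps$phi_star), tolerance = 1e-8)
})

test_that("anti-phase loses stability when b/a drops below 1/4", {
  fps <- hkb_fixed_points(hkb_params(1, 0.1))
  at_pi <- fps[abs(fps$phi_star - pi) < 1e-6, ]
  expect_false(at_pi$stable)
  expect_equal(at_pi$curvature, -0.6, tolerance = 1e-8)
  at_0 <- fps[abs(fps$phi_star) < 1e-6, ]
  expect_true(at_0$stable)
  for (b in c(0.05, 0.2, 0.24)) {
    fps <- hkb_fixed_points(hkb_params(1, b))
    expect_false(fps$stable[which.min(abs(fps$phi_star - pi))],
                 label = sprintf("pi unstable at b = %g", b))
  }
  # and the in-phase well is always the stiffer attractor
  for (i in 1:5) {
    a <- 0.2 + i / 3; b <- 0.3 + i / 7
    expect_gt(hkb_curvature(0, hkb_params(a, b)),
              hkb_curvature(pi, hkb_params(a, b)))
  }
})

test_that("detuning shifts the in-phase attractor to the oracle root", {
  p <- hkb_params(1, 1, delta_omega = 0.5)
  fps <- hkb_fixed_points(p)
  near0 <- fps[which.min(abs(fps$phi_star)), ]
  oracle <- uniroot(function(x) 0.5 - sin(x) - 2 * sin(2 * x),
                    c(0, 0.5), tol = 1e-14)$root
  expect_true(near0$stable)
  expect_equal(near0$phi_star, oracle, tolerance = 1e-8)
  expect_true(all(abs(hkb_drift(fps$phi_star, p)) < 1e-10))
  # drift residual contract holds on every root of every landscape tried
  for (dw in c(-1, -0.2, 0, 0.7)) {
    fps <- hkb_fixed_points(hkb_params(0.8, 0.5, dw))
    expect_true(all(abs(hkb_drift(fps$phi_star, hkb_params(0.8, 0.5, dw)))
                    < 1e-10))
    expect_false(is.unsorted(fps$phi_star))
  }
})

test_that("excessive detuning yields no stationary phase (empty set)", {
  fps <- hkb_fixed_points(hkb_params(1, 1, delta_omega = 10))
  expect_equal(nrow(fps), 0)
})

test_that("small-noise SD prediction follows sqrt(Q / 2k)", {
  p <- hkb_params(1, 1)
  fps <- hkb_fixed_points(p)
  fp0 <- fps[fps$phi_star == 0, ]
  expect_equal(hkb_predicted_sd(p, Q = 0.01, fp0), sqrt(0.001))
  # ratio of anti-phase to in-phase variability
  fppi <- fps[abs(fps$phi_star - pi) < 1e-9, ]
  expect_equal(hkb_predicted_sd(p, 0.02, fppi) / hkb_predicted_sd(p, 0.02, fp0),
               sqrt(5 / 3))
  # vanishing noise limit
  expect_lt(hkb_predicted_sd(p, 1e-12, fp0), 1e-6)
  # unstable points rejected
  unst <- fps[!fps$stable, ][1, ]
  expect_error(hkb_predicted_sd(p, 0.01, unst), "stable")
})

test_that("degenerate or non-finite parameters are rejected", {
  expect_error(hkb_params(-1, 1), "non-negative")
  expect_error(hkb_params(0, 0), "strictly positive")
  expect_error(hkb_params(1, 1, Inf))
  expect_error(hkb_potential(NA_real_, hkb_params(1, 1)), "finite")
})
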