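#' Extended HKB model parameters
#'
#' Bundles the coupling strengths of the Haken--Kelso--Bunz (HKB) relative
#' phase potential together with a detuning (symmetry breaking) term. The
#' potential is
#' \deqn{V(\phi) = -\Delta\omega\,\phi - a\cos\phi - b\cos 2\phi,}
#' whose wells at \eqn{\phi = 0} (in-phase) and \eqn{\phi = \pi} (anti-phase)
#' encode the two stable bimanual coordination modes. With `delta_omega = 0`
#' the landscape is symmetric; a nonzero detuning, reflecting different
#' eigenfrequencies of the two limbs, tilts it and shifts the attractors.
#'
#' @param a In-phase coupling strength (1/s, >= 0).
#' @param b Anti-phase coupling strength (1/s, >= 0).
#' @param delta_omega Detuning \eqn{\Delta\omega} (rad/s, any sign).
#'
#' @return An object of class `hkb_params`: a named list with elements
#'   `a`, `b`, `delta_omega`.
#'
#' @details At least one of `a`, `b` must be strictly positive so that the
#'   landscape is nondegenerate. All angles in this package are radians
#'   internally; degrees appear only in reported summaries.
#'
#' @examples
#' p <- hkb_params(a = 1, b = 1)
#' hkb_potential(pi, p)
#' @export
hkb_params <- function(a = 1, b = 1, delta_omega = 0) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a),
            is.numeric(b), length(b) == 1, is.finite(b),
            is.numeric(delta_omega), length(delta_omega) == 1,
            is.finite(delta_omega))
  if (a < 0 || b < 0) {
    stop("coupling strengths `a` and `b` must be non-negative", call. = FALSE)
  }
  if (a == 0 && b == 0) {
    stop("at least one of `a`, `b` must be strictly positive", call. = FALSE)
  }
  structure(list(a = a, b = b, delta_omega = delta_omega),
            class = "hkb_params")
}

#' @export
print.hkb_params <- function(x, ...) {
  cat(sprintf(
    "<hkb_params> a = %g 1/s, b = %g 1/s, delta_omega = %g rad/s\n",
    x$a, x$b, x$delta_omega))
  invisible(x)
}

check_hkb_params <- function(params) {
  if (!inherits(params, "hkb_params")) {
    if (is.list(params) && all(c("a", "b") %in% names(params))) {
      params <- hkb_params(params$a, params$b,
                           params$delta_omega %||% 0)
    } else {
      stop("`params` must be created by hkb_params()", call. = FALSE)
    }
  }
  params
}

check_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) == 0 || !all(is.finite(phi))) {
    stop("`phi` must be finite numeric (radians)", call. = FALSE)
  }
  phi
}

#' HKB potential, drift and curvature
#'
#' `hkb_potential()` evaluates the tilted two-mode potential
#' \eqn{V(\phi) = -\Delta\omega\phi - a\cos\phi - b\cos 2\phi}.
#' `hkb_drift()` is the overdamped (gradient) phase dynamics
#' \eqn{\dot\phi = -V'(\phi) = \Delta\omega - a\sin\phi - 2b\sin 2\phi}.
#' `hkb_curvature()` is \eqn{V''(\phi) = a\cos\phi + 4b\cos 2\phi}; its sign
#' at a stationary point decides stability (positive = attractor).
#'
#' @param phi Relative phase (radians); vectorised.
#' @param params An [hkb_params()] object.
#'
#' @return Numeric vector the length of `phi`.
#' @examples
#' p <- hkb_params(1, 1)
#' hkb_potential(c(0, pi / 2, pi), p)
#' hkb_drift(0.3, p)
#' hkb_curvature(0, p) # a + 4b
#' @export
hkb_potential <- function(phi, params) {
  params <- check_hkb_params(params)
  phi <- check_phi(phi)
  -params$delta_omega * phi - params$a * cos(phi) - params$b * cos(2 * phi)
}

#' @rdname hkb_potential
#' @export
hkb_drift <- function(phi, params) {
  params <- check_hkb_params(params)
  phi <- check_phi(phi)
  params$delta_omega - params$a * sin(phi) - 2 * params$b * sin(2 * phi)
}

#' @rdname hkb_potential
#' @export
hkb_curvature <- function(phi, params) {
  params <- check_hkb_params(params)
  phi <- check_phi(phi)
  params$a * cos(phi) + 4 * params$b * cos(2 * phi)
}

#' Stationary points of the HKB phase dynamics
#'
#' Finds all zeros of the drift \eqn{\Delta\omega - a\sin\phi - 2b\sin 2\phi}
#' on the half-open interval \eqn{(-\pi, \pi]} by a sign-change scan on a
#' dense grid followed by bisection, and classifies each root by the sign of
#' the curvature \eqn{V''}.
#'
#' @param params An [hkb_params()] object.
#' @param n_grid Number of scan points (default 4096).
#' @param tol Bisection tolerance on \eqn{\phi} (default 1e-12).
#'
#' @return A tibble with one row per stationary point, sorted by `phi_star`:
#'   columns `phi_star` (rad, in \eqn{(-\pi, \pi]}), `stable` (logical,
#'   `curvature > 0`) and `curvature` (1/s). Zero rows when the detuning is
#'   too large for entrainment (no stationary phase exists: phase wrapping).
#'
#' @examples
#' hkb_fixed_points(hkb_params(1, 1))        # 0 and pi stable
#' hkb_fixed_points(hkb_params(1, 0.1))      # pi has lost stability
#' hkb_fixed_points(hkb_params(1, 1, delta_omega = 10))  # empty: wrapping
#' @export
hkb_fixed_points <- function(params, n_grid = 4096, tol = 1e-12) {
  params <- check_hkb_params(params)
  stopifnot(n_grid >= 8, tol > 0)
  # scan the closed interval; grid endpoints chosen so that the canonical
  # roots 0 and pi fall on grid nodes when delta_omega = 0
  grid <- seq(-pi, pi, length.out = n_grid + 1)
  f <- hkb_drift(grid, params)
  roots <- numeric(0)
  # (near-)exact hits on grid nodes; the scaled tolerance catches roots such
  # as phi = pi where sin() is zero only to machine precision and the drift
  # does not change sign inside the scan interval
  hit <- which(abs(f) < 1e-12 * max(abs(f)))
  roots <- c(roots, grid[hit])
  # sign changes between adjacent nodes
  sgn <- sign(f)
  change <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in change) {
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- f[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- hkb_drift(mid, params)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  # wrap to (-pi, pi]: -pi maps to pi
  roots[roots <= -pi + tol] <- pi
  roots <- sort(unique(round(roots / tol) * tol))
  # de-duplicate roots that coincide within a few grid tolerances
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-8)
    roots <- roots[keep]
    if (length(roots) > 1 &&
        abs((roots[length(roots)] - 2 * pi) - roots[1]) < 1e-8) {
      roots <- roots[-length(roots)]
    }
  }
  if (length(roots) == 0) {
    # detuning too strong for entrainment: running phase, no stationary state
    return(tibble::tibble(phi_star = numeric(0), stable = logical(0),
                          curvature = numeric(0)))
  }
  curv <- hkb_curvature(roots, params)
  tibble::tibble(phi_star = roots, stable = curv > 0, curvature = curv)
}

#' Small-noise prediction of stationary phase variability
#'
#' Linearised Ornstein--Uhlenbeck approximation of the stochastic phase
#' dynamics around a stable attractor: for noise intensity `Q` and local
#' stiffness \eqn{V''(\phi^*) = k}, the stationary SD of the phase is
#' \eqn{\sqrt{Q / (2k)}} (radians). Used in this package as a closed-form
#' oracle against which simulated variability is checked; valid only for
#' small noise (SD much smaller than the basin width).
#'
#' @param params An [hkb_params()] object (used for validation only; the
#'   stiffness is taken from `fixed_point`).
#' @param Q Noise intensity (rad^2/s, > 0).
#' @param fixed_point A one-row data frame as returned by
#'   [hkb_fixed_points()] (columns `stable`, `curvature`), or a number taken
#'   as \eqn{\phi^*} at which the curvature is evaluated.
#'
#' @return Predicted stationary SD of the relative phase, radians.
#' @examples
#' p <- hkb_params(1, 1)
#' fps <- hkb_fixed_points(p)
#' hkb_predicted_sd(p, Q = 0.01, fps[fps$phi_star == 0, ])
#' @export
hkb_predicted_sd <- function(params, Q, fixed_point) {
  params <- check_hkb_params(params)
  stopifnot(is.numeric(Q), length(Q) == 1, is.finite(Q), Q > 0)
  if (is.numeric(fixed_point)) {
    curv <- hkb_curvature(fixed_point, params)
    stable <- curv > 0
  } else {
    fp <- as.data.frame(fixed_point)
    stopifnot(nrow(fp) == 1, all(c("stable", "curvature") %in% names(fp)))
    curv <- fp$curvature
    stable <- fp$stable
  }
  if (!isTRUE(stable)) {
    stop("predicted SD is defined only at a stable fixed point", call. = FALSE)
  }
  sqrt(Q / (2 * curv))
}
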