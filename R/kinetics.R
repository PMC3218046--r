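#' Parameters of the probe activation cycle
#'
#' A unimolecular FRET probe is driven between an inactive state P and an
#' active, FRET-competent state P* by a forward enzyme (activity `F_a`) and a
#' reverse enzyme (activity `R_a`), each following a Michaelis-Menten
#' mechanism with constants `K_MF` and `K_MR`.  Activities are maximal
#' (Vmax-type) rates in concentration per unit time; `P_TOT` is the total
#' probe concentration, conserved by the cycle.
#'
#' @param F_a Forward-enzyme activity (concentration/time), >= 0.
#' @param R_a Reverse-enzyme activity (concentration/time), >= 0.
#' @param K_MF Forward Michaelis constant (concentration), > 0.
#' @param K_MR Reverse Michaelis constant (concentration), > 0.
#' @param P_TOT Total probe concentration, > 0.
#' @return An object of class `probe_cycle_params`.
#' @examples
#' probe_cycle_params(F_a = 1, R_a = 2, K_MF = 1, K_MR = 4, P_TOT = 100)
#' @export
probe_cycle_params <- function(F_a, R_a, K_MF, K_MR, P_TOT) {
  for (nm in c("F_a", "R_a", "K_MF", "K_MR", "P_TOT")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (F_a < 0 || R_a < 0)
    stop("enzyme activities F_a and R_a must be non-negative", call. = FALSE)
  if (K_MF <= 0 || K_MR <= 0)
    stop("Michaelis constants K_MF and K_MR must be positive", call. = FALSE)
  if (P_TOT <= 0)
    stop("total probe concentration P_TOT must be positive", call. = FALSE)
  structure(list(F_a = F_a, R_a = R_a, K_MF = K_MF, K_MR = K_MR,
                 P_TOT = P_TOT),
            class = "probe_cycle_params")
}

#' @export
print.probe_cycle_params <- function(x, ...) {
  cat("Probe activation cycle parameters\n")
  cat(sprintf("  F_a = %g, R_a = %g, K_MF = %g, K_MR = %g, P_TOT = %g\n",
              x$F_a, x$R_a, x$K_MF, x$K_MR, x$P_TOT))
  invisible(x)
}

new_steady_state <- function(p_star, regime, params) {
  structure(list(p_star = p_star, regime = regime, params = params),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state: P* = %g (regime: %s, P_TOT = %g)\n",
              x$p_star, x$regime, x$params$P_TOT))
  invisible(x)
}

.kinetic_regimes <- c("forward_saturated", "reverse_saturated", "both_linear")

#' Closed-form steady state in a saturation limit
#'
#' Solves the steady-state balance of the activation cycle in one of the
#' three limiting regimes:
#' \describe{
#'   \item{`forward_saturated`}{forward enzyme saturated, reverse in its
#'     linear range: `F_a = R_a * P / K_MR`, so `P* = F_a * K_MR / R_a` --
#'     the one regime in which P* is linear in the forward activity.}
#'   \item{`reverse_saturated`}{reverse saturated, forward linear:
#'     `(F_a / K_MF) * (P_TOT - P) = R_a`, so `P* = P_TOT - R_a * K_MF / F_a`.}
#'   \item{`both_linear`}{both linear:
#'     `(F_a / K_MF) * (P_TOT - P) = (R_a / K_MR) * P`.}
#' }
#' The stated limit is only self-consistent when the closed form lands inside
#' `[0, P_TOT]`; otherwise an error is raised rather than silently clipping.
#'
#' @param params A [probe_cycle_params()] object.
#' @param regime One of `"forward_saturated"`, `"reverse_saturated"`,
#'   `"both_linear"`.
#' @return A `steady_state` object with fields `p_star` and `regime`.
#' @seealso [steady_state_mm()] for the full Michaelis-Menten root.
#' @examples
#' p <- probe_cycle_params(F_a = 1, R_a = 2, K_MF = 1, K_MR = 4, P_TOT = 100)
#' steady_state_limit(p, "forward_saturated")$p_star  # 2
#' @export
steady_state_limit <- function(params, regime = .kinetic_regimes) {
  stopifnot(inherits(params, "probe_cycle_params"))
  regime <- match.arg(regime)
  p <- params
  p_star <- switch(regime,
    forward_saturated = {
      if (p$R_a == 0)
        stop("forward_saturated limit requires R_a > 0", call. = FALSE)
      p$F_a * p$K_MR / p$R_a
    },
    reverse_saturated = {
      if (p$F_a == 0)
        stop("reverse_saturated limit requires F_a > 0", call. = FALSE)
      p$P_TOT - p$R_a * p$K_MF / p$F_a
    },
    both_linear = {
      fk <- p$F_a / p$K_MF
      rk <- p$R_a / p$K_MR
      if (fk + rk == 0)
        stop("both_linear limit requires F_a + R_a > 0", call. = FALSE)
      p$P_TOT * fk / (fk + rk)
    })
  if (p_star < 0 || p_star > p$P_TOT)
    stop(sprintf(
      "regime inconsistency: closed-form P* = %g lies outside [0, %g]; the '%s' limit assumption cannot hold for these parameters",
      p_star, p$P_TOT, regime), call. = FALSE)
  new_steady_state(p_star, regime, params)
}

#' Steady state with both enzymes following Michaelis-Menten kinetics
#'
#' Solves the rate balance
#' `F_a * (P_TOT - P) / (K_MF + P_TOT - P) = R_a * P / (K_MR + P)`
#' (the Goldbeter-Koshland covalent-modification steady state), a quadratic
#' in P* with exactly one root in `[0, P_TOT]` when both activities are
#' positive.  If floating-point noise places both quadratic roots inside the
#' interval, the one with the smaller absolute rate imbalance is returned.
#'
#' @param params A [probe_cycle_params()] object with `F_a + R_a > 0`.
#' @return A `steady_state` object, regime `"michaelis"`.
#' @examples
#' p <- probe_cycle_params(F_a = 3, R_a = 1, K_MF = 0.5, K_MR = 2, P_TOT = 10)
#' steady_state_mm(p)$p_star
#' @export
steady_state_mm <- function(params) {
  stopifnot(inherits(params, "probe_cycle_params"))
  p <- params
  if (p$F_a == 0 && p$R_a == 0)
    stop("degenerate parameters: F_a = R_a = 0 leaves every P* stationary",
         call. = FALSE)
  if (p$F_a == 0) return(new_steady_state(0, "michaelis", params))
  if (p$R_a == 0) return(new_steady_state(p$P_TOT, "michaelis", params))
  # F*(P_TOT - u)*(K_MR + u) - R*u*(K_MF + P_TOT - u) = 0
  # => (R - F) u^2 + [F (P_TOT - K_MR) - R (K_MF + P_TOT)] u + F P_TOT K_MR
  a <- p$R_a - p$F_a
  b <- p$F_a * (p$P_TOT - p$K_MR) - p$R_a * (p$K_MF + p$P_TOT)
  cc <- p$F_a * p$P_TOT * p$K_MR
  if (abs(a) < .Machine$double.eps * (abs(b) + abs(cc))) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    disc <- max(disc, 0)
    # numerically stable quadratic roots via the q-formula
    q <- -0.5 * (b + sign(b) * sqrt(disc))
    roots <- c(q / a, if (q != 0) cc / q else -b / a)
  }
  eps <- 1e-9 * p$P_TOT
  inside <- roots[roots >= -eps & roots <= p$P_TOT + eps]
  if (length(inside) == 0L)
    stop("no steady-state root found in [0, P_TOT]; parameters may be invalid",
         call. = FALSE)
  imbalance <- function(u) {
    abs(p$F_a * (p$P_TOT - u) / (p$K_MF + p$P_TOT - u) -
        p$R_a * u / (p$K_MR + u))
  }
  u <- inside[which.min(vapply(inside, imbalance, numeric(1)))]
  new_steady_state(min(max(u, 0), p$P_TOT), "michaelis", params)
}

#' Net activation rate of the probe cycle
#'
#' `dP*/dt` of the activation cycle at active-probe concentration `p_star`.
#' Exposed so that oracles and users can audit rate balances directly.
#'
#' @param p_star Active-probe concentration, in `[0, P_TOT]`.
#' @param params A [probe_cycle_params()] object.
#' @return The net rate `F_a (P_TOT - P*)/(K_MF + P_TOT - P*) -
#'   R_a P*/(K_MR + P*)`.
#' @export
cycle_rate <- function(p_star, params) {
  p <- params
  p$F_a * (p$P_TOT - p_star) / (p$K_MF + p$P_TOT - p_star) -
    p$R_a * p_star / (p$K_MR + p_star)
}

#' Independent ODE oracle for the cycle steady state
#'
#' Integrates `dP*/dt` from `P*(0) = 0` (via `deSolve::lsoda`) until the net
#' rate is below `tol` times the dominant activity.  Serves as an oracle that
#' is independent of the closed-form algebra in [steady_state_limit()] and
#' [steady_state_mm()]; conservation `P + P* = P_TOT` holds at every step
#' because only P* is integrated and P is its complement by definition.
#'
#' @param params A [probe_cycle_params()] object.
#' @param tol Relative tolerance on the residual net rate (default `1e-8`).
#' @param max_chunks Step budget: maximum number of doubling time chunks
#'   before a non-convergence error (default 60).
#' @return A `steady_state` object, regime `"michaelis"`.
#' @export
ode_steady_state_oracle <- function(params, tol = 1e-8, max_chunks = 60L) {
  stopifnot(inherits(params, "probe_cycle_params"))
  p <- params
  if (p$F_a == 0) return(new_steady_state(0, "michaelis", params))
  scale <- max(p$F_a, p$R_a)
  # relaxation time scale from the linearized cycle
  t_relax <- p$P_TOT / scale
  rhs <- function(t, y, parms) list(cycle_rate(y, p))
  u <- 0
  t_span <- t_relax
  for (i in seq_len(max_chunks)) {
    out <- deSolve::lsoda(y = u, times = c(0, t_span), func = rhs,
                          parms = NULL, rtol = tol * 1e-2, atol = tol * 1e-2 * p$P_TOT)
    u <- out[nrow(out), 2]
    u <- min(max(u, 0), p$P_TOT)
    if (abs(cycle_rate(u, p)) < tol * scale)
      return(new_steady_state(u, "michaelis", params))
    t_span <- t_span * 2
  }
  stop("ODE oracle did not converge within the step budget", call. = FALSE)
}

#' Bisection oracle for the cycle steady state
#'
#' Finds the root of the net rate on `[0, P_TOT]` by bisection; a second
#' independent cross-check on the closed forms.
#'
#' @inheritParams ode_steady_state_oracle
#' @param tol Absolute tolerance on P* (default `1e-12` times `P_TOT`).
#' @return A `steady_state` object.
#' @export
bisection_steady_state_oracle <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "probe_cycle_params"))
  p <- params
  if (p$F_a == 0) return(new_steady_state(0, "michaelis", params))
  if (p$R_a == 0) return(new_steady_state(p$P_TOT, "michaelis", params))
  lo <- 0; hi <- p$P_TOT
  f_lo <- cycle_rate(lo, p)
  while (hi - lo > tol * p$P_TOT) {
    mid <- 0.5 * (lo + hi)
    f_mid <- cycle_rate(mid, p)
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  new_steady_state(0.5 * (lo + hi), "michaelis", params)
}

#' Deviation of the activity-response curve from linearity
#'
#' Evaluates `P*(F_a)` over a grid of forward activities with the other
#' parameters held fixed, fits the best affine line by ordinary least
#' squares, and reports the maximum absolute residual relative to the range
#' of `P*`.  Zero means the map is exactly affine on the grid (the
#' forward-saturated regime); the other regimes give strictly positive
#' deviations.
#'
#' @param params A [probe_cycle_params()] template; its `F_a` is ignored.
#' @param f_a_grid Numeric vector of forward activities, >= 3 distinct values.
#' @param regime `"michaelis"` (default, full [steady_state_mm()]) or one of
#'   the three limit regimes of [steady_state_limit()].
#' @return A list with `deviation` (max relative residual), `p_star`
#'   (response values) and `fit` (the `lm` object).
#' @export
linearity_deviation <- function(params, f_a_grid,
                                regime = c("michaelis", .kinetic_regimes)) {
  stopifnot(inherits(params, "probe_cycle_params"))
  regime <- match.arg(regime)
  f_a_grid <- as.numeric(f_a_grid)
  if (length(unique(f_a_grid)) < 3L)
    stop("degenerate grid: need at least 3 distinct F_a values (an affine fit through 2 points is exact by construction)",
         call. = FALSE)
  solve1 <- function(fa) {
    pars <- probe_cycle_params(fa, params$R_a, params$K_MF, params$K_MR,
                               params$P_TOT)
    if (regime == "michaelis") steady_state_mm(pars)$p_star
    else steady_state_limit(pars, regime)$p_star
  }
  p_star <- vapply(f_a_grid, solve1, numeric(1))
  fit <- stats::lm(p_star ~ f_a_grid)
  rng <- diff(range(p_star))
  dev <- if (rng == 0) 0 else max(abs(stats::resid(fit))) / rng
  list(deviation = dev, p_star = p_star, fit = fit)
}
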