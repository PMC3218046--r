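test_that("limit-regime closed forms reproduce hand-solved balances", {
  # forward saturated: F_a = R_a P*/K_MR  =>  P* = F_a K_MR / R_a = 2
  p <- probe_cycle_params(F_a = 1, R_a = 2, K_MF = 1, K_MR = 4, P_TOT = 100)
  expect_equal(steady_state_limit(p, "forward_saturated")$p_star, 2)
  # reverse saturated: P* = P_TOT - R_a K_MF / F_a = 10 - 0.5 = 9.5
  p <- probe_cycle_params(F_a = 2, R_a = 1, K_MF = 1, K_MR = 1, P_TOT = 10)
  expect_equal(steady_state_limit(p, "reverse_saturated")$p_star, 9.5)
  # both linear with symmetric rates: P* = P_TOT / 2
  p <- probe_cycle_params(F_a = 3, R_a = 6, K_MF = 1, K_MR = 2, P_TOT = 10)
  expect_equal(steady_state_limit(p, "both_linear")$p_star, 5)
})

test_that("limit closed forms error when the limit assumption cannot hold", {
  # forward-saturated form would exceed P_TOT
  p <- probe_cycle_params(F_a = 10, R_a = 1, K_MF = 1, K_MR = 50, P_TOT = 10)
  expect_error(steady_state_limit(p, "forward_saturated"),
               "regime inconsistency")
  # reverse-saturated form would go negative
  p <- probe_cycle_params(F_a = 0.1, R_a = 10, K_MF = 5, K_MR = 1, P_TOT = 10)
  expect_error(steady_state_limit(p, "reverse_saturated"),
               "regime inconsistency")
  expect_error(probe_cycle_params(1, 1, 0, 1, 10), "Michaelis")
  expect_error(probe_cycle_params(1, 1, 1, -2, 10), "Michaelis")
})

test_that("Michaelis-Menten steady state has the analytic symmetry and limits", {
  # symmetric enzymes: P* = P_TOT / 2 for any total
  for (ptot in c(0.3, 10, 400)) {
    p <- probe_cycle_params(2, 2, 5, 5, ptot)
    expect_equal(steady_state_mm(p)$p_star, ptot / 2, tolerance = 1e-12)
  }
  # large-K_M limit reduces to the both-linear closed form
  p_lim <- probe_cycle_params(3, 1, 1e6, 2e6, 10)
  expect_equal(steady_state_mm(p_lim)$p_star,
               steady_state_limit(p_lim, "both_linear")$p_star,
               tolerance = 1e-4)
  # degenerate cycle
  expect_error(steady_state_mm(probe_cycle_params(0, 0, 1, 1, 10)),
               "degenerate")
  # one-sided fluxes
  expect_equal(steady_state_mm(probe_cycle_params(0, 1, 1, 1, 10))$p_star, 0)
  expect_equal(steady_state_mm(probe_cycle_params(1, 0, 1, 1, 10))$p_star, 10)
})

test_that("steady_state_mm converges monotonically to each saturation limit", {
  rel_err <- function(F_a, R_a, K_MF, K_MR, regime) {
    p <- probe_cycle_params(F_a, R_a, K_MF, K_MR, P_TOT = 10)
    abs(steady_state_mm(p)$p_star -
        steady_state_limit(p, regime)$p_star) /
      steady_state_limit(p, regime)$p_star
  }
  scales <- 10^(2:5)
  # both Michaelis constants large -> both_linear
  err_bl <- sapply(scales, function(s)
    rel_err(1.3, 2.1, s, 2 * s, "both_linear"))
  expect_true(all(diff(err_bl) < 0))
  # forward saturated: K_MF -> 0 jointly with K_MR -> infinity (F_a scaled
  # to hold the limiting P* = F_a K_MR / R_a fixed at 1)
  err_fs <- sapply(scales, function(s)
    rel_err(2.1 / (100 * s), 2.1, 1 / s, 100 * s, "forward_saturated"))
  expect_true(all(diff(err_fs) < 0))
  expect_lt(err_fs[length(err_fs)], 1e-4)
  # reverse saturated: K_MR -> 0, K_MF -> infinity (R_a scaled to hold the
  # limiting P_TOT - P* = R_a K_MF / F_a fixed at 1)
  err_rs <- sapply(scales, function(s)
    rel_err(1.3, 1.3 / (100 * s), 100 * s, 1 / s, "reverse_saturated"))
  expect_true(all(diff(err_rs) < 0))
  expect_lt(err_rs[length(err_rs)], 1e-4)
})

test_that("closed forms agree with bisection and ODE oracles on random draws", {
  draws <- random_cycle_params(100)
  for (p in draws) {
    mm <- steady_state_mm(p)$p_star
    expect_gte(mm, 0); expect_lte(mm, p$P_TOT)
    expect_lt(abs(mm - bisection_steady_state_oracle(p)$p_star),
              1e-8 * p$P_TOT)
  }
  # ODE integration is the slower oracle; audit a fixed subset
  for (p in draws[seq(1, 100, by = 7)]) {
    expect_lt(abs(steady_state_mm(p)$p_star -
                    ode_steady_state_oracle(p, tol = 1e-10)$p_star),
              1e-6 * p$P_TOT)
  }
})

test_that("P* is monotone increasing in F_a and decreasing in R_a", {
  fa_grid <- 10^seq(-2, 2, length.out = 25)
  p_star_f <- sapply(fa_grid, function(fa)
    steady_state_mm(probe_cycle_params(fa, 1.7, 2, 3, 10))$p_star)
  expect_true(all(diff(p_star_f) > 0))
  p_star_r <- sapply(fa_grid, function(ra)
    steady_state_mm(probe_cycle_params(1.7, ra, 2, 3, 10))$p_star)
  expect_true(all(diff(p_star_r) < 0))
})

test_that("ODE trajectory conserves total probe", {
  # integrate the full two-state system and check P + P* = P_TOT throughout
  p <- probe_cycle_params(2, 1, 0.5, 2, 10)
  rhs <- function(t, y, parms) {
    v <- p$F_a * y[1] / (p$K_MF + y[1]) - p$R_a * y[2] / (p$K_MR + y[2])
    list(c(-v, v))
  }
  out <- deSolve::lsoda(y = c(P = 10, P_star = 0), times = seq(0, 50, 0.5),
                        func = rhs, parms = NULL, rtol = 1e-12, atol = 1e-12)
  expect_true(all(abs(out[, "P"] + out[, "P_star"] - 10) < 1e-9))
})

test_that("linearity deviation is zero only for the forward-saturated regime", {
  p <- probe_cycle_params(1, 2, 1.5, 4, 10)
  grid <- seq(0.1, 2, length.out = 9)
  expect_equal(
    linearity_deviation(p, grid, regime = "forward_saturated")$deviation, 0,
    tolerance = 1e-12)
  # both-linear response saturates over a wide activity span
  wide <- seq(0.1, 10, length.out = 15) * p$R_a * p$K_MF / p$K_MR
  expect_gt(linearity_deviation(p, wide, regime = "both_linear")$deviation,
            0.05)
  expect_gt(linearity_deviation(p, wide, regime = "michaelis")$deviation, 0)
  expect_error(linearity_deviation(p, c(1, 2), regime = "michaelis"),
               "degenerate grid")
  expect_error(linearity_deviation(p, c(1, 1, 1), regime = "michaelis"),
               "degenerate grid")
})
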