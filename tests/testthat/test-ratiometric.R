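test_that("channel intensities match hand-evaluated components", {
  ci <- channel_intensities(fret_state(E = 0.3, phi_F = 0.5),
                            excitation_state(1000, N_A_acc = 1000),
                            standard_cov)
  expect_equal(ci$I_D_don, 340)          # 1000 * 0.85 * 0.4
  expect_equal(ci$I_A_don, 137.5)        # 1000*(0.15*0.35 + 0.85*0.1)
  expect_equal(ci$I_A_acc, 350)          # 1000 * 0.35
  # no FRET: pure crosstalk baseline
  ci0 <- channel_intensities(fret_state(0.3, 0),
                             excitation_state(1000, N_A_direct = 50),
                             standard_cov)
  expect_equal(ci0$I_D_don, 1000 * 0.4)
  expect_equal(ci0$I_A_don, 50 * 0.35 + 1000 * 0.1)
  # complete transfer: donor channel dark
  ci1 <- channel_intensities(fret_state(1, 1), excitation_state(1000),
                             standard_cov)
  expect_equal(ci1$I_D_don, 0)
  expect_equal(ci1$I_A_don, 1000 * 0.35)
})

test_that("the standard ratio R reproduces its closed form", {
  st <- fret_state(0.3, 0.5)
  exc <- excitation_state(1000, N_A_acc = 1000)
  expect_equal(ratio_R(st, exc, standard_cov), 137.5 / 340)
  # crosstalk-only baseline at phi_F = 0
  expect_equal(ratio_R(fret_state(0.5, 0), exc, standard_cov), 0.1 / 0.4)
  # no crosstalk, matched coverages, E phi_F = 0.6 -> 0.6 / 0.4
  cov <- coverage_fractions(f_DD = 0.4, f_AD = 0, f_AA = 0.4)
  expect_equal(ratio_R(fret_state(0.6, 1), exc, cov), 1.5)
  expect_error(ratio_R(fret_state(1, 1), exc, standard_cov),
               "division by zero")
})

test_that("R_alt reproduces its closed form and is exactly affine in phi_F", {
  exc <- excitation_state(1000, N_A_acc = 1000)
  expect_equal(ratio_R_alt(fret_state(0.3, 0), exc, standard_cov),
               0.4 / 0.35)
  expect_equal(ratio_R_alt(fret_state(0.3, 0.5), exc, standard_cov),
               0.85 * 0.4 / 0.35)
  # affine midpoint exactness
  r <- sapply(c(0, 0.5, 1), function(phi)
    ratio_R_alt(fret_state(0.3, phi), exc, standard_cov))
  expect_equal(r[2], (r[1] + r[3]) / 2, tolerance = 1e-12)
  expect_error(ratio_R_alt(fret_state(0.3, 0.5), excitation_state(1000),
                           standard_cov), "division by zero")
})

test_that("R_alt is affine in phi_F; R and 1/R_alt are strictly not", {
  phis <- seq(0, 1, length.out = 11)
  exc <- excitation_state(800, N_A_acc = 1200, gain_D = 1.3, gain_A = 0.7)
  for (E in c(0.15, 0.4, 0.6)) {
    ralt <- sapply(phis, function(p)
      ratio_R_alt(fret_state(E, p), exc, standard_cov))
    expect_lt(affine_residual(phis, ralt), 1e-10)
    expect_true(all(diff(ralt) < 0))          # strictly decreasing
    expect_gt(affine_residual(phis, 1 / ralt), 1e-6)
    r <- sapply(phis[-11], function(p)
      ratio_R(fret_state(E, p), exc, standard_cov))
    expect_gt(affine_residual(phis[-11], r), 1e-6)
    expect_true(all(diff(r) > 0))             # strictly increasing
  }
})

test_that("ratios are invariant to common gain and scale with gain_A", {
  st <- fret_state(0.4, 0.6)
  base <- excitation_state(1000, N_A_acc = 900)
  both <- excitation_state(1000, N_A_acc = 900, gain_D = 3.7, gain_A = 3.7)
  accx <- excitation_state(1000, N_A_acc = 900, gain_D = 1, gain_A = 2)
  expect_equal(ratio_R(st, both, standard_cov),
               ratio_R(st, base, standard_cov), tolerance = 1e-12)
  expect_equal(ratio_R_alt(st, both, standard_cov),
               ratio_R_alt(st, base, standard_cov), tolerance = 1e-12)
  expect_equal(ratio_R(st, accx, standard_cov),
               2 * ratio_R(st, base, standard_cov), tolerance = 1e-12)
  expect_equal(1 / ratio_R_alt(st, accx, standard_cov),
               2 / ratio_R_alt(st, base, standard_cov), tolerance = 1e-12)
})

test_that("the simulated R surface is monotone and convex along E*phi_F", {
  e_phi <- seq(0, 0.6, by = 0.05)
  ct <- seq(0, 1, by = 0.1)
  R <- r_surface(e_phi, ct)
  # baseline column: R at E phi_F = 0 equals the crosstalk grid
  expect_equal(unname(R[1, ]), ct)
  expect_equal(unname(R[length(e_phi), 1]), 1.5)  # E phi_F = 0.6, no crosstalk
  expect_true(all(apply(R, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(R[, -1], 1, function(row) all(diff(row) > 0))))
  # convexity: positive second finite difference along the E phi_F axis
  d2 <- apply(R, 2, function(col) diff(col, differences = 2))
  expect_true(all(d2 > 0))
  expect_error(r_surface(c(0, 0.5, 1)), "\\[0, 1\\)")
})

test_that("naive linear reading of R carries the predicted bias", {
  cov <- coverage_fractions(f_DD = 0.4, f_AD = 0, f_AA = 0.4)
  exc <- excitation_state(1000, N_A_acc = 1000)
  r_at <- function(E, phi) ratio_R(fret_state(E, phi), exc, cov)
  est <- naive_fraction_from_R(r_at(0.6, 0.5), r_at(0.6, 1), r_at(0.6, 0))
  expect_equal(est, (0.3 / 0.7) / 1.5, tolerance = 1e-12)
  expect_equal(est - 0.5, -0.2142857, tolerance = 1e-6)
  expect_equal(naive_fraction_from_R(r_at(0.6, 0), r_at(0.6, 1), r_at(0.6, 0)),
               0)
  # bias vanishes as E -> 0 at fixed phi_F
  bias <- sapply(c(0.3, 0.03, 0.003), function(E)
    abs(naive_fraction_from_R(r_at(E, 0.5), r_at(E, 1), r_at(E, 0)) - 0.5))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 1e-3)
  expect_error(naive_fraction_from_R(1, 2, 2), "degenerate")
})

test_that("closed-form ratios agree with the channel-intensity route", {
  set.seed(7)
  for (i in 1:20) {
    st <- fret_state(runif(1, 0, 0.9), runif(1))
    exc <- excitation_state(runif(1, 100, 2000), 0, runif(1, 100, 2000),
                            runif(1, 0.5, 2), runif(1, 0.5, 2))
    cov <- coverage_fractions(runif(1, 0.1, 1), runif(1, 0, 0.5),
                              runif(1, 0.1, 1))
    x <- st$E * st$phi_F
    closed_R <- (x * cov$f_AA + (1 - x) * cov$f_AD) /
      ((1 - x) * cov$f_DD) * exc$gain_A / exc$gain_D
    expect_equal(ratio_R(st, exc, cov), closed_R, tolerance = 1e-12)
    closed_alt <- exc$gain_D * exc$N_D_star * (1 - x) * cov$f_DD /
      (exc$gain_A * exc$N_A_acc * cov$f_AA)
    expect_equal(ratio_R_alt(st, exc, cov), closed_alt, tolerance = 1e-12)
  }
})
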