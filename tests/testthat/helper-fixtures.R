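# Shared fixtures built in code at test time.

fix_spectra <- default_spectra()

# random but reproducible probe-cycle parameter draws spanning saturated,
# linear and intermediate regimes
random_cycle_params <- function(n, seed = 20111116) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    P_TOT <- 10^stats::runif(1, -1, 2)
    probe_cycle_params(
      F_a = 10^stats::runif(1, -2, 2),
      R_a = 10^stats::runif(1, -2, 2),
      K_MF = P_TOT * 10^stats::runif(1, -1, 1),
      K_MR = P_TOT * 10^stats::runif(1, -1, 1),
      P_TOT = P_TOT)
  })
}

# residual of the best affine fit of y against x, relative to range(y)
affine_residual <- function(x, y) {
  fit <- stats::lm(y ~ x)
  max(abs(stats::resid(fit))) / diff(range(y))
}

standard_cov <- coverage_fractions(f_DD = 0.4, f_AD = 0.1, f_AA = 0.35)
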