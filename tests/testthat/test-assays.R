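test_that("Michaelis-Menten fitting recovers noiseless parameters exactly", {
  grid <- c(10, 25, 50, 100, 200, 400, 700, 1000)
  r <- gen_initial_rates(69, 4.2, grid, noise_cv = 0, n_rep = 1, seed = 1)
  f <- fit_michaelis_menten(r)
  expect_true(f$converged)
  expect_lt(abs(f$km - 69) / 69, 1e-3)
  expect_lt(abs(f$vmax - 4.2) / 4.2, 1e-3)
  # MM identity on the fitted curve: v(Km) = Vmax / 2
  expect_equal(f$vmax * f$km / (f$km + f$km), f$vmax / 2)
  # degenerate input flags, never silently fits
  zero <- data.frame(S = grid, v = 0)
  expect_false(fit_michaelis_menten(zero)$converged)
  expect_error(fit_michaelis_menten(data.frame(S = c(1, 2, 3),
                                               v = c(1, 2, 3))),
               "4 distinct")
})

test_that("noisy kinetic fits cover the generating Km within their 95% CI", {
  grid <- c(10, 25, 50, 100, 200, 400, 700, 1000)
  hits <- 0L
  for (seed in 1:10) {
    r <- gen_initial_rates(198.7, 33.3, grid, noise_cv = 0.05, n_rep = 3,
                           seed = seed)
    f <- fit_michaelis_menten(r)
    if (f$km_ci[1] <= 198.7 && 198.7 <= f$km_ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 8)   # nominal 95% coverage, small-sample slack
})

test_that("fold acceleration divides Vmax values with propagated error", {
  grid <- c(10, 25, 50, 100, 200, 400, 700, 1000)
  fp <- fit_michaelis_menten(gen_initial_rates(198.7, 33.3, grid, 0, 1, 1))
  fm <- fit_michaelis_menten(gen_initial_rates(69, 4.2, grid, 0, 1, 1))
  fa <- fold_acceleration(fp, fm)
  expect_equal(fa$ratio, 33.3 / 4.2, tolerance = 1e-3)
  # relative propagated error is symmetric in the two relative errors
  mk <- function(v, se) list(vmax = v, vmax_se = se, converged = TRUE)
  a <- fold_acceleration(mk(10, 1), mk(5, 0.25))
  b <- fold_acceleration(mk(10, 0.5), mk(5, 0.5))
  expect_equal(a$se / a$ratio, b$se / b$ratio)
})

test_that("stoichiometry estimator matches the closed form and is scale-equivariant", {
  exact <- data.frame(ca_rate = c(1, 2, 3), pi_rate = c(2, 4, 6))
  st <- estimate_stoichiometry(exact, n_boot = 200, seed = 1)
  expect_equal(st$ratio, 2.0)
  expect_equal(unname(diff(st$ci)), 0)
  eq <- data.frame(ca_rate = c(1, 2, 3), pi_rate = c(1, 2, 3))
  expect_equal(estimate_stoichiometry(eq, 100, 1)$ratio, 1.0)
  noisy <- data.frame(ca_rate = runif(12, 1, 3))
  noisy$pi_rate <- noisy$ca_rate * 1.3 + rnorm(12, 0, 0.05)
  s1 <- estimate_stoichiometry(noisy, 200, 5)
  scaled <- noisy; scaled$ca_rate <- scaled$ca_rate * 7
  scaled$pi_rate <- scaled$pi_rate * 7
  s2 <- estimate_stoichiometry(scaled, 200, 5)
  expect_equal(s1$ratio, s2$ratio)
  expect_equal(s1$ci, s2$ci)
  expect_error(estimate_stoichiometry(data.frame(ca_rate = c(0, 0, 0),
                                                 pi_rate = c(1, 2, 3))),
               "all-zero")
})

test_that("one-site ITC fit recovers parameters and honors the model structure", {
  it <- gen_itc_isotherm(kd = 0.93, delta_h = -2, n_sites = 1,
                         cell_conc = 0.01, syringe_conc = 10,
                         conc_scale = 1e-3, noise_sd = 0, seed = 1)
  f <- fit_itc_one_site(it, fix_n = 1)
  expect_true(f$converged)
  expect_lt(abs(f$kd - 0.93) / 0.93, 0.01)
  expect_lt(abs(f$delta_h - (-2)) / 2, 0.01)
  # linearity in dH: doubling dH doubles every predicted heat
  q1 <- capiflux:::itc_model_heats(c(kd = 1, delta_h = -2, n_sites = 1,
                                     offset = 0), 0.01, 10, 0.01, 20, 1.4166,
                                   1e-3)
  q2 <- capiflux:::itc_model_heats(c(kd = 1, delta_h = -4, n_sites = 1,
                                     offset = 0), 0.01, 10, 0.01, 20, 1.4166,
                                   1e-3)
  expect_equal(q2, 2 * q1)
  # no-signal limit is flagged rather than fitted
  flat <- it; flat$heat <- rep(0, nrow(flat))
  expect_false(fit_itc_one_site(flat, fix_n = 1)$converged)
})

test_that("lifetime fitting recovers tau and flags non-decaying traces", {
  d <- gen_lret_decay(1.5, n_points = 200, noise_sd = 0, seed = 1)
  f <- fit_lifetime(d)
  expect_true(f$converged)
  expect_lt(abs(f$tau - 1.5) / 1.5, 1e-3)
  # y(tau)/y(0) = 1/e on the fitted curve
  y0 <- f$amplitude + f$baseline
  ytau <- f$amplitude * exp(-1) + f$baseline
  expect_equal(ytau / y0, exp(-1), tolerance = 1e-6)
  flat <- data.frame(t = seq(0, 10, length.out = 50), y = 1)
  expect_false(fit_lifetime(flat)$converged)
  expect_error(fit_lifetime(data.frame(t = 1:5, y = 1:5)), "10 points")
})

test_that("Forster distance evaluates the lifetime relation and its inverse", {
  expect_equal(forster_distance(1.5, 0.75, 30), 30)   # 50% transfer
  # R -> 0 as tau_DA -> 0 (sixth-root approach, so slowly)
  expect_lt(forster_distance(1.5, 1e-12, 30), 0.5)
  expect_equal(forster_distance(1.5, 0, 30), 0)
  expect_error(forster_distance(1.5, 1.5, 30), "tau_DA")
  # inverse round trip across the valid domain, incl. the apo distance 25.5
  for (r in c(10, 25.5, 26.9, 40)) {
    tda <- forster_tau_da(r, 1.5, 30)
    expect_equal(forster_distance(1.5, tda, 30), r, tolerance = 1e-10)
  }
})

test_that("phosphate speciation follows Henderson-Hasselbalch", {
  expect_equal(phosphate_speciation(7.2), 0.5)
  expect_equal(phosphate_speciation(8.2), 1 / 11)
  f <- phosphate_speciation(seq(4, 10, 0.5))
  expect_true(all(diff(f) < 0))
  expect_error(phosphate_speciation(15))
})

test_that("pH-profile peak is a discrete argmax with boundary and tie handling", {
  tab <- data.frame(ph = c(6.5, 7.0, 7.5, 8.0, 8.5),
                    vmax = c(0.02, 0.06, 0.097, 0.05, 0.01))
  pk <- ph_profile_peak(tab)
  expect_equal(pk$ph_peak, 7.5)
  expect_false(pk$boundary)
  mono <- data.frame(ph = c(6.5, 7.0, 7.5), vmax = c(1, 2, 3))
  expect_true(ph_profile_peak(mono)$boundary)
  tie <- data.frame(ph = c(6.5, 7.0, 7.5), vmax = c(1, 2, 2))
  expect_equal(ph_profile_peak(tie)$ph_peak, c(7.0, 7.5))
  single <- ph_profile_peak(data.frame(ph = 7, vmax = 1))
  expect_true(single$degenerate)
})
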