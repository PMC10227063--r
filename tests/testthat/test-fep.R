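test_that("exponential averaging matches constants, Gaussians, and stays stable", {
  expect_equal(exp_free_energy(rep(3.3, 5)), 3.3)
  set.seed(11)
  x <- rnorm(1e5, 2, 1)
  est <- exp_free_energy(x)
  # Gaussian work: dG = mu - sigma^2/2; delta-method SE of the estimator
  w <- exp(-x); se <- sd(w) / (mean(w) * sqrt(length(w)))
  expect_lt(abs(est - 1.5), 3 * se)
  # log-sum-exp contract at the extremes of the sampled range
  expect_equal(exp_free_energy(c(700, 700)), 700)
  expect_equal(exp_free_energy(c(-700, -700)), -700)
  # Jensen bounds: min(dU) <= dG <= mean(dU); and -> ln 2 for {0, M}
  expect_gte(exp_free_energy(c(0, 50)), 0)
  expect_lte(exp_free_energy(c(0, 50)), 25)
  expect_equal(exp_free_energy(c(0, 1e4)), log(2), tolerance = 1e-9)
  expect_error(exp_free_energy(numeric(0)), "empty")
})

test_that("BAR agrees with the Gaussian analytic value", {
  set.seed(4)
  f <- rnorm(2e4, 2.5, 1); r <- rnorm(2e4, -1.5, 1)
  expect_lt(abs(bar_free_energy(f, r) - 2.0), 0.05)
})

test_that("equilibration discard masks the leading fraction of each window", {
  ds <- gen_fep_samples(n_windows = 4, samples_per_window = 1000,
                        true_dg_per_window = 0.1, work_sd = 1,
                        equil_fraction = 0, seed = 2)
  d1 <- discard_equilibration(ds, 0.2)
  sm <- d1$samples
  per_win <- tapply(!sm$equil, paste(sm$lambda, sm$direction), sum)
  expect_true(all(per_win == 800))
  expect_true(all(sm$sample[sm$equil] <= 200))
  d0 <- discard_equilibration(ds, 0)
  expect_equal(sum(d0$samples$equil), 0)
  ds240 <- gen_fep_samples(n_windows = 2, samples_per_window = 240,
                           true_dg_per_window = 0.1, work_sd = 1,
                           equil_fraction = 0, seed = 2)
  d6 <- discard_equilibration(ds240, 1 / 6)
  expect_equal(as.vector(tapply(d6$samples$equil,
                                paste(d6$samples$lambda, d6$samples$direction),
                                sum)), rep(40L, 4))
  tiny <- gen_fep_samples(n_windows = 1, samples_per_window = 2,
                          true_dg_per_window = 0.1, work_sd = 1,
                          equil_fraction = 0, seed = 1)
  expect_error(discard_equilibration(tiny, 0.5), "< 2 samples")
})

test_that("path totals convert kT to kcal/mol and respect direction signs", {
  # 40 windows of exactly 0.1 kT each (zero-width work distributions)
  ds <- gen_fep_samples(n_windows = 40, samples_per_window = 10,
                        true_dg_per_window = 0.1, work_sd = 0, seed = 1)
  tot <- total_free_energy(ds)
  expect_equal(unname(tot["forward"]), 4 * 1.98720e-3 * 298,
               tolerance = 1e-12)
  expect_equal(unname(tot["forward"]), 2.369, tolerance = 1e-3)
  # zero-noise reverse equals forward after its sign flip
  expect_equal(unname(tot["reverse"]), unname(tot["forward"]))
  # single window reduces to the window estimator
  one <- gen_fep_samples(n_windows = 1, samples_per_window = 50,
                         true_dg_per_window = 0.7, work_sd = 0.5, seed = 3)
  sm <- one$samples
  expect_equal(
    unname(total_free_energy(one)["forward"]),
    exp_free_energy(sm$delta_u[sm$direction == "forward" & !sm$equil]) *
      1.98720e-3 * 298)
  # mismatched window counts across directions error out
  bad <- structure(list(samples = data.frame(
    lambda = c(1, 1, 2, 2, 1, 1),
    direction = rep(c("forward", "reverse"), c(4, 2)),
    sample = c(1, 2, 1, 2, 1, 2),
    delta_u = 0.1, equil = FALSE), temperature = 298),
    class = "fep_dataset")
  expect_error(total_free_energy(bad), "inconsistent window count")
})

test_that("bidirectional combination is the mean with half-difference error", {
  r <- combine_bidirectional(1.6, 1.4)
  expect_equal(r$dg, 1.5); expect_equal(r$error, 0.1)
  r2 <- combine_bidirectional(2.2, 2.2)
  expect_equal(r2$error, 0)
  expect_equal(combine_bidirectional(1.4, 1.6)$dg, r$dg)
  expect_equal(combine_bidirectional(1.4, 1.6)$error, r$error)
})

test_that("the protonation cycle subtracts the solution reference", {
  p <- combine_bidirectional(-5, -5)
  s <- combine_bidirectional(-3, -3)
  dd <- protonation_ddg(p, s)
  expect_equal(dd$dg, -2)
  # antisymmetry: swapping protein and solution negates ddG exactly
  expect_equal(protonation_ddg(s, p)$dg, 2)
  # surface-site null: identical legs give exactly 0
  expect_equal(protonation_ddg(p, p)$dg, 0)
  # errors add in quadrature
  pe <- combine_bidirectional(-5.3, -4.7)   # error 0.3
  se <- combine_bidirectional(-3.4, -2.6)   # error 0.4
  expect_equal(protonation_ddg(pe, se)$error, 0.5)
})

test_that("ddG <-> pKa-shift conversion is exact and invertible", {
  rt_ln10 <- 1.98720e-3 * 298 * log(10)
  expect_equal(ddg_to_pka_shift(-rt_ln10), 1.0)
  expect_equal(ddg_to_pka_shift(0), 0)
  expect_equal(ddg_to_pka_shift(-11.5), 11.5 / rt_ln10)
  for (x in c(-11.5, -1.4, 0.3, 3.3))
    expect_equal(pka_shift_to_ddg(ddg_to_pka_shift(x)), x, tolerance = 1e-12)
  # the reference table carries the ten annotated shifts with errors
  ref <- protonation_reference()
  expect_equal(nrow(ref), 10)
  expect_true(all(ref$error > 0))
})

test_that("estimator error shrinks with sample size on Gaussian work", {
  err <- vapply(c(500, 5000, 50000), function(n) {
    set.seed(99)
    abs(exp_free_energy(rnorm(n, 1, 1)) - 0.5)
  }, numeric(1))
  expect_lt(err[3], err[1])
})
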