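test_that("scaffold contains the nine site residues, two ions, and the seed geometry", {
  s <- build_scaffold()
  prot <- s$atoms[s$atoms$type == "ATOM", ]
  expect_setequal(unique(prot$resno),
                  c(68, 69, 72, 99, 252, 255, 256, 278, 281))
  expect_equal(sum(s$atoms$resid == "CA" & s$atoms$type == "HETATM"), 1)
  expect_equal(sum(s$atoms$resid == "2HP"), 5)
  ca <- with(s$atoms, c(x[resid == "CA"], y[resid == "CA"], z[resid == "CA"]))
  p <- with(s$atoms, c(x[elety == "P"], y[elety == "P"], z[elety == "P"]))
  expect_lt(sqrt(sum((ca - p)^2)), 8)     # common-site seed placement
  # carboxylate oxygens of both glutamates near the Ca2+ seed
  carbox <- s$atoms[s$atoms$elety %in% c("OE1", "OE2") &
                      s$atoms$resno %in% c(72, 255), ]
  d <- sqrt((carbox$x - ca[1])^2 + (carbox$y - ca[2])^2 + (carbox$z - ca[3])^2)
  expect_equal(length(d), 4)
  expect_true(all(d < 6))
})

test_that("scaffold construction is deterministic and validates its spec", {
  expect_identical(build_scaffold(), build_scaffold())
  expect_error(scaffold_spec(c("G68", "G68")), "duplicates")
  expect_error(scaffold_spec("X99"), "unknown residue")
  expect_error(build_scaffold(scaffold_spec(setdiff(
    c("G68", "N69", "E72", "N99", "N252", "E255", "H256", "S278", "Q281"),
    "H256"))), "H256")
})

test_that("initial-rate generator follows Michaelis-Menten with CV noise", {
  r <- gen_initial_rates(69, 4.2, 69, noise_cv = 0, n_rep = 1, seed = 1)
  expect_equal(r$v, 2.1)                    # half-saturation at S = Km
  r2 <- gen_initial_rates(69, 4.2, 1e9, noise_cv = 0, n_rep = 1, seed = 1)
  expect_equal(r2$v, 4.2, tolerance = 1e-6) # saturating limit -> Vmax
  a <- gen_initial_rates(69, 4.2, c(10, 100, 1000), noise_cv = 0.05,
                         n_rep = 3, seed = 7)
  expect_identical(a, gen_initial_rates(69, 4.2, c(10, 100, 1000),
                                        noise_cv = 0.05, n_rep = 3, seed = 7))
  expect_error(gen_initial_rates(69, 4.2, numeric(0)), "empty")
})

test_that("time-course generator honors the transport modes", {
  tt <- seq(2, 16, 2)
  cccp <- gen_transport_timecourse("cccp", times = tt, noise_cv = 0,
                                   n_rep = 2, seed = 1)
  expect_true(all(cccp$ca_uptake == 0) && all(cccp$pi_uptake == 0))
  ctrl <- gen_transport_timecourse("control_empty", times = tt, seed = 1)
  expect_true(all(ctrl$ca_uptake == 0))
  edta <- gen_transport_timecourse("edta", times = tt, noise_cv = 0.05,
                                   seed = 1)
  expect_true(all(edta$pi_uptake == 0))
  expect_true(all(edta$ca_uptake > 0))
  co <- gen_transport_timecourse("co_transport", times = tt, noise_cv = 0,
                                 coupling_ratio = 1, seed = 1)
  expect_equal(co$pi_uptake / co$ca_uptake, rep(1, nrow(co)))
  expect_error(gen_transport_timecourse("co_transport", times = tt,
                                        ca_conc = -1), "negative")
})

test_that("ITC generator conserves heat and round-trips through the fitter", {
  it <- gen_itc_isotherm(kd = 0.93, delta_h = -2, n_sites = 1,
                         cell_conc = 0.01, syringe_conc = 10,
                         conc_scale = 1e-3, noise_sd = 0, seed = 1)
  fit <- fit_itc_one_site(it, fix_n = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - 0.93) / 0.93, 0.01)
  # no-binding limit: heats vanish as Kd -> infinity
  it0 <- gen_itc_isotherm(kd = 1e9, delta_h = -2, n_sites = 1,
                          cell_conc = 0.01, syringe_conc = 10,
                          conc_scale = 1e-3, noise_sd = 0, seed = 1)
  expect_lt(max(abs(it0$heat)), 1e-4)
  # saturation bookkeeping: cumulative heat approaches n*dH*M0 corrected for
  # the per-injection dilution of material already in the cell
  sat <- gen_itc_isotherm(kd = 1e-6, delta_h = -5, n_sites = 1,
                          cell_conc = 5, syringe_conc = 500,
                          conc_scale = 1e-6, n_injections = 30,
                          noise_sd = 0, seed = 1)
  setup <- attr(sat, "setup")
  total_kcal <- sum(sat$heat) / 1e9
  dil <- (1 - setup$injection_volume / setup$cell_volume)
  bound_total <- 5e-6 * setup$cell_volume * 1e-3  # all sites filled (mol-ish)
  expect_lt(abs(abs(total_kcal) - 5 * bound_total) / (5 * bound_total), 0.15)
  # under-loaded syringe raises the saturation warning flag
  weak <- gen_itc_isotherm(kd = 1, delta_h = -2, n_sites = 1, cell_conc = 100,
                           syringe_conc = 5, conc_scale = 1e-6, seed = 1)
  expect_true(attr(weak, "saturation_warning"))
})

test_that("LRET decay generator matches the closed form and round-trips", {
  d <- gen_lret_decay(1.5, n_points = 151, noise_sd = 0, seed = 1)
  expect_gte(max(d$t), 3 * 1.5)
  i <- which.min(abs(d$t - 1.5))
  expect_equal(d$y[i], exp(-d$t[i] / 1.5))
  fit <- fit_lifetime(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau - 1.5) / 1.5, 1e-3)
  expect_identical(gen_lret_decay(1.5, seed = 3), gen_lret_decay(1.5, seed = 3))
  expect_error(gen_lret_decay(-1), "positive")
})

test_that("FEP generator encodes the Gaussian ground truth per window", {
  ds <- gen_fep_samples(n_windows = 5, samples_per_window = 50,
                        true_dg_per_window = 0.3, work_sd = 0, seed = 1)
  sm <- ds$samples
  # zero-width work distribution: every sample equals mu = dG exactly
  expect_true(all(sm$delta_u[sm$direction == "forward"] == 0.3))
  expect_true(all(sm$delta_u[sm$direction == "reverse"] == -0.3))
  expect_equal(ds$true_total_dg, 1.5)   # additivity over the path
  ds2 <- gen_fep_samples(n_windows = 3, samples_per_window = 100,
                         true_dg_per_window = c(0.1, 0.2, 0.3), work_sd = 1,
                         equil_fraction = 0.2, seed = 9)
  expect_equal(sum(ds2$samples$equil),
               2 * 3 * 20)              # both directions, 20% of 100
  expect_identical(ds2, gen_fep_samples(n_windows = 3, samples_per_window = 100,
                                        true_dg_per_window = c(0.1, 0.2, 0.3),
                                        work_sd = 1, equil_fraction = 0.2,
                                        seed = 9))
})

test_that("noiseless generator output recovers generating parameters <= 1%", {
  # kinetics
  r <- gen_initial_rates(4.9, 0.097, c(0.5, 1, 2, 5, 10, 20, 40),
                         noise_cv = 0, n_rep = 1, seed = 1)
  f <- fit_michaelis_menten(r)
  expect_lt(abs(f$km - 4.9) / 4.9, 0.01)
  expect_lt(abs(f$vmax - 0.097) / 0.097, 0.01)
  # lifetime (covered above) and ITC (covered above) complete the round-trip
  # property for the remaining generators
  ds <- gen_fep_samples(n_windows = 2, samples_per_window = 10,
                        true_dg_per_window = 0.5, work_sd = 0, seed = 1)
  tot <- total_free_energy(ds)
  kt <- 1.98720e-3 * 298
  expect_equal(unname(tot["forward"]), 1.0 * kt, tolerance = 1e-12)
})
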