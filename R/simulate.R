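#' Simulated Michaelis-Menten initial rates
#'
#' Rates follow v = Vmax * S / (Km + S) with multiplicative Gaussian noise
#' (coefficient of variation `noise_cv`), the error model typical of
#' scintillation-counted transport assays.
#'
#' @param km Michaelis constant (same concentration unit as `conc_grid`).
#' @param vmax maximal rate (e.g. umol/min/g).
#' @param conc_grid substrate concentrations.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_rep replicates per concentration.
#' @param seed integer seed.
#' @return data.frame with columns `S`, `replicate`, `v`.
#' @export
gen_initial_rates <- function(km, vmax, conc_grid, noise_cv = 0.05,
                              n_rep = 3L, seed = 1L) {
  stopifnot(km > 0, vmax > 0, noise_cv >= 0, noise_cv <= 0.5, n_rep >= 1)
  if (!length(conc_grid)) stop("empty concentration grid")
  with_seed(seed, {
    out <- expand.grid(S = conc_grid, replicate = seq_len(n_rep))
    mu <- vmax * out$S / (km + out$S)
    out$v <- mu * (1 + stats::rnorm(nrow(out), 0, noise_cv))
    out[order(out$S, out$replicate), , drop = FALSE]
  })
}

#' Simulated paired Ca2+/Pi uptake time courses
#'
#' Saturating uptake curves U(t) = A (1 - exp(-t/t0)) emulating vesicle
#' accumulation, in one of five modes: `low_flux` (Ca2+ only), `co_transport`
#' (Pi uptake = coupling_ratio x Ca uptake), `control_empty` (no transporter:
#' both zero), `cccp` (protonophore collapses the H+ gradient: both zero) and
#' `edta` (no Ca2+ available: Pi uptake zero). Noise is multiplicative
#' Gaussian on each uptake reading.
#'
#' @param mode one of `"low_flux"`, `"co_transport"`, `"control_empty"`,
#'   `"cccp"`, `"edta"`.
#' @param times sampling times in minutes (sorted, nonnegative).
#' @param ca_conc,pi_conc substrate concentrations (uM, mM) feeding the
#'   Michaelis-Menten amplitude.
#' @param km_ca Michaelis constant for Ca2+ (uM).
#' @param vmax_ca maximal Ca2+ rate (umol/min/g).
#' @param km_pi Michaelis constant for Pi (mM), used for the Pi leg.
#' @param coupling_ratio Pi:Ca coupling (1.0 for strict 1:1 co-transport).
#' @param t_sat saturation time constant (min).
#' @param noise_cv coefficient of variation.
#' @param n_rep replicates.
#' @param seed integer seed.
#' @return data.frame with `time`, `replicate`, `ca_uptake`, `pi_uptake`.
#' @export
gen_transport_timecourse <- function(mode = c("co_transport", "low_flux",
                                              "control_empty", "cccp", "edta"),
                                     times, ca_conc = 500, pi_conc = 5,
                                     km_ca = 198.7, vmax_ca = 33.3,
                                     km_pi = 4.9, coupling_ratio = 1.0,
                                     t_sat = 10, noise_cv = 0.05, n_rep = 3L,
                                     seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(km_ca > 0, vmax_ca > 0, km_pi > 0, coupling_ratio > 0,
            noise_cv >= 0, noise_cv <= 0.5)
  if (any(ca_conc < 0, pi_conc < 0)) stop("negative concentrations")
  if (is.unsorted(times) || any(times < 0))
    stop("times must be sorted and nonnegative")
  rate_ca <- vmax_ca * ca_conc / (km_ca + ca_conc)
  base <- rate_ca * t_sat                 # asymptotic uptake amplitude
  with_seed(seed, {
    out <- expand.grid(time = times, replicate = seq_len(n_rep))
    shape <- 1 - exp(-out$time / t_sat)
    ca_mu <- switch(mode,
                    co_transport = base * shape,
                    low_flux = base * shape,
                    control_empty = 0, cccp = 0,
                    edta = base * shape)
    pi_mu <- switch(mode,
                    co_transport = coupling_ratio * base * shape,
                    low_flux = 0, control_empty = 0, cccp = 0, edta = 0)
    n <- nrow(out)
    out$ca_uptake <- ca_mu * (1 + stats::rnorm(n, 0, noise_cv))
    out$pi_uptake <- pi_mu * (1 + stats::rnorm(n, 0, noise_cv))
    out[order(out$time, out$replicate), , drop = FALSE]
  })
}

#' Average transport rates from an uptake time course
#'
#' Converts paired cumulative uptake readings into per-time-point average
#' rates (uptake / time), the quantity compared across species when reading a
#' coupling stoichiometry off matched time points. The t = 0 point, if
#' present, is dropped.
#'
#' @param tc data.frame from [gen_transport_timecourse()].
#' @return data.frame with `time`, `replicate`, `ca_rate`, `pi_rate`.
#' @export
timecourse_rates <- function(tc) {
  stopifnot(all(c("time", "ca_uptake", "pi_uptake") %in% names(tc)))
  tc <- tc[tc$time > 0, , drop = FALSE]
  data.frame(time = tc$time, replicate = tc$replicate,
             ca_rate = tc$ca_uptake / tc$time,
             pi_rate = tc$pi_uptake / tc$time)
}

#' Simulated one-site ITC titration
#'
#' Injection heats follow the single-site binding isotherm with per-injection
#' dilution bookkeeping (see [fit_itc_one_site()] for the model) plus additive
#' Gaussian noise, the error model of power-compensation calorimeters.
#'
#' @param kd dissociation constant (same unit as concentrations).
#' @param delta_h binding enthalpy (kcal/mol).
#' @param n_sites binding stoichiometry.
#' @param cell_conc,syringe_conc cell (macromolecule) and syringe (ligand)
#'   concentrations.
#' @param injection_volume per-injection volume (ml).
#' @param n_injections number of injections (>= 5).
#' @param cell_volume calorimeter cell volume (ml; default 1.4166, VP-ITC).
#' @param conc_scale factor converting the concentration unit to mol/l
#'   (1 for M, 1e-3 for mM, 1e-6 for uM); heats come out in ucal.
#' @param noise_sd additive heat noise in ucal (default 0.01, the baseline
#'   noise level of power-compensation instruments of the VP-ITC class).
#' @param seed integer seed.
#' @return data.frame with `injection`, `heat` (ucal) and attributes carrying
#'   the setup; attribute `saturation_warning` is TRUE when the syringe load
#'   cannot approach saturation.
#' @export
gen_itc_isotherm <- function(kd, delta_h, n_sites = 1, cell_conc,
                             syringe_conc, injection_volume = 0.010,
                             n_injections = 25L, cell_volume = 1.4166,
                             conc_scale = 1, noise_sd = 0.01, seed = 1L) {
  stopifnot(kd > 0, cell_conc > 0, syringe_conc > 0, injection_volume > 0,
            n_injections >= 5, noise_sd >= 0)
  q <- itc_model_heats(c(kd = kd, delta_h = delta_h, n_sites = n_sites,
                         offset = 0),
                       cell_conc, syringe_conc, injection_volume,
                       n_injections, cell_volume, conc_scale)
  out <- data.frame(injection = seq_len(n_injections), heat = q)
  with_seed(seed, {
    out$heat <- out$heat + stats::rnorm(n_injections, 0, noise_sd)
  })
  attr(out, "setup") <- list(cell_conc = cell_conc,
                             syringe_conc = syringe_conc,
                             injection_volume = injection_volume,
                             cell_volume = cell_volume,
                             conc_scale = conc_scale)
  attr(out, "saturation_warning") <- syringe_conc <= cell_conc * n_sites / 10
  out
}

#' Simulated single-exponential luminescence decay
#'
#' y(t) = exp(-t / tau) * (1 + eps), eps ~ Normal(0, noise_sd), on a time grid
#' spanning at least three lifetimes.
#'
#' @param tau lifetime (ms).
#' @param n_points number of samples.
#' @param noise_sd multiplicative noise SD (fraction of the local amplitude).
#' @param seed integer seed.
#' @param span time-grid extent in lifetimes (default 5, >= 3).
#' @return data.frame with `t` (ms) and `y`.
#' @export
gen_lret_decay <- function(tau, n_points = 200L, noise_sd = 0.01, seed = 1L,
                           span = 5) {
  if (tau <= 0) stop("tau must be positive")
  stopifnot(n_points >= 10, span >= 3)
  tt <- seq(0, span * tau, length.out = n_points)
  with_seed(seed, {
    data.frame(t = tt,
               y = exp(-tt / tau) * (1 + stats::rnorm(n_points, 0, noise_sd)))
  })
}

#' Simulated per-window free-energy-perturbation samples
#'
#' Per window w, energy differences Delta U ~ Normal(mu_w, sd^2) in kT, with
#' the known analytic window free energy dG_w = mu_w - sd^2/2 (the
#' exponential-averaging identity for Gaussian work). The forward direction
#' uses the supplied per-window ground truth; the reverse-direction dataset is
#' generated with the negated ground truth. The first `equil_fraction` of
#' samples in each window is flagged as equilibration.
#'
#' @param n_windows number of lambda windows (default 40).
#' @param samples_per_window samples per window.
#' @param true_dg_per_window scalar or length-`n_windows` vector of window
#'   free energies (kT).
#' @param work_sd per-sample SD of the energy differences (kT).
#' @param equil_fraction fraction of each window flagged as equilibration,
#'   in [0, 0.9).
#' @param temperature temperature in K (bookkeeping only; samples are kT).
#' @param seed integer seed.
#' @return object of class `fep_dataset`: data.frame `samples` (`lambda`,
#'   `direction`, `sample`, `delta_u`, `equil`), `temperature`, and
#'   `true_total_dg` (kT, forward direction).
#' @export
gen_fep_samples <- function(n_windows = 40L, samples_per_window = 1000L,
                            true_dg_per_window = 0.1, work_sd = 1.0,
                            equil_fraction = 0.2, temperature = 298,
                            seed = 1L) {
  stopifnot(n_windows >= 1, samples_per_window >= 2, work_sd >= 0,
            equil_fraction >= 0, equil_fraction < 0.9)
  dg <- rep_len(true_dg_per_window, n_windows)
  n_eq <- ceiling(equil_fraction * samples_per_window)
  with_seed(seed, {
    blocks <- list()
    for (dir in c("forward", "reverse")) {
      sign <- if (dir == "forward") 1 else -1
      for (w in seq_len(n_windows)) {
        mu <- sign * dg[w] + work_sd^2 / 2
        blocks[[length(blocks) + 1L]] <- data.frame(
          lambda = w, direction = dir,
          sample = seq_len(samples_per_window),
          delta_u = stats::rnorm(samples_per_window, mu, work_sd),
          equil = seq_len(samples_per_window) <= n_eq)
      }
    }
    structure(list(samples = do.call(rbind, blocks),
                   temperature = temperature,
                   true_total_dg = sum(dg)),
              class = "fep_dataset")
  })
}
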