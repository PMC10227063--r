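#' Fit Michaelis-Menten kinetics by nonlinear least squares
#'
#' Fits v = Vmax * S / (Km + S) with positivity enforced by a log
#' parameterization. Initial guesses: Vmax = max(v), Km = S nearest
#' half-maximal rate. Non-convergence is flagged, never silently replaced.
#'
#' @param rates data.frame with columns `S` and `v` (replicates as extra
#'   rows); at least 4 distinct substrate concentrations.
#' @return object of class `kinetic_fit`: `km`, `vmax`, `km_se`, `vmax_se`,
#'   `km_ci`, `vmax_ci` (95%), `converged`, `n_points`, `residual_sd`, `fit`.
#' @export
fit_michaelis_menten <- function(rates) {
  stopifnot(all(c("S", "v") %in% names(rates)))
  if (length(unique(rates$S)) < 4)
    stop("need at least 4 distinct substrate concentrations")
  if (any(rates$v < 0 & abs(rates$v) > 1e-9 * max(abs(rates$v))))
    rates$v <- pmax(rates$v, 0)
  vmax0 <- max(rates$v)
  fail <- function() structure(
    list(km = NA_real_, vmax = NA_real_, km_se = NA_real_, vmax_se = NA_real_,
         km_ci = c(NA_real_, NA_real_), vmax_ci = c(NA_real_, NA_real_),
         converged = FALSE, n_points = nrow(rates), residual_sd = NA_real_,
         fit = NULL), class = "kinetic_fit")
  if (vmax0 <= 0) return(fail())
  km0 <- rates$S[which.min(abs(rates$v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(rates$S)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ exp(lvmax) * S / (exp(lkm) + S), data = rates,
                      start = list(lvmax = log(vmax0), lkm = log(km0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  km <- exp(cf[["lkm"]]); vmax <- exp(cf[["lvmax"]])
  km_se <- km * sqrt(vc[2, 2]); vmax_se <- vmax * sqrt(vc[1, 1])
  tq <- stats::qt(0.975, df = nrow(rates) - 2)
  structure(list(
    km = km, vmax = vmax, km_se = km_se, vmax_se = vmax_se,
    km_ci = km * exp(c(-1, 1) * tq * sqrt(vc[2, 2])),
    vmax_ci = vmax * exp(c(-1, 1) * tq * sqrt(vc[1, 1])),
    converged = TRUE, n_points = nrow(rates),
    residual_sd = stats::sigma(fit), fit = fit), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) cat("kinetic_fit: NOT converged\n")
  else cat(sprintf("kinetic_fit: Km = %.4g (SE %.2g), Vmax = %.4g (SE %.2g), n = %d\n",
                   x$km, x$km_se, x$vmax, x$vmax_se, x$n_points))
  invisible(x)
}

#' Vmax fold-acceleration between two kinetic fits
#'
#' @param fit_plus,fit_minus converged [fit_michaelis_menten()] results
#'   (e.g. with and without the co-substrate).
#' @return list with `ratio` (Vmax_plus / Vmax_minus) and `se` by first-order
#'   error propagation.
#' @export
fold_acceleration <- function(fit_plus, fit_minus) {
  stopifnot(fit_plus$converged, fit_minus$converged)
  if (fit_minus$vmax == 0) stop("zero denominator Vmax")
  ratio <- fit_plus$vmax / fit_minus$vmax
  se <- ratio * sqrt((fit_plus$vmax_se / fit_plus$vmax)^2 +
                       (fit_minus$vmax_se / fit_minus$vmax)^2)
  list(ratio = ratio, se = se)
}

#' Co-transport stoichiometry from paired rates
#'
#' Through-origin ordinary least squares of the second species' rate on the
#' first (slope = sum(xy)/sum(x^2)) with a seeded bootstrap 95% CI.
#'
#' @param paired data.frame with columns `ca_rate` and `pi_rate` at matched
#'   times; at least 3 pairs.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @return list with `ratio`, `ci` (2.5/97.5 percentiles), `n`.
#' @export
estimate_stoichiometry <- function(paired, n_boot = 1000L, seed = 1L) {
  stopifnot(all(c("ca_rate", "pi_rate") %in% names(paired)),
            nrow(paired) >= 3)
  x <- paired$ca_rate; y <- paired$pi_rate
  if (all(x == 0)) stop("all-zero reference rates")
  slope <- sum(x * y) / sum(x^2)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      j <- sample.int(length(x), replace = TRUE)
      sum(x[j] * y[j]) / sum(x[j]^2)
    }, numeric(1))
  })
  list(ratio = slope,
       ci = unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)),
       n = length(x))
}

# Wiseman single-site isotherm with per-injection dilution bookkeeping.
# Concentrations: any consistent unit; volumes in ml; heats in ucal with
# delta_h in kcal/mol and concentrations in mol/l scaled by `conc_scale`
# (e.g. 1e-6 if concentrations are uM).
itc_model_heats <- function(par, cell_conc, syringe_conc, injection_volume,
                            n_injections, cell_volume, conc_scale = 1) {
  kd <- par[["kd"]]; dh <- par[["delta_h"]]; n <- par[["n_sites"]]
  off <- par[["offset"]]
  dil <- 1 - injection_volume / cell_volume
  M <- cell_conc; X <- 0
  bound_prev <- 0
  q <- numeric(n_injections)
  for (i in seq_len(n_injections)) {
    M <- M * dil
    X <- X * dil + syringe_conc * injection_volume / cell_volume
    b <- n * M + X + kd
    bound <- (b - sqrt(b^2 - 4 * n * M * X)) / 2
    # kcal/mol * mol/l * l -> kcal; *1e9 -> ucal; conc_scale converts the
    # user's concentration unit to mol/l, cell_volume ml -> l is 1e-3
    q[i] <- dh * (bound - bound_prev * dil) * conc_scale *
      cell_volume * 1e-3 * 1e9 + off
    bound_prev <- bound
  }
  q
}

#' Fit a one-site binding isotherm to ITC injection heats
#'
#' Single-site 1:1 equilibrium solved per injection from the quadratic in the
#' current total concentrations with dilution bookkeeping;
#' heat_i = dH * V_cell * delta[bound] + offset, least squares over
#' (Kd, dH, n, offset) with Kd kept positive through a log parameterization.
#' Dilution heat is absorbed by the fitted constant offset. A warning flag is
#' raised when the Wiseman c-value (n * cell_conc / Kd) leaves [0.01, 1e4];
#' for low-c titrations fix the stoichiometry (`fix_n = 1`), the standard
#' practice when n is not identifiable.
#'
#' @param heats data.frame with columns `injection`, `heat` (ucal), e.g. from
#'   [gen_itc_isotherm()]; at least 5 injections.
#' @param cell_conc,syringe_conc,injection_volume,cell_volume titration setup
#'   (taken from the `setup` attribute when present).
#' @param conc_scale factor converting the concentration unit to mol/l
#'   (1e-6 for uM, 1e-3 for mM).
#' @param fix_n fix the stoichiometry at this value instead of fitting it
#'   (NULL = fit n).
#' @return object of class `binding_fit`: `kd`, `delta_h`, `n_sites`,
#'   standard errors, `kd_ci` (95%), `converged`, `c_value`, `c_warning`.
#' @export
fit_itc_one_site <- function(heats, cell_conc = NULL, syringe_conc = NULL,
                             injection_volume = NULL, cell_volume = NULL,
                             conc_scale = NULL, fix_n = NULL) {
  setup <- attr(heats, "setup")
  cell_conc <- cell_conc %||% setup$cell_conc
  syringe_conc <- syringe_conc %||% setup$syringe_conc
  injection_volume <- injection_volume %||% setup$injection_volume
  cell_volume <- cell_volume %||% setup$cell_volume
  conc_scale <- conc_scale %||% setup$conc_scale %||% 1
  stopifnot(!is.null(cell_conc), !is.null(syringe_conc),
            !is.null(injection_volume), !is.null(cell_volume))
  n_inj <- nrow(heats)
  if (n_inj < 5) stop("need at least 5 injections")
  y <- heats$heat
  fail <- function() structure(
    list(kd = NA_real_, delta_h = NA_real_, n_sites = NA_real_,
         kd_se = NA_real_, dh_se = NA_real_, kd_ci = c(NA_real_, NA_real_),
         converged = FALSE, c_value = NA_real_, c_warning = TRUE),
    class = "binding_fit")
  if (max(abs(y)) < .Machine$double.eps^0.5) return(fail())
  dh0 <- sum(y) / (cell_conc * conc_scale * cell_volume * 1e-3 * 1e9)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- sign(y[1]) * 1
  kd0 <- syringe_conc * injection_volume * n_inj / cell_volume / 2
  model <- function(lkd, dh, lgn, off) {
    n_val <- if (is.null(fix_n)) exp(lgn) else fix_n
    itc_model_heats(c(kd = exp(lkd), delta_h = dh, n_sites = n_val,
                      offset = off),
                    cell_conc, syringe_conc, injection_volume, n_inj,
                    cell_volume, conc_scale)
  }
  dat <- data.frame(y = y)
  fit <- tryCatch({
    if (is.null(fix_n))
      minpack.lm::nlsLM(y ~ model(lkd, dh, lgn, off), data = dat,
                        start = list(lkd = log(kd0), dh = dh0, lgn = 0,
                                     off = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
    else
      minpack.lm::nlsLM(y ~ model(lkd, dh, 0, off), data = dat,
                        start = list(lkd = log(kd0), dh = dh0, off = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 300))
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA, length(cf), length(cf), dimnames = list(names(cf), names(cf))))
  kd <- exp(cf[["lkd"]])
  n_sites <- if (is.null(fix_n)) exp(cf[["lgn"]]) else fix_n
  kd_se <- kd * sqrt(vc["lkd", "lkd"])
  tq <- stats::qt(0.975, df = n_inj - length(cf))
  c_value <- n_sites * cell_conc / kd
  structure(list(
    kd = kd, delta_h = cf[["dh"]], n_sites = n_sites,
    kd_se = kd_se, dh_se = sqrt(vc["dh", "dh"]),
    kd_ci = kd * exp(c(-1, 1) * tq * sqrt(vc["lkd", "lkd"])),
    converged = TRUE, c_value = c_value,
    c_warning = !is.na(c_value) && (c_value < 0.01 || c_value > 1e4)),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) cat("binding_fit: NOT converged\n")
  else cat(sprintf(
    "binding_fit: Kd = %.4g (SE %.2g), dH = %.3g kcal/mol, n = %.3g, c = %.3g%s\n",
    x$kd, x$kd_se, x$delta_h, x$n_sites, x$c_value,
    if (x$c_warning) " [c-value warning]" else ""))
  invisible(x)
}

#' Fit a single-exponential luminescence decay
#'
#' y = A exp(-t / tau) + baseline by nonlinear least squares; a trace whose
#' fitted amplitude is not positive or that does not decay is flagged.
#'
#' @param decay data.frame with columns `t` and `y`; at least 10 points
#'   spanning at least two lifetimes.
#' @return list with `tau`, `tau_se`, `amplitude`, `baseline`, `converged`.
#' @export
fit_lifetime <- function(decay) {
  stopifnot(all(c("t", "y") %in% names(decay)))
  if (nrow(decay) < 10) stop("need at least 10 points")
  tau0 <- tryCatch({
    iy <- decay$y > max(decay$y) * exp(-1)
    max(decay$t[iy])
  }, warning = function(w) diff(range(decay$t)) / 3)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(decay$t)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / exp(ltau)) + b, data = decay,
                      start = list(A = max(decay$y), ltau = log(tau0), b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau = NA_real_, tau_se = NA_real_, amplitude = NA_real_,
                baseline = NA_real_, converged = FALSE))
  cf <- stats::coef(fit)
  tau <- exp(cf[["ltau"]])
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 3, 3,
                   dimnames = list(names(cf), names(cf))))
  ok <- cf[["A"]] > 0 && tau < 10 * diff(range(decay$t))
  list(tau = tau, tau_se = tau * sqrt(vc["ltau", "ltau"]),
       amplitude = cf[["A"]], baseline = cf[["b"]], converged = ok)
}

#' Donor-acceptor distance from LRET lifetimes
#'
#' R = R0 * (tau_DA / (tau_D - tau_DA))^(1/6): the Forster relation between
#' the donor-only lifetime tau_D, the donor-acceptor lifetime tau_DA, and the
#' Forster radius R0 of the probe pair (user-supplied; it is a property of
#' the dye pair, not of the protein).
#'
#' @param tau_d donor-only lifetime (ms).
#' @param tau_da donor-acceptor lifetime (ms), 0 < tau_da < tau_d.
#' @param r0 Forster radius (Angstrom).
#' @return distance in Angstrom.
#' @export
forster_distance <- function(tau_d, tau_da, r0) {
  stopifnot(r0 > 0, tau_d > 0)
  if (tau_da <= 0) return(0)
  if (tau_da >= tau_d)
    stop("tau_DA must be smaller than tau_D (transfer efficiency <= 0)")
  r0 * (tau_da / (tau_d - tau_da))^(1 / 6)
}

#' Donor-acceptor lifetime implied by a distance (inverse Forster relation)
#'
#' @param r distance (Angstrom).
#' @param tau_d donor-only lifetime (ms).
#' @param r0 Forster radius (Angstrom).
#' @return tau_DA in ms.
#' @export
forster_tau_da <- function(r, tau_d, r0) {
  stopifnot(r > 0, tau_d > 0, r0 > 0)
  ratio <- (r / r0)^6
  tau_d * ratio / (1 + ratio)
}

#' Mono-anionic fraction of inorganic phosphate at a given pH
#'
#' Two-species Henderson-Hasselbalch approximation for the
#' H2PO4^- / HPO4^2- equilibrium: f = 1 / (1 + 10^(pH - pKa)).
#'
#' @param ph pH in [0, 14].
#' @param pka acid constant of the equilibrium (default 7.2).
#' @return fraction of phosphate in the mono-anionic form.
#' @export
phosphate_speciation <- function(ph, pka = 7.2) {
  stopifnot(all(ph >= 0 & ph <= 14), pka > 0, pka < 14)
  1 / (1 + 10^(ph - pka))
}

#' pH of maximal Vmax across a measured pH series
#'
#' Discrete argmax over the measured values (no interpolation); ties report
#' all tied pH values, and a maximum at the boundary of the series or a
#' single-point table is flagged.
#'
#' @param km_vmax_by_ph data.frame with columns `ph` and `vmax`.
#' @return list with `ph_peak` (possibly several), `boundary`, `degenerate`.
#' @export
ph_profile_peak <- function(km_vmax_by_ph) {
  stopifnot(all(c("ph", "vmax") %in% names(km_vmax_by_ph)))
  d <- km_vmax_by_ph[order(km_vmax_by_ph$ph), , drop = FALSE]
  if (nrow(d) == 1L)
    return(list(ph_peak = d$ph, boundary = TRUE, degenerate = TRUE))
  peaks <- d$ph[d$vmax == max(d$vmax)]
  list(ph_peak = peaks,
       boundary = any(peaks %in% range(d$ph)),
       degenerate = FALSE)
}
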