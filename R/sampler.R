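#' Sample an ensemble of restraint-satisfying binding-site models
#'
#' Generates side-chain/ion configurations on the fixed scaffold backbone that
#' satisfy a restraint ledger. Degrees of freedom are the side-chain chi
#' torsions of the nine site residues, the Ca2+ position, and a rigid-body
#' translation + rotation of the phosphate; backbone atoms never move. Each
#' model comes from an independently seeded restart: the state is perturbed
#' away from the scaffold configuration, annealed against the restraint
#' pseudo-energy (geometric cooling, T 10 -> 0.01 score units over 200
#' Metropolis steps), then polished by quasi-Newton minimization. A restart is
#' accepted when every per-term deviation is within `max_violation` sigmas.
#'
#' @param scaffold a [structure_model] from [build_scaffold()].
#' @param rs restraint set from [build_default_restraints()].
#' @param n_models number of accepted models to produce.
#' @param seed integer seed; the ensemble is a pure function of
#'   (scaffold, rs, n_models, seed, restart budget).
#' @param max_violation per-term acceptance tolerance in sigma units
#'   (default 3, i.e. every deviation <= 3 sigma).
#' @param max_restarts restart budget; if exhausted a partial ensemble is
#'   returned with a warning.
#' @param perturb_torsion,perturb_ion initial perturbation scales (degrees;
#'   Angstrom). Ion perturbation defaults to half the distance-restraint sigma
#'   and ion proposal steps to a fifth of it, so the annealer refines ion
#'   placement instead of random-walking across the penalty-free flat-bottom
#'   region; accepted models then concentrate in the restraint basin.
#' @return list of `site_model` objects, each carrying `structure`, `score`
#'   and `per_restraint` (the violation table).
#' @export
sample_ensemble <- function(scaffold, rs, n_models, seed,
                            max_violation = 3, max_restarts = 20 * n_models,
                            perturb_torsion = 25, perturb_ion = 0.05) {
  stopifnot(n_models >= 1)
  ev <- make_energy_evaluator(scaffold, rs)
  n_dof <- ev$n_dof
  models <- vector("list", n_models)
  accepted <- 0L
  with_seed(seed, {
    restarts <- 0L
    while (accepted < n_models && restarts < max_restarts) {
      restarts <- restarts + 1L
      state <- c(stats::runif(ev$n_torsion, -perturb_torsion, perturb_torsion),
                 stats::rnorm(3, 0, perturb_ion),          # Ca translation
                 stats::rnorm(3, 0, perturb_ion),          # P translation
                 stats::rnorm(3, 0, 0.10))                 # P rotation vector
      e <- ev$energy(state)
      temp <- 10; cool <- (0.01 / 10)^(1 / 199)
      for (step in 1:200) {
        cand <- state
        j <- sample.int(n_dof, 1L)
        cand[j] <- cand[j] + stats::rnorm(1, 0, ev$step_sd[j])
        e2 <- ev$energy(cand)
        if (e2 <= e || stats::runif(1) < exp((e - e2) / temp)) {
          state <- cand; e <- e2
        }
        temp <- temp * cool
      }
      if (max_violation > 0) {
        opt <- stats::optim(state, ev$energy_polish, method = "BFGS",
                            control = list(maxit = 60, reltol = 1e-7))
        state <- opt$par
      }
      res <- ev$evaluate(state)
      if (all(res$per_term$deviation <= max_violation * rs$sigma)) {
        accepted <- accepted + 1L
        models[[accepted]] <- res$model
      }
    }
  })
  if (accepted < n_models) {
    warning("sampler budget exhausted: accepted ", accepted, " of ",
            n_models, " requested models")
    models <- models[seq_len(accepted)]
  }
  models
}

# Precompiled energy evaluator: selectors resolved to row indices once, state
# vector -> coordinates via incremental torsion rotations, ion rigid moves.
make_energy_evaluator <- function(scaffold, rs) {
  at <- scaffold$atoms
  xyz0 <- as.matrix(at[, c("x", "y", "z")])
  key <- paste(at$resno, trimws(at$elety), sep = ":")
  idx <- function(sel) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (parts[2] == "O*")
      return(which(at$resno == as.integer(parts[1]) & at$elesy == "O"))
    i <- which(key == sel)
    if (length(i) != 1L) stop("cannot resolve selector: ", sel)
    i
  }

  # torsion DOF table
  tors <- list()
  for (lab in SITE_RESIDUES) {
    resno <- SITE_RESNO[[lab]]
    chis <- CHI_TABLE[[SITE_RESID3[[lab]]]]
    for (ch in chis) {
      tors[[length(tors) + 1L]] <- list(
        ax1 = idx(paste0(resno, ":", ch$axis[1])),
        ax2 = idx(paste0(resno, ":", ch$axis[2])),
        moved = vapply(ch$moved, function(a) idx(paste0(resno, ":", a)), 1L))
    }
  }
  n_torsion <- length(tors)
  i_ca <- which(at$resno == 501L)
  i_ph <- which(at$resno == 502L)
  ph_centroid <- colMeans(xyz0[i_ph, , drop = FALSE])

  # lean Rodrigues rotation for the hot loop (pts: n x 3)
  rot3 <- function(pts, o, k, th) {
    px <- pts[, 1] - o[1]; py <- pts[, 2] - o[2]; pz <- pts[, 3] - o[3]
    ct <- cos(th); st <- sin(th); vt <- 1 - ct
    kd <- k[1] * px + k[2] * py + k[3] * pz
    cx <- k[2] * pz - k[3] * py
    cy <- k[3] * px - k[1] * pz
    cz <- k[1] * py - k[2] * px
    cbind(o[1] + px * ct + cx * st + k[1] * kd * vt,
          o[2] + py * ct + cy * st + k[2] * kd * vt,
          o[3] + pz * ct + cz * st + k[3] * kd * vt)
  }

  rebuild <- function(state) {
    xyz <- xyz0
    for (k in seq_len(n_torsion)) {
      th <- state[k] * pi / 180
      if (abs(th) < 1e-12) next
      t <- tors[[k]]
      o <- xyz[t$ax1, ]
      ax <- xyz[t$ax2, ] - o
      ax <- ax / sqrt(sum(ax^2))
      xyz[t$moved, ] <- rot3(xyz[t$moved, , drop = FALSE], o, ax, th)
    }
    xyz[i_ca, ] <- xyz[i_ca, ] + state[n_torsion + 1:3]
    rot <- state[n_torsion + 7:9]
    ang <- sqrt(sum(rot^2))
    ph <- xyz[i_ph, , drop = FALSE]
    if (ang > 1e-12)
      ph <- rot3(ph, ph_centroid, rot / ang, ang)
    ph[, 1] <- ph[, 1] + state[n_torsion + 4]
    ph[, 2] <- ph[, 2] + state[n_torsion + 5]
    ph[, 3] <- ph[, 3] + state[n_torsion + 6]
    xyz[i_ph, ] <- ph
    xyz
  }

  # restraint terms as index records
  terms <- lapply(seq_len(nrow(rs)), function(i) {
    if (rs$kind[i] == "dihedral")
      list(kind = "dihedral",
           i = vapply(c(rs$a1[i], rs$a2[i], rs$a3[i], rs$a4[i]), idx, 1L),
           target = rs$target[i], sigma = rs$sigma[i])
    else
      list(kind = rs$kind[i], i1 = idx(rs$a1[i]), i2 = idx(rs$a2[i]),
           target = rs$target[i], sigma = rs$sigma[i])
  })

  term_devs <- function(xyz) {
    vapply(terms, function(t) {
      if (t$kind == "dihedral") {
        th <- dihedral_angle(xyz[t$i[1], ], xyz[t$i[2], ], xyz[t$i[3], ],
                             xyz[t$i[4], ])
        angle_dev(th - t$target)
      } else {
        d <- if (length(t$i2) > 1L) min(dist_to(xyz[t$i1, ],
                                                xyz[t$i2, , drop = FALSE]))
             else vnorm(xyz[t$i1, ] - xyz[t$i2, ])
        if (t$kind %in% c("upper", "upper_nearest")) max(0, d - t$target)
        else abs(d - t$target)
      }
    }, numeric(1))
  }

  energy <- function(state) {
    dev <- term_devs(rebuild(state))
    sum((dev / rs$sigma)^2) / 2
  }

  # Polish objective: restraint energy plus a weak seating term that prefers
  # flat-bottom (coordination) distances just inside their bound. Inside the
  # penalty-free region the restraint energy is flat, so without this term
  # the ion placement would be an artifact of the optimizer's entry point;
  # the seating term makes it determinate. Acceptance is still judged on the
  # restraint deviations alone.
  upper_terms <- which(rs$kind %in% c("upper", "upper_nearest"))
  seat_d <- rs$target[upper_terms] - rs$sigma[upper_terms]
  energy_polish <- function(state) {
    xyz <- rebuild(state)
    dev <- term_devs(xyz)
    seat <- vapply(upper_terms, function(j) {
      t <- terms[[j]]
      if (length(t$i2) > 1L) min(dist_to(xyz[t$i1, ], xyz[t$i2, , drop = FALSE]))
      else vnorm(xyz[t$i1, ] - xyz[t$i2, ])
    }, numeric(1))
    sum((dev / rs$sigma)^2) / 2 + 0.01 * sum((seat - seat_d)^2)
  }

  evaluate <- function(state) {
    xyz <- rebuild(state)
    s2 <- scaffold
    s2$atoms$x <- xyz[, 1]; s2$atoms$y <- xyz[, 2]; s2$atoms$z <- xyz[, 3]
    s2$source_id <- "site-model"
    en <- restraint_energy(s2, rs)
    list(model = structure(list(structure = s2, score = en$total,
                                per_restraint = en$per_term),
                           class = "site_model"),
         per_term = en$per_term)
  }

  list(energy = energy, energy_polish = energy_polish, evaluate = evaluate,
       n_dof = n_torsion + 9L,
       n_torsion = n_torsion,
       step_sd = c(rep(8, n_torsion), rep(0.02, 6), rep(0.02, 3)))
}

#' @export
print.site_model <- function(x, ...) {
  cat("site_model: restraint score", sprintf("%.4f", x$score),
      "| max deviation", sprintf("%.3f", max(x$per_restraint$deviation)), "\n")
  invisible(x)
}

#' Count coordinating O/N atoms around an ion
#'
#' @param model a `site_model` or [structure_model].
#' @param center residue number of the center ion (default 501, the Ca2+).
#' @param cutoff coordination cutoff in Angstrom (default 3.0).
#' @return list with `count` and `partners` (data.frame of coordinating atoms
#'   with distances, sorted by distance).
#' @export
coordination_count <- function(model, center = 501L, cutoff = 3.0) {
  s <- if (inherits(model, "site_model")) model$structure else model
  at <- s$atoms
  i0 <- which(at$resno == center & at$type == "HETATM" &
                at$elesy %in% c("CA", "P"))
  if (length(i0) < 1L) stop("center ion (resno ", center, ") absent")
  p <- c(at$x[i0[1]], at$y[i0[1]], at$z[i0[1]])
  d <- dist_to(p, as.matrix(at[, c("x", "y", "z")]))
  keep <- which(d <= cutoff & at$elesy %in% c("O", "N") &
                  !(at$resno == center))
  partners <- data.frame(elety = at$elety[keep], resid = at$resid[keep],
                         resno = at$resno[keep], distance = d[keep],
                         stringsAsFactors = FALSE)
  partners <- partners[order(partners$distance), , drop = FALSE]
  list(count = nrow(partners), partners = partners)
}
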