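#' Default geometric restraint ledger for the Ca2+/phosphate binding site
#'
#' Encodes the ten binding-site restraints used to model concurrent
#' Ca2+/phosphate recognition on the fixed scaffold backbone:
#' \describe{
#'   \item{r1}{flat-bottom upper-distance restraints (2.6 A, sigma 0.1 A) from
#'     Ca2+ to each of the four carboxylate oxygens of E72 and E255 (4 terms).}
#'   \item{r2}{same form, Ca2+ to the nearest phosphate oxygen.}
#'   \item{r3}{same form, Ca2+ to the G68 backbone carbonyl oxygen.}
#'   \item{r4}{same form, Ca2+ to the N69 side-chain carbonyl oxygen (OD1).}
#'   \item{r5}{target distance P--H256 ND1 = 3.9 A.}
#'   \item{r6}{target distance P--N252 CG = 4.5 A.}
#'   \item{r7}{target distance P--S278 OG = 4.5 A (the ledger uses the serine
#'     OG; a literal "CG of S278" does not exist for serine and the intended
#'     side-chain landmark is taken to be the hydroxyl oxygen).}
#'   \item{r8}{target distance Q281 OE1 -- N69 ND2 = 3.2 A.}
#'   \item{r9}{target distance N252 CG -- N99 CG = 4.2 A.}
#'   \item{r10}{planarity dihedrals Ca--CD--OE1--OE2 of E72 and of E255,
#'     target 0 deg, sigma 20 deg (2 terms), imposing bidentate coordination.}
#' }
#' Together r1--r4 imply a Ca2+ coordination number of 7 (four carboxylate
#' oxygens, one phosphate oxygen, the G68 carbonyl and the N69 side-chain
#' carbonyl).
#'
#' @param scaffold a [structure_model] containing all referenced atoms; each
#'   selector is validated against it.
#' @param sigma_distance sigma (A) for the distance restraints; default 0.1 A.
#' @param sigma_dihedral sigma (degrees) for the planarity dihedrals;
#'   default 20.
#' @return object of class `restraint_set`: a data.frame of scalar terms with
#'   columns `id`, `kind` (`"upper"`, `"target"`, `"dihedral"`), selectors
#'   `a1..a4` (as `"resno:atom"` strings; `a3`,`a4` only for dihedrals),
#'   `target` and `sigma`.
#' @export
build_default_restraints <- function(scaffold, sigma_distance = 0.1,
                                     sigma_dihedral = 20) {
  term <- function(id, kind, a1, a2, a3 = NA, a4 = NA, target, sigma)
    data.frame(id = id, kind = kind, a1 = a1, a2 = a2, a3 = a3, a4 = a4,
               target = target, sigma = sigma, stringsAsFactors = FALSE)
  ca <- "501:CA"
  terms <- rbind(
    term("r1", "upper", ca, "72:OE1", target = 2.6, sigma = sigma_distance),
    term("r1", "upper", ca, "72:OE2", target = 2.6, sigma = sigma_distance),
    term("r1", "upper", ca, "255:OE1", target = 2.6, sigma = sigma_distance),
    term("r1", "upper", ca, "255:OE2", target = 2.6, sigma = sigma_distance),
    term("r2", "upper_nearest", ca, "502:O*", target = 2.6,
         sigma = sigma_distance),
    term("r3", "upper", ca, "68:O", target = 2.6, sigma = sigma_distance),
    term("r4", "upper", ca, "69:OD1", target = 2.6, sigma = sigma_distance),
    term("r5", "target", "502:P", "256:ND1", target = 3.9,
         sigma = sigma_distance),
    term("r6", "target", "502:P", "252:CG", target = 4.5,
         sigma = sigma_distance),
    term("r7", "target", "502:P", "278:OG", target = 4.5,
         sigma = sigma_distance),
    term("r8", "target", "281:OE1", "69:ND2", target = 3.2,
         sigma = sigma_distance),
    term("r9", "target", "252:CG", "99:CG", target = 4.2,
         sigma = sigma_distance),
    term("r10", "dihedral", ca, "72:CD", "72:OE1", "72:OE2", target = 0,
         sigma = sigma_dihedral),
    term("r10", "dihedral", ca, "255:CD", "255:OE1", "255:OE2", target = 0,
         sigma = sigma_dihedral))
  # validate every selector against the scaffold
  sels <- unique(stats::na.omit(unlist(terms[, c("a1", "a2", "a3", "a4")])))
  for (sel in sels) resolve_selector(scaffold, sel)
  structure(terms, class = c("restraint_set", "data.frame"))
}

# "resno:atom" -> coordinates; "502:O*" resolves to the matrix of all
# phosphate oxygens (nearest-atom restraints pick their own partner).
resolve_selector <- function(s, sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed selector: ", sel)
  resno <- as.integer(parts[1]); atom <- parts[2]
  if (atom == "O*") {
    at <- s$atoms
    i <- which(at$resno == resno & at$elesy == "O")
    if (!length(i)) stop("selector ", sel, " resolves to no atoms")
    return(as.matrix(at[i, c("x", "y", "z")]))
  }
  tryCatch(atom_xyz(s, resno, atom),
           error = function(e) stop("cannot resolve selector '", sel, "': ",
                                    conditionMessage(e)))
}

#' Restraint pseudo-energy of a model
#'
#' Flat-bottom upper-distance terms contribute 0 for d <= target and
#' ((d - target)/sigma)^2 / 2 beyond it; target-distance terms contribute
#' ((d - target)/sigma)^2 / 2 everywhere; dihedral terms
#' ((delta theta)/sigma)^2 / 2 with delta theta the minimal angular difference
#' to the target. The total is the sum over all scalar terms.
#'
#' @param model a [structure_model] (or `site_model`) with resolvable selectors.
#' @param rs a `restraint_set` from [build_default_restraints()].
#' @return list with `total` (dimensionless score) and `per_term` data.frame
#'   (`id`, `kind`, `value` (A or deg), `target`, `deviation`, `energy`).
#' @export
restraint_energy <- function(model, rs) {
  s <- if (inherits(model, "site_model")) model$structure else model
  n <- nrow(rs)
  value <- deviation <- energy <- numeric(n)
  for (i in seq_len(n)) {
    kind <- rs$kind[i]
    if (kind == "dihedral") {
      p <- lapply(c(rs$a1[i], rs$a2[i], rs$a3[i], rs$a4[i]),
                  function(a) resolve_selector(s, a))
      value[i] <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
      deviation[i] <- angle_dev(value[i] - rs$target[i])
      energy[i] <- (deviation[i] / rs$sigma[i])^2 / 2
    } else {
      p1 <- resolve_selector(s, rs$a1[i])
      p2 <- resolve_selector(s, rs$a2[i])
      d <- if (is.matrix(p2)) min(dist_to(p1, p2)) else vnorm(p1 - p2)
      value[i] <- d
      if (kind %in% c("upper", "upper_nearest")) {
        deviation[i] <- max(0, d - rs$target[i])
      } else {
        deviation[i] <- abs(d - rs$target[i])
      }
      energy[i] <- (deviation[i] / rs$sigma[i])^2 / 2
    }
  }
  per_term <- data.frame(id = rs$id, kind = rs$kind, value = value,
                         target = rs$target, deviation = deviation,
                         energy = energy, stringsAsFactors = FALSE)
  list(total = sum(energy), per_term = per_term)
}
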