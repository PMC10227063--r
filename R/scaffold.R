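#' Specification for the synthetic YfkE-like binding-site scaffold
#'
#' The scaffold stands in for the alpha-repeat region of an inward-facing
#' CAX antiporter: the nine residues implicated in Ca2+/phosphate recognition
#' (G68, N69, E72, N99, N252, E255, H256, S278, Q281) arranged around seed
#' positions for one Ca2+ ion and one mono-anionic phosphate (H2PO4-).
#' Geometry is idealized -- bond lengths are standard, the inter-residue
#' distances are chosen so the default restraint ledger is satisfiable -- and
#' no fidelity to any deposited backbone is claimed.
#'
#' @param residues character vector of residue labels; the default (and only
#'   valid complete set) is the nine site residues.
#' @return object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(residues = SITE_RESIDUES) {
  bad <- setdiff(residues, SITE_RESIDUES)
  if (length(bad))
    stop("unknown residue identity: ", paste(bad, collapse = ", "))
  if (anyDuplicated(residues))
    stop("residue list contains duplicates")
  structure(list(residues = residues), class = "scaffold_spec")
}

SITE_RESIDUES <- c("G68", "N69", "E72", "N99", "N252", "E255", "H256",
                   "S278", "Q281")

SITE_RESNO <- c(G68 = 68L, N69 = 69L, E72 = 72L, N99 = 99L, N252 = 252L,
                E255 = 255L, H256 = 256L, S278 = 278L, Q281 = 281L)

SITE_RESID3 <- c(G68 = "GLY", N69 = "ASN", E72 = "GLU", N99 = "ASN",
                 N252 = "ASN", E255 = "GLU", H256 = "HIS", S278 = "SER",
                 Q281 = "GLN")

#' Build the synthetic binding-site scaffold
#'
#' Deterministically constructs a `structure_model` containing the nine site
#' residues (full side chains plus an N/CA/C/O backbone cap per residue, frozen
#' during sampling), one Ca2+ ion and one H2PO4- ion, in a geometry that
#' exactly satisfies the default restraint ledger: bidentate E72/E255
#' carboxylates, G68 backbone carbonyl and the N69 side-chain carbonyl around
#' Ca2+ (coordination number 7 including one phosphate oxygen), and the
#' phosphate cradled by H256, N252, S278 with the N69--Q281 and N99--N252
#' polar contacts in place.
#'
#' @param spec a [scaffold_spec]; must contain all nine site residues.
#' @return a [structure_model] with `source_id = "synthetic-scaffold"`.
#' @export
build_scaffold <- function(spec = scaffold_spec()) {
  if (!inherits(spec, "scaffold_spec")) stop("spec must be a scaffold_spec")
  missing_res <- setdiff(SITE_RESIDUES, spec$residues)
  if (length(missing_res))
    stop("scaffold spec missing residue(s): ",
         paste(missing_res, collapse = ", "))

  place <- function(base, dir, len) base + len * unitv(dir)
  rows <- list()
  add <- function(label, atoms_xyz, chain = "A") {
    resno <- SITE_RESNO[[label]]
    resid <- SITE_RESID3[[label]]
    for (nm in names(atoms_xyz)) {
      p <- atoms_xyz[[nm]]
      rows[[length(rows) + 1L]] <<- data.frame(
        elety = nm, resid = resid, resno = resno, chain = chain,
        x = p[1], y = p[2], z = p[3], type = "ATOM",
        elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }
  }

  ca_ion <- c(0, 0, 0)
  rc <- 2.45   # Ca--O coordination distance (within the 2.6 A flat bottom)

  ## E72: bidentate carboxylate centered on +x, carboxylate plane = z = 0
  half <- asin(1.093 / rc)               # half-angle giving O--O ~ 2.19 A
  oe1 <- rc * c(cos(half), sin(half), 0)
  oe2 <- rc * c(cos(half), -sin(half), 0)
  cd  <- c(cos(half) * rc + sqrt(1.25^2 - 1.093^2), 0, 0)
  cg  <- place(cd, c(1, 0, 0.35), 1.52)
  cb  <- place(cg, c(1, 0, -0.35), 1.53)
  caa <- place(cb, c(1, 0.45, 0.25), 1.53)
  add("E72", list(N = place(caa, c(0.25, 1, -0.2), 1.46), CA = caa,
                  C = place(caa, c(0.6, -0.75, 0.3), 1.52),
                  O = place(place(caa, c(0.6, -0.75, 0.3), 1.52),
                            c(0.1, -1, 0.3), 1.23),
                  CB = cb, CG = cg, CD = cd, OE1 = oe1, OE2 = oe2))

  ## E255: mirror image through x -> -x
  m <- function(p) c(-p[1], p[2], p[3])
  cd2 <- m(cd); cg2 <- m(cg); cb2 <- m(cb); caa2 <- m(caa)
  add("E255", list(N = m(place(caa, c(0.25, 1, -0.2), 1.46)), CA = caa2,
                   C = m(place(caa, c(0.6, -0.75, 0.3), 1.52)),
                   O = m(place(place(caa, c(0.6, -0.75, 0.3), 1.52),
                               c(0.1, -1, 0.3), 1.23)),
                   CB = cb2, CG = cg2, CD = cd2, OE1 = m(oe1), OE2 = m(oe2)))

  ## G68: backbone carbonyl O coordinates Ca from below
  o68 <- c(0, 0, -rc)
  c68 <- place(o68, c(0.4, 0.4, -0.82), 1.23)
  ca68 <- place(c68, c(0.9, -0.2, -0.45), 1.52)
  add("G68", list(N = place(ca68, c(0.2, 0.9, -0.4), 1.46), CA = ca68,
                  C = c68, O = o68))

  ## N69: side-chain carbonyl O (OD1) coordinates Ca from +y
  od1 <- c(0, rc, 0)
  cg69 <- place(od1, c(0.25, 0.95, 0.2), 1.23)
  nd2_69 <- place(cg69, c(1.0, 0.35, 0.1), 1.33)
  cb69 <- place(cg69, c(-0.8, 0.55, 0.3), 1.52)
  ca69 <- place(cb69, c(-0.6, 0.7, -0.3), 1.53)
  add("N69", list(N = place(ca69, c(-1, 0.1, 0.3), 1.46), CA = ca69,
                  C = place(ca69, c(0.1, 0.9, -0.5), 1.52),
                  O = place(place(ca69, c(0.1, 0.9, -0.5), 1.52),
                            c(0.4, 0.3, -1), 1.23),
                  CB = cb69, CG = cg69, OD1 = od1, ND2 = nd2_69))

  ## phosphate: one oxygen coordinates Ca along +z, P beyond it
  o1 <- c(0, 0, rc)
  p_atom <- place(o1, c(0, 0.25, 0.97), 1.55)
  d0 <- unitv(o1 - p_atom)
  # three remaining tetrahedral directions around d0
  ref <- c(1, 0, 0)
  e1 <- unitv(ref - sum(ref * d0) * d0)
  e2 <- pracma_cross(d0, e1)
  tet <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi)
    unitv(-d0 * cos(70.53 * pi / 180) +
            sin(70.53 * pi / 180) * (cos(phi) * e1 + sin(phi) * e2)))
  po <- lapply(tet, function(u) place(p_atom, u, 1.55))

  ## H256: imidazole ND1 is a phosphate acceptor contact at 3.9 A from P
  nd1 <- place(p_atom, c(0, 0.55, 0.84), 3.9)
  # regular-pentagon imidazole (bond ~1.37 A -> circumradius 1.16 A) in the
  # plane spanned by u/v, with ND1 on the ring facing the phosphate
  u <- unitv(c(0.9, 0.35, 0.1)); v <- unitv(pracma_cross(u, c(0, 0.55, 0.84)))
  ring_r <- 1.165
  c0 <- nd1 + ring_r * u
  e1 <- unitv(nd1 - c0)
  ring_at <- function(deg) c0 + ring_r * (cos(deg * pi / 180) * e1 +
                                            sin(deg * pi / 180) * v)
  ce1 <- ring_at(72); ne2 <- ring_at(144); cd2_256 <- ring_at(216)
  cg256 <- ring_at(288)
  outw <- unitv(cg256 - c0)
  cb256 <- place(cg256, outw + 0.25 * v, 1.50)
  ca256 <- place(cb256, outw - 0.45 * v, 1.53)
  away256 <- unitv(ca256 - cb256)
  add("H256", list(N = place(ca256, away256 + 0.9 * v, 1.46), CA = ca256,
                   C = place(ca256, away256 - 0.9 * v, 1.52),
                   O = place(place(ca256, away256 - 0.9 * v, 1.52),
                             away256 - 1.8 * v, 1.23),
                   CB = cb256, CG = cg256, ND1 = nd1, CD2 = cd2_256,
                   CE1 = ce1, NE2 = ne2))

  ## N252: CG at 4.5 A from P; N99: CG at 4.2 A from N252 CG
  cg252 <- place(p_atom, c(-0.85, 0.35, 0.4), 4.5)
  od1_252 <- place(cg252, c(-0.2, 1, 0.1), 1.23)
  nd2_252 <- place(cg252, c(-0.9, -0.4, 0.3), 1.33)
  cb252 <- place(cg252, c(-0.4, 0.2, -1), 1.52)
  ca252 <- place(cb252, c(-0.8, 0.4, -0.5), 1.53)
  add("N252", list(N = place(ca252, c(0, 1, -0.4), 1.46), CA = ca252,
                   C = place(ca252, c(-0.9, -0.4, -0.2), 1.52),
                   O = place(place(ca252, c(-0.9, -0.4, -0.2), 1.52),
                             c(-0.3, -1, 0.2), 1.23),
                   CB = cb252, CG = cg252, OD1 = od1_252, ND2 = nd2_252))

  cg99 <- place(cg252, c(-0.45, -0.6, 0.7), 4.2)
  od1_99 <- place(cg99, c(0.3, -1, 0.2), 1.23)
  nd2_99 <- place(cg99, c(-1, 0.2, 0.4), 1.33)
  cb99 <- place(cg99, c(-0.2, 0.5, 1), 1.52)
  ca99 <- place(cb99, c(-0.7, 0.6, 0.4), 1.53)
  add("N99", list(N = place(ca99, c(0.2, 1, 0.1), 1.46), CA = ca99,
                  C = place(ca99, c(-1, 0, 0.4), 1.52),
                  O = place(place(ca99, c(-1, 0, 0.4), 1.52),
                            c(-0.4, -0.9, 0.3), 1.23),
                  CB = cb99, CG = cg99, OD1 = od1_99, ND2 = nd2_99))

  ## S278: hydroxyl OG at 4.5 A from P
  og <- place(p_atom, c(0.9, 0.3, 0.25), 4.5)
  cb278 <- place(og, c(1, 0.3, 0.4), 1.42)
  ca278 <- place(cb278, c(0.7, -0.5, 0.6), 1.53)
  add("S278", list(N = place(ca278, c(0, -1, 0.3), 1.46), CA = ca278,
                   C = place(ca278, c(1, 0.4, 0.1), 1.52),
                   O = place(place(ca278, c(1, 0.4, 0.1), 1.52),
                             c(0.4, 1, 0.1), 1.23),
                   CB = cb278, OG = og))

  ## Q281: OE1 3.2 A from N69 ND2 (hydrogen-bond partner)
  oe1_281 <- place(nd2_69, c(1, 0.4, 0.2), 3.2)
  cd281 <- place(oe1_281, c(0.5, 1, 0), 1.23)
  ne2_281 <- place(cd281, c(1, -0.35, 0.1), 1.33)
  cg281 <- place(cd281, c(-0.3, 1, 0.35), 1.52)
  cb281 <- place(cg281, c(0.4, 0.8, -0.5), 1.53)
  ca281 <- place(cb281, c(0.9, 0.3, 0.4), 1.53)
  add("Q281", list(N = place(ca281, c(0, 1, 0.5), 1.46), CA = ca281,
                   C = place(ca281, c(1, -0.4, 0.2), 1.52),
                   O = place(place(ca281, c(1, -0.4, 0.2), 1.52),
                             c(0.3, -1, -0.1), 1.23),
                   CB = cb281, CG = cg281, CD = cd281, OE1 = oe1_281,
                   NE2 = ne2_281))

  at <- do.call(rbind, rows)
  ion_rows <- data.frame(
    elety = c("CA", "P", "O1", "O2", "O3", "O4"),
    resid = c("CA", rep("2HP", 5)),
    resno = c(501L, rep(502L, 5)), chain = "X",
    x = c(ca_ion[1], p_atom[1], o1[1], po[[1]][1], po[[2]][1], po[[3]][1]),
    y = c(ca_ion[2], p_atom[2], o1[2], po[[1]][2], po[[2]][2], po[[3]][2]),
    z = c(ca_ion[3], p_atom[3], o1[3], po[[1]][3], po[[2]][3], po[[3]][3]),
    type = "HETATM",
    elesy = c("CA", "P", "O", "O", "O", "O"), stringsAsFactors = FALSE)
  at <- rbind(at, ion_rows)
  at$eleno <- seq_len(nrow(at))
  at <- at[, c("eleno", "elety", "resid", "resno", "chain", "x", "y", "z",
               "type", "elesy")]
  structure_model(at, resolution = NA_real_, source_id = "synthetic-scaffold")
}

# Side-chain torsion topology: per residue type, each chi entry gives the
# rotation axis (two atom names) and the atoms displaced by that rotation.
CHI_TABLE <- list(
  GLU = list(list(axis = c("CA", "CB"), moved = c("CG", "CD", "OE1", "OE2")),
             list(axis = c("CB", "CG"), moved = c("CD", "OE1", "OE2")),
             list(axis = c("CG", "CD"), moved = c("OE1", "OE2"))),
  ASN = list(list(axis = c("CA", "CB"), moved = c("CG", "OD1", "ND2")),
             list(axis = c("CB", "CG"), moved = c("OD1", "ND2"))),
  HIS = list(list(axis = c("CA", "CB"),
                  moved = c("CG", "ND1", "CD2", "CE1", "NE2")),
             list(axis = c("CB", "CG"), moved = c("ND1", "CD2", "CE1", "NE2"))),
  SER = list(list(axis = c("CA", "CB"), moved = "OG")),
  GLN = list(list(axis = c("CA", "CB"), moved = c("CG", "CD", "OE1", "NE2")),
             list(axis = c("CB", "CG"), moved = c("CD", "OE1", "NE2")),
             list(axis = c("CG", "CD"), moved = c("OE1", "NE2"))),
  GLY = list())
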