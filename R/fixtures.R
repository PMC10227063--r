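#' Plant a labelled set of mini-PDB survey fixtures
#'
#' Writes a self-contained fixture set for exercising the structure survey:
#' two true positives (shared Ca2+/phosphate site at <= 3.0 A, flanked by two
#' glutamates and one histidine, resolution <= 3.0 A) and four decoys that
#' each fail exactly one criterion -- ion distance (5.0 A), flanking motif
#' (one acidic missing), resolution (3.5 A), and sequence redundancy (a valid
#' site whose chain is >70% identical to the first positive). A JSON truth
#' sidecar records the expected label and failing criterion per file.
#'
#' Fixture chains carry a CA-only trace (for sequence content) away from the
#' site, plus side-chain functional atoms around the ions; resolutions are
#' written as standard `REMARK   2` records so fixtures and real files share
#' one parse path.
#'
#' @param out_dir writable output directory (created if absent).
#' @param seed integer seed controlling sequences and coordinate jitter.
#' @return invisibly, a list with `files` (paths) and `truth` (data.frame
#'   `file`, `label` ("accept"/"reject"), `reason`).
#' @export
plant_survey_fixtures <- function(out_dir, seed = 11L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("unwritable directory: ", out_dir)
  with_seed(seed, {
    aa20 <- names(AA_321)
    seq1 <- sample(aa20, 30, replace = TRUE)
    seq2 <- sample(aa20, 30, replace = TRUE)
    seq_red <- seq1
    seq_red[sample(30, 3)] <- sample(aa20, 3, replace = TRUE)

    spec <- list(
      pos_a = list(res = 2.0, dist = 3.0, motif = "EEH", seq = seq1),
      pos_b = list(res = 2.5, dist = 2.8, motif = "DEH", seq = seq2),
      neg_distance = list(res = 2.0, dist = 5.0, motif = "EEH",
                          seq = sample(aa20, 30, TRUE)),
      neg_motif = list(res = 2.0, dist = 3.0, motif = "EH",
                       seq = sample(aa20, 30, TRUE)),
      neg_resolution = list(res = 3.5, dist = 3.0, motif = "EEH",
                            seq = sample(aa20, 30, TRUE)),
      neg_redundant = list(res = 2.6, dist = 3.0, motif = "EEH",
                           seq = seq_red))
    files <- character(0)
    for (nm in names(spec)) {
      sp <- spec[[nm]]
      s <- fixture_structure(nm, sp$res, sp$dist, sp$motif, sp$seq)
      f <- file.path(out_dir, paste0(nm, ".pdb"))
      write_structure_pdb(s, f)
      files[nm] <- f
    }
  })
  truth <- data.frame(
    file = basename(files),
    label = c("accept", "accept", "reject", "reject", "reject", "reject"),
    reason = c("", "", "ion_distance", "motif", "resolution", "redundancy"),
    stringsAsFactors = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(list(files = unname(files), truth = truth))
}

# One mini fixture: CA trace chain (sequence content), Ca2+ + PO4 site at a
# controlled minimum ion distance, and flanking side-chain functional atoms.
fixture_structure <- function(id, resolution, ion_dist, motif, seq3) {
  rows <- list()
  push <- function(elety, resid, resno, chain, p, type, elesy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      elety = elety, resid = resid, resno = resno, chain = chain,
      x = p[1], y = p[2], z = p[3], type = type, elesy = elesy,
      stringsAsFactors = FALSE)
  }
  # CA-only chain trace, 3.8 A spacing, far from the site
  for (i in seq_along(seq3))
    push("CA", seq3[i], i, "A",
         c(3.8 * i, 20 + stats::rnorm(1, 0, 0.2), stats::rnorm(1, 0, 0.2)),
         "ATOM", "C")
  # site: Ca at origin; phosphate O1 at ion_dist along +z, P beyond it
  push("CA", "CA", 901L, "B", c(0, 0, 0), "HETATM", "CA")
  o1 <- c(0, 0, ion_dist)
  p_at <- o1 + c(0, 0.37, 1.5)
  push("P", "PO4", 902L, "B", p_at, "HETATM", "P")
  push("O1", "PO4", 902L, "B", o1, "HETATM", "O")
  push("O2", "PO4", 902L, "B", p_at + c(1.4, 0.3, 0.5), "HETATM", "O")
  push("O3", "PO4", 902L, "B", p_at + c(-1.4, 0.3, 0.5), "HETATM", "O")
  push("O4", "PO4", 902L, "B", p_at + c(0, -1.2, 0.9), "HETATM", "O")
  # flanking functional atoms (residues with side-chain atoms only, so the
  # chain sequence stays defined by the CA trace)
  flank <- strsplit(motif, "")[[1]]
  dirs <- list(c(2.5, 0, 0), c(-2.5, 0.3, 0), c(0, 2.6, 1.2), c(0, -2.6, 1))
  for (k in seq_along(flank)) {
    p <- dirs[[k]]
    resno <- 200L + k
    if (flank[k] == "E") {
      push("OE1", "GLU", resno, "A", p, "ATOM", "O")
      push("OE2", "GLU", resno, "A", p + c(0.6, 1.9, 0.6), "ATOM", "O")
      push("CD", "GLU", resno, "A", p + c(0.8, 1.0, 0.2), "ATOM", "C")
    } else if (flank[k] == "D") {
      push("OD1", "ASP", resno, "A", p, "ATOM", "O")
      push("OD2", "ASP", resno, "A", p + c(0.6, 1.9, 0.6), "ATOM", "O")
      push("CG", "ASP", resno, "A", p + c(0.8, 1.0, 0.2), "ATOM", "C")
    } else if (flank[k] == "H") {
      push("ND1", "HIS", resno, "A", p, "ATOM", "N")
      push("NE2", "HIS", resno, "A", p + c(0.8, 1.8, 0.8), "ATOM", "N")
    }
  }
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  at <- at[, c("eleno", "elety", "resid", "resno", "chain", "x", "y", "z",
               "type", "elesy")]
  structure_model(at, resolution = resolution, source_id = id)
}
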