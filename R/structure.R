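#' Structure container shared by the survey, modeling and clustering stages
#'
#' A `structure_model` is a light S3 wrapper around an atom table (one row per
#' atom, PDB-style naming) plus the metadata the site survey needs: the crystal
#' resolution (when the file records one) and per-chain one-letter sequences.
#'
#' @param atoms data.frame with columns `eleno`, `elety` (atom name), `resid`
#'   (3-letter residue/het code), `resno`, `chain`, `x`, `y`, `z`, `type`
#'   (`"ATOM"` or `"HETATM"`), `elesy` (element symbol).
#' @param resolution crystallographic resolution in Angstrom, or `NA` when the
#'   source carries none.
#' @param source_id free-text identifier (file name, PDB id, "synthetic", ...).
#'
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, resolution = NA_real_, source_id = "") {
  req <- c("eleno", "elety", "resid", "resno", "chain", "x", "y", "z",
           "type", "elesy")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(atoms)) stop("structure has no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (!is.na(resolution) && resolution <= 0)
    stop("resolution must be positive when present")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom (chain, residue number, atom name) entries")
  structure(
    list(atoms = atoms, resolution = as.numeric(resolution),
         source_id = source_id),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", x$source_id, "\n")
  cat("  atoms:", nrow(x$atoms),
      " chains:", paste(unique(x$atoms$chain), collapse = ","), "\n")
  cat("  resolution:",
      if (is.na(x$resolution)) "absent" else sprintf("%.2f A", x$resolution),
      "\n")
  invisible(x)
}

#' Parse a PDB or mmCIF file into a structure_model
#'
#' Coordinates are read with bio3d; HETATM entities (metal ions, phosphate
#' ligands) are retained. The resolution is taken from the `REMARK   2` record
#' (PDB) or the `_refine.ls_d_res_high` item (mmCIF) and left `NA` when absent.
#'
#' @param file path to a `.pdb` or `.cif` file.
#' @return a [structure_model].
#' @export
parse_structure <- function(file) {
  if (!file.exists(file)) stop("cannot read file: ", file)
  is_cif <- grepl("\\.cif$", file, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(if (is_cif) bio3d::read.cif(file) else bio3d::read.pdb(file)),
    error = function(e) stop("parse error in '", file, "': ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("no atoms parsed from '", file, "'")
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z, type = at$type,
    elesy = toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                  substr(trimws(at$elety), 1, 1), at$elesy))),
    stringsAsFactors = FALSE)
  res <- if (is_cif) cif_resolution(file) else pdb_remark2_resolution(file)
  structure_model(atoms, resolution = res, source_id = basename(file))
}

pdb_remark2_resolution <- function(file) {
  ln <- grep("^REMARK   2 RESOLUTION", readLines(file, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NA_real_)
  tail_txt <- sub("^REMARK\\s+2\\s+RESOLUTION\\.?", "", ln[1])
  m <- regmatches(tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

cif_resolution <- function(file) {
  ln <- grep("_refine\\.ls_d_res_high", readLines(file, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NA_real_)
  v <- suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2]))
  if (is.na(v)) NA_real_ else v
}

#' Per-chain one-letter amino-acid sequences of a structure
#'
#' Derived from the CA atoms of standard residues, in residue-number order.
#'
#' @param s a [structure_model].
#' @return named character vector, one sequence per chain (chains with no
#'   standard amino acids are dropped).
#' @export
chain_sequences <- function(s) {
  at <- s$atoms
  ca <- at[at$type == "ATOM" & trimws(at$elety) == "CA", , drop = FALSE]
  ca <- ca[ca$resid %in% names(AA_321), , drop = FALSE]
  if (!nrow(ca)) return(character(0))
  out <- vapply(split(ca, ca$chain), function(d) {
    d <- d[order(d$resno), , drop = FALSE]
    paste(AA_321[d$resid], collapse = "")
  }, character(1))
  out[nchar(out) > 0]
}

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

# Look up one atom's coordinates by residue number + atom name (chain-blind:
# site structures here are single chain for protein, ions on their own chain).
atom_xyz <- function(s, resno, elety) {
  at <- s$atoms
  i <- which(at$resno == resno & trimws(at$elety) == elety)
  if (length(i) != 1L)
    stop("selector (resno ", resno, ", atom ", elety, ") resolves to ",
         length(i), " atoms")
  c(at$x[i], at$y[i], at$z[i])
}

#' Write a structure_model (or several, as MODEL blocks) to a PDB file
#'
#' Minimal fixed-column PDB writer that also emits the `REMARK   2` resolution
#' record, so fixture and real files share one parse path.
#'
#' @param s a [structure_model] or a list of them (multi-model output).
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_structure_pdb <- function(s, file) {
  models <- if (inherits(s, "structure_model")) list(s) else s
  con <- file(file, "w")
  on.exit(close(con))
  res <- models[[1]]$resolution
  if (!is.na(res))
    writeLines(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", res), con)
  multi <- length(models) > 1L
  for (k in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    at <- models[[k]]$atoms
    lines <- sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$type, at$eleno,
      ifelse(nchar(trimws(at$elety)) < 4, paste0(" ", trimws(at$elety)),
             trimws(at$elety)),
      at$resid, at$chain, at$resno, at$x, at$y, at$z, 1, 0, at$elesy)
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(file)
}
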