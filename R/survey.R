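#' Selection criteria for the shared Ca2+/phosphate site survey
#'
#' The four filters applied, in order, by [run_survey()]: crystallographic
#' resolution, co-bound-site geometry (minimum Ca-to-phosphate-atom distance),
#' flanking-residue motif (two acidic side chains plus one histidine), and
#' sequence redundancy against previously accepted structures.
#'
#' @param max_resolution resolution cutoff in Angstrom (default 3.0).
#' @param max_ion_distance maximum Ca-to-phosphate minimum inter-atom distance
#'   in Angstrom defining a common binding site (default 3.2).
#' @param identity_threshold pairwise sequence identity above which a hit is
#'   redundant (default 0.70).
#' @param flank_cutoff distance (A) from either ion to a side-chain functional
#'   atom for a residue to count as flanking (default 4.5).
#' @param phosphate_codes het codes treated as phosphate entities.
#' @return object of class `survey_criteria`.
#' @export
survey_criteria <- function(max_resolution = 3.0, max_ion_distance = 3.2,
                            identity_threshold = 0.70, flank_cutoff = 4.5,
                            phosphate_codes = c("PO4", "2HP", "PI", "H2P")) {
  stopifnot(max_resolution > 0, max_ion_distance > 0, flank_cutoff > 0,
            identity_threshold > 0, identity_threshold <= 1)
  structure(list(max_resolution = max_resolution,
                 max_ion_distance = max_ion_distance,
                 identity_threshold = identity_threshold,
                 flank_cutoff = flank_cutoff,
                 phosphate_codes = phosphate_codes),
            class = "survey_criteria")
}

# side-chain functional atoms considered when measuring flanking distances
FLANK_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"),
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"))

#' Detect co-bound Ca2+/phosphate sites in a structure
#'
#' For every Ca2+ HETATM entity and every phosphate-bearing HETATM entity the
#' minimum over atom pairs of the Ca-to-phosphate (non-hydrogen) distance is
#' computed; a site is emitted when it does not exceed
#' `criteria$max_ion_distance`. Each site carries the flanking residues whose
#' side-chain functional atoms lie within `criteria$flank_cutoff` of either
#' ion, sorted by closest approach.
#'
#' @param s a [structure_model].
#' @param criteria a [survey_criteria].
#' @return list of `co_bound_site` objects (possibly empty), each with
#'   `ca_atom` (row of the atom table), `phosphate_resno`, `min_ion_distance`
#'   and `flanking` (data.frame resid/resno/distance).
#' @export
find_co_bound_sites <- function(s, criteria = survey_criteria()) {
  at <- s$atoms
  ca_idx <- which(at$type == "HETATM" & at$resid == "CA" & at$elesy == "CA")
  ph_res <- unique(at[at$type == "HETATM" &
                        at$resid %in% criteria$phosphate_codes,
                      c("chain", "resno")])
  sites <- list()
  if (!length(ca_idx) || !nrow(ph_res)) return(sites)
  for (i in ca_idx) {
    p_ca <- c(at$x[i], at$y[i], at$z[i])
    for (r in seq_len(nrow(ph_res))) {
      pa <- at[at$chain == ph_res$chain[r] & at$resno == ph_res$resno[r] &
                 at$elesy != "H", , drop = FALSE]
      dmin <- min(dist_to(p_ca, as.matrix(pa[, c("x", "y", "z")])))
      if (dmin <= criteria$max_ion_distance) {
        flank <- flanking_residues(s, rbind(p_ca,
                                            as.matrix(pa[, c("x", "y", "z")])),
                                   criteria$flank_cutoff)
        sites[[length(sites) + 1L]] <- structure(
          list(ca_atom = at[i, ], phosphate_resno = ph_res$resno[r],
               min_ion_distance = dmin, flanking = flank),
          class = "co_bound_site")
      }
    }
  }
  sites
}

flanking_residues <- function(s, ion_xyz, cutoff) {
  at <- s$atoms
  prot <- at[at$type == "ATOM", , drop = FALSE]
  out <- list()
  for (key in unique(paste(prot$chain, prot$resno))) {
    d <- prot[paste(prot$chain, prot$resno) == key, , drop = FALSE]
    fa <- FLANK_ATOMS[[d$resid[1]]]
    if (is.null(fa)) next
    d <- d[trimws(d$elety) %in% fa, , drop = FALSE]
    if (!nrow(d)) next
    dd <- min(apply(as.matrix(d[, c("x", "y", "z")]), 1,
                    function(p) min(dist_to(p, ion_xyz))))
    if (dd <= cutoff)
      out[[length(out) + 1L]] <- data.frame(
        resid = d$resid[1], resno = d$resno[1], chain = d$chain[1],
        distance = dd, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(resid = character(0), resno = integer(0),
                      chain = character(0), distance = numeric(0)))
  out <- do.call(rbind, out)
  out[order(out$distance), , drop = FALSE]
}

#' Check the two-acidic-plus-histidine flanking motif
#'
#' @param site a `co_bound_site`.
#' @param criteria a [survey_criteria] (the flanking list was already built at
#'   its cutoff; the motif itself is composition-only).
#' @return TRUE iff the flanking residues include at least two of Asp/Glu and
#'   at least one His.
#' @export
motif_check <- function(site, criteria = survey_criteria()) {
  fl <- site$flanking$resid
  sum(fl %in% c("ASP", "GLU")) >= 2 && sum(fl == "HIS") >= 1
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap opening -5,
#' gap extension -1, via Biostrings) followed by an identity computed as the
#' number of identical aligned positions divided by the alignment length
#' after excluding terminal-gap columns. Symmetric by construction of the
#' scoring scheme.
#'
#' @param seq_a,seq_b amino-acid sequences (one-letter, non-empty).
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s))
      stop("non-amino-acid characters in sequence")
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  mat <- matrix(0, length(aa), length(aa), dimnames = list(aa, aa))
  diag(mat) <- 1
  al <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 1)
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- a == "-" | b == "-"
  # exclude terminal gap columns from the denominator
  core <- which(!gap)
  span <- seq(min(core), max(core))
  sum(a[span] == b[span] & !gap[span]) / length(span)
}

#' Run the four-criterion structure survey over a set of files
#'
#' Files are parsed, ordered deterministically (ascending resolution, then
#' lexicographic source id; files without a resolution record sort last), and
#' filtered in order: resolution, co-bound-site detection, flanking motif,
#' greedy sequence-redundancy against already-accepted hits. Every rejection
#' is annotated with the first failing criterion; parse failures are reported,
#' not fatal.
#'
#' @param files paths to PDB/mmCIF files.
#' @param criteria a [survey_criteria].
#' @return object of class `survey_report`: data.frame `report` (file, status,
#'   reason, resolution, min_ion_distance) plus `hits` (named list of accepted
#'   structures' sites).
#' @export
run_survey <- function(files, criteria = survey_criteria()) {
  stopifnot(length(files) >= 1)
  parsed <- list(); notes <- list()
  for (f in files) {
    s <- tryCatch(parse_structure(f), error = function(e) e)
    if (inherits(s, "error")) {
      notes[[basename(f)]] <- conditionMessage(s)
    } else parsed[[basename(f)]] <- s
  }
  res_order <- order(vapply(parsed, function(s)
    if (is.na(s$resolution)) Inf else s$resolution, numeric(1)),
    names(parsed))
  parsed <- parsed[res_order]

  rows <- list(); hits <- list(); hit_seqs <- list()
  for (nm in names(parsed)) {
    s <- parsed[[nm]]
    row <- data.frame(file = nm, status = "accepted", reason = "",
                      resolution = s$resolution,
                      min_ion_distance = NA_real_, stringsAsFactors = FALSE)
    if (is.na(s$resolution) || s$resolution > criteria$max_resolution) {
      row$status <- "rejected"; row$reason <- "resolution"
      rows[[nm]] <- row; next
    }
    sites <- find_co_bound_sites(s, criteria)
    if (!length(sites)) {
      row$status <- "rejected"; row$reason <- "ion_distance"
      rows[[nm]] <- row; next
    }
    row$min_ion_distance <- min(vapply(sites, function(x) x$min_ion_distance,
                                       numeric(1)))
    ok_motif <- vapply(sites, motif_check, logical(1), criteria = criteria)
    if (!any(ok_motif)) {
      row$status <- "rejected"; row$reason <- "motif"
      rows[[nm]] <- row; next
    }
    seqs <- chain_sequences(s)
    redundant <- FALSE
    for (prev in hit_seqs) {
      ids <- outer(seqs, prev, Vectorize(pairwise_identity))
      if (length(ids) && max(ids) >= criteria$identity_threshold) {
        redundant <- TRUE; break
      }
    }
    if (redundant) {
      row$status <- "rejected"; row$reason <- "redundancy"
      rows[[nm]] <- row; next
    }
    hits[[nm]] <- sites[ok_motif]
    hit_seqs[[nm]] <- seqs
    rows[[nm]] <- row
  }
  for (nm in names(notes))
    rows[[nm]] <- data.frame(file = nm, status = "error", reason = notes[[nm]],
                             resolution = NA_real_,
                             min_ion_distance = NA_real_,
                             stringsAsFactors = FALSE)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, hits = hits, criteria = criteria),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("survey_report:", nrow(x$report), "files,",
      length(x$hits), "accepted\n")
  print(x$report[, c("file", "status", "reason")], row.names = FALSE)
  invisible(x)
}

#' Write a survey report as TSV
#'
#' @param report a `survey_report`.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_survey_report <- function(report, file) {
  utils::write.table(report$report, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
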