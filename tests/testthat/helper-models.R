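# Shared fixtures built in code. The scaffold/restraints/ensemble are cached
# per test run because sampling is the slow step.

scaffold_cache <- new.env(parent = emptyenv())

cached_scaffold <- function() {
  if (is.null(scaffold_cache$s)) scaffold_cache$s <- build_scaffold()
  scaffold_cache$s
}

cached_restraints <- function() {
  if (is.null(scaffold_cache$rs))
    scaffold_cache$rs <- build_default_restraints(cached_scaffold())
  scaffold_cache$rs
}

cached_ensemble <- function() {
  if (is.null(scaffold_cache$ens))
    scaffold_cache$ens <- sample_ensemble(cached_scaffold(),
                                          cached_restraints(),
                                          n_models = 10, seed = 42)
  scaffold_cache$ens
}

# rigid copy of a structure/site model, translated by `dx`
translate_model <- function(m, dx) {
  s <- if (inherits(m, "site_model")) m$structure else m
  s$atoms$x <- s$atoms$x + dx[1]
  s$atoms$y <- s$atoms$y + dx[2]
  s$atoms$z <- s$atoms$z + dx[3]
  s
}

# independent brute-force oracle: minimum distance between a Ca HETATM and
# any non-H atom of phosphate-coded HETATM residues, over all atom pairs
brute_force_min_ion_distance <- function(s, codes = c("PO4", "2HP", "PI",
                                                      "H2P")) {
  at <- s$atoms
  ca <- at[at$type == "HETATM" & at$resid == "CA" & at$elesy == "CA", ]
  ph <- at[at$type == "HETATM" & at$resid %in% codes & at$elesy != "H", ]
  if (!nrow(ca) || !nrow(ph)) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(ca)))
    for (j in seq_len(nrow(ph)))
      best <- min(best, sqrt((ca$x[i] - ph$x[j])^2 + (ca$y[i] - ph$y[j])^2 +
                               (ca$z[i] - ph$z[j])^2))
  best
}
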