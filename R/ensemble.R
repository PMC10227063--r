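#' Atom selection for ensemble RMSD
#'
#' Default selection mirrors the clustering protocol: all non-hydrogen atoms
#' of the eight side-chain residues N69, E72, N99, N252, E255, H256, S278,
#' Q281 plus the Ca2+ and phosphate ions. Models share a frozen backbone
#' frame, so RMSD is computed without superposition.
#'
#' @param residues residue numbers to include (protein part).
#' @param include_ions include the Ca2+ and phosphate entities.
#' @return object of class `rmsd_selection`.
#' @export
rmsd_selection <- function(residues = c(69L, 72L, 99L, 252L, 255L, 256L,
                                        278L, 281L),
                           include_ions = TRUE) {
  if (!length(residues) && !include_ions) stop("empty selection")
  structure(list(residues = as.integer(residues),
                 include_ions = include_ions), class = "rmsd_selection")
}

selection_index <- function(s, sel) {
  at <- s$atoms
  keep <- at$resno %in% sel$residues & at$elesy != "H"
  if (sel$include_ions) keep <- keep | at$resno %in% c(501L, 502L)
  which(keep)
}

model_xyz <- function(m, idx) {
  s <- if (inherits(m, "site_model")) m$structure else m
  as.matrix(s$atoms[idx, c("x", "y", "z")])
}

#' Pairwise RMSD between two site models (no superposition)
#'
#' @param a,b `site_model` or [structure_model] objects sharing the scaffold
#'   atom ordering.
#' @param sel an [rmsd_selection].
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(a, b, sel = rmsd_selection()) {
  sa <- if (inherits(a, "site_model")) a$structure else a
  sb <- if (inherits(b, "site_model")) b$structure else b
  ia <- selection_index(sa, sel); ib <- selection_index(sb, sel)
  if (!identical(ia, ib) ||
      !identical(paste(sa$atoms$resno[ia], sa$atoms$elety[ia]),
                 paste(sb$atoms$resno[ib], sb$atoms$elety[ib])))
    stop("selection mismatch between models")
  d <- model_xyz(a, ia) - model_xyz(b, ib)
  sqrt(mean(rowSums(d^2)))
}

#' Leader clustering of a model ensemble by pairwise RMSD
#'
#' Models are visited in index order; a model joins the first existing cluster
#' whose representative (founding model) is within `threshold`, otherwise it
#' founds a new cluster. Deterministic for a fixed model order.
#'
#' @param models list of `site_model`s.
#' @param sel an [rmsd_selection].
#' @param threshold RMSD threshold in Angstrom (default 0.6).
#' @return object of class `ensemble_clustering`: `n_models`, `threshold`,
#'   `assignments` (integer per model), `populations`, `representatives`
#'   (model indices).
#' @export
cluster_ensemble <- function(models, sel = rmsd_selection(), threshold = 0.6) {
  stopifnot(length(models) >= 1, threshold > 0)
  s1 <- if (inherits(models[[1]], "site_model")) models[[1]]$structure
        else models[[1]]
  idx <- selection_index(s1, sel)
  coords <- lapply(models, model_xyz, idx = idx)
  reps <- integer(0)
  assignments <- integer(length(models))
  for (i in seq_along(models)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      d <- coords[[i]] - coords[[reps[k]]]
      if (sqrt(mean(rowSums(d^2))) <= threshold) {
        assignments[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignments[i] <- length(reps)
    }
  }
  structure(list(n_models = length(models), threshold = threshold,
                 assignments = assignments,
                 populations = as.integer(table(factor(assignments,
                                                levels = seq_along(reps)))),
                 representatives = reps),
            class = "ensemble_clustering")
}

#' @export
print.ensemble_clustering <- function(x, ...) {
  cat("ensemble_clustering:", x$n_models, "models,",
      length(x$populations), "clusters at", x$threshold, "A\n")
  cat("  populations:", paste(sort(x$populations, decreasing = TRUE),
                              collapse = " "), "\n")
  invisible(x)
}

#' Cluster population summary
#'
#' @param clustering an `ensemble_clustering`.
#' @param min_size minimum cluster population to count (default 10, i.e.
#'   clusters "comprising more than `min_size` models" are those with
#'   population > min_size... the summary uses population >= min_size; set
#'   `min_size = 11` for a strict "more than 10" reading).
#' @return list with `n_clusters` (clusters of population >= min_size),
#'   `coverage` (fraction of models they hold), `top_fraction` (largest
#'   cluster's fraction).
#' @export
cluster_statistics <- function(clustering, min_size = 1L) {
  pop <- clustering$populations
  big <- pop[pop >= min_size]
  list(n_clusters = length(big),
       coverage = sum(big) / clustering$n_models,
       top_fraction = max(pop) / clustering$n_models)
}

#' Occupancy grid over an ensemble
#'
#' Voxel value = fraction of models with at least one selected atom within
#' `radius` of the voxel center, i.e. atoms stamp a spherical footprint of
#' that radius (the convention of standard volumetric-occupancy tools). With
#' `radius = 0` an atom occupies only the voxel containing its center. Grids
#' cover the bounding box of all selected atoms plus the footprint, anchored
#' so the selection centroid falls on a voxel center.
#'
#' @param models list of `site_model`s.
#' @param sel an [rmsd_selection] choosing which atoms are counted (e.g.
#'   `rmsd_selection(residues = integer(0), include_ions = TRUE)` restricted
#'   further via `resno`).
#' @param resno optional residue-number filter applied after `sel` (e.g. `501L`
#'   for the Ca2+ ion only).
#' @param spacing voxel edge length in Angstrom (default 0.5).
#' @param radius atom footprint radius in Angstrom (default 1.0, of the order
#'   of an ionic/united-atom radius).
#' @return object of class `occupancy_grid`: `origin`, `spacing`, `dim`,
#'   `values` (3D array of fractions in [0, 1]).
#' @export
occupancy_map <- function(models, sel = rmsd_selection(), resno = NULL,
                          spacing = 0.5, radius = 1.0) {
  stopifnot(length(models) >= 1, radius >= 0)
  if (spacing <= 0) stop("spacing must be positive")
  s1 <- if (inherits(models[[1]], "site_model")) models[[1]]$structure
        else models[[1]]
  idx <- selection_index(s1, sel)
  if (!is.null(resno)) idx <- idx[s1$atoms$resno[idx] %in% resno]
  if (!length(idx)) stop("selection resolves to no atoms")
  coords <- lapply(models, model_xyz, idx = idx)
  all_xyz <- do.call(rbind, coords)
  # anchor the grid on the selection centroid to avoid boundary artifacts
  ctr <- colMeans(all_xyz)
  lo <- apply(all_xyz, 2, min) - radius
  hi <- apply(all_xyz, 2, max) + radius
  origin <- ctr - spacing / 2 -
    spacing * ceiling((ctr - spacing / 2 - lo) / spacing + 1e-9)
  dim3 <- as.integer(pmax(1L, ceiling((hi - origin) / spacing + 1e-9)))
  counts <- array(0L, dim = dim3)
  halo <- as.integer(ceiling(radius / spacing))
  offs <- as.matrix(expand.grid(dx = -halo:halo, dy = -halo:halo,
                                dz = -halo:halo))
  for (xyz in coords) {
    vox <- floor(sweep(xyz, 2, origin) / spacing) + 1L
    if (radius > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(vox)), function(a) {
        v <- sweep(offs, 2, vox[a, ], `+`)
        cc <- sweep((v - 0.5) * spacing, 2, origin, `+`)
        keep <- sqrt(rowSums(sweep(cc, 2, xyz[a, ])^2)) <= radius
        v[keep, , drop = FALSE]
      }))
    } else cand <- vox
    ok <- cand[, 1] >= 1 & cand[, 2] >= 1 & cand[, 3] >= 1 &
      cand[, 1] <= dim3[1] & cand[, 2] <= dim3[2] & cand[, 3] <= dim3[3]
    cand <- cand[ok, , drop = FALSE]
    lin <- unique((cand[, 3] - 1L) * dim3[1] * dim3[2] +
                    (cand[, 2] - 1L) * dim3[1] + cand[, 1])
    counts[lin] <- counts[lin] + 1L
  }
  structure(list(origin = origin, spacing = spacing, dim = dim3,
                 radius = radius, values = counts / length(models)),
            class = "occupancy_grid")
}

#' Occupancy contour mask
#'
#' @param grid an `occupancy_grid`.
#' @param level contour level (default 0.85); voxels with value >= level are
#'   inside the contour.
#' @return list with `mask` (logical 3D array) and `centers` (matrix of voxel
#'   centers, in Angstrom, of the voxels inside the contour).
#' @export
occupancy_contour <- function(grid, level = 0.85) {
  mask <- grid$values >= level
  ijk <- which(mask, arr.ind = TRUE)
  centers <- if (nrow(ijk)) {
    sweep((ijk - 0.5) * grid$spacing, 2, grid$origin, `+`)
  } else matrix(numeric(0), ncol = 3)
  colnames(centers) <- c("x", "y", "z")
  list(mask = mask, centers = centers)
}

#' Write an occupancy grid in OpenDX scalar-field format
#'
#' @param grid an `occupancy_grid`.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
write_dx <- function(grid, file) {
  d <- grid$dim
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX expects z-fastest ordering
  flat <- numeric(prod(d))
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    flat[n + seq_len(d[3])] <- grid$values[i, j, ]
    n <- n + d[3]
  }
  idx <- seq(1, length(flat), by = 3)
  lines <- vapply(idx, function(i)
    paste(sprintf("%.6f", flat[i:min(i + 2, length(flat))]), collapse = " "),
    character(1))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(file)
}
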