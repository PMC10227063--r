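test_that("pairwise RMSD matches the direct formula and its invariances", {
  ens <- cached_ensemble()
  sel <- rmsd_selection()
  expect_equal(pairwise_rmsd(ens[[1]], ens[[1]], sel), 0)
  # uniform +1 A shift in x of every atom -> RMSD exactly 1
  shifted <- translate_model(ens[[1]], c(1, 0, 0))
  expect_equal(pairwise_rmsd(ens[[1]], shifted, sel), 1, tolerance = 1e-12)
  # direct formula evaluation on two sampled models
  a <- ens[[1]]$structure$atoms; b <- ens[[2]]$structure$atoms
  keep <- a$resno %in% c(69, 72, 99, 252, 255, 256, 278, 281, 501, 502)
  d2 <- (a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2
  expect_equal(pairwise_rmsd(ens[[1]], ens[[2]], sel),
               sqrt(mean(d2[keep])), tolerance = 1e-10)
  expect_equal(pairwise_rmsd(ens[[1]], ens[[2]], sel),
               pairwise_rmsd(ens[[2]], ens[[1]], sel))
})

test_that("leader clustering honors threshold, populations and membership", {
  ens <- cached_ensemble()
  s <- ens[[1]]
  # three identical models -> one cluster of population 3
  cl <- cluster_ensemble(list(s, s, s), threshold = 0.6)
  expect_equal(length(cl$populations), 1)
  expect_equal(cl$populations, 3L)
  # two tight groups 5 A apart -> two clusters with the right populations
  far <- translate_model(s, c(5, 0, 0))
  grp <- list(s, s, far, s, far)
  cl2 <- cluster_ensemble(grp, threshold = 0.6)
  expect_equal(sort(cl2$populations), c(2L, 3L))
  expect_equal(sum(cl2$populations), 5)
  # every member within threshold of its representative
  for (i in seq_along(grp)) {
    rep_i <- cl2$representatives[cl2$assignments[i]]
    expect_lte(pairwise_rmsd(grp[[i]], grp[[rep_i]]), 0.6)
  }
  # infinite threshold -> single cluster
  expect_equal(length(cluster_ensemble(grp, threshold = Inf)$populations), 1)
  # determinism on the sampled ensemble
  expect_identical(cluster_ensemble(ens), cluster_ensemble(ens))
})

test_that("cluster statistics summarize populations correctly", {
  fake <- structure(list(n_models = 100L, threshold = 0.6,
                         assignments = rep(1:3, c(60, 30, 10)),
                         populations = c(60L, 30L, 10L),
                         representatives = c(1L, 61L, 91L)),
                    class = "ensemble_clustering")
  st <- cluster_statistics(fake, min_size = 11)
  expect_equal(st$n_clusters, 2)
  expect_equal(st$coverage, 0.9)
  expect_equal(st$top_fraction, 0.6)
  # coverage non-increasing in min_size
  cov <- vapply(c(1, 11, 31, 61, 101), function(ms)
    cluster_statistics(fake, ms)$coverage, numeric(1))
  expect_true(all(diff(cov) <= 0))
  one <- structure(list(n_models = 100L, threshold = 0.6,
                        assignments = rep(1L, 100), populations = 100L,
                        representatives = 1L), class = "ensemble_clustering")
  expect_equal(cluster_statistics(one)$top_fraction, 1.0)
})

test_that("occupancy maps count voxel membership per model", {
  s <- cached_ensemble()[[1]]
  # identical ensemble: occupied voxels at 1, everything else 0
  g <- occupancy_map(list(s, s, s), spacing = 0.5)
  expect_true(all(g$values %in% c(0, 1)))
  expect_true(any(g$values == 1))
  # Ca split between two voxels (point footprint): both at 0.5, and the
  # 85% contour is empty
  far <- translate_model(s, c(4, 0, 0))
  g2 <- occupancy_map(list(s, far), resno = 501L, spacing = 0.5, radius = 0)
  expect_setequal(unique(as.vector(g2$values)), c(0, 0.5))
  expect_equal(sum(g2$values == 0.5), 2)
  expect_equal(nrow(occupancy_contour(g2, 0.85)$centers), 0)
  # finite footprint: a lone atom covers every voxel center within radius
  g3 <- occupancy_map(list(s), resno = 501L, spacing = 0.5, radius = 1.0)
  expect_gt(sum(g3$values == 1), 1)
  expect_error(occupancy_map(list(s), spacing = 0), "positive")
})

test_that("the Ca 85% contour of a default ensemble sits at the restraint-ideal position", {
  ens <- cached_ensemble()
  g <- occupancy_map(ens, resno = 501L, spacing = 0.5)
  ct <- occupancy_contour(g, 0.85)
  expect_gt(nrow(ct$centers), 0)
  # scaffold seats Ca at the origin; the tight ensemble stays within 1 A
  d <- sqrt(rowSums(ct$centers^2))
  expect_true(all(d <= 1.0))
})

test_that("occupancy grids serialize to OpenDX", {
  g <- occupancy_map(cached_ensemble()[1:2], resno = 501L, spacing = 0.5)
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  ln <- readLines(f)
  expect_true(grepl("gridpositions", ln[1]))
  items <- as.integer(sub(".*items (\\d+) data.*", "\\1",
                          grep("items", ln, value = TRUE)))
  expect_equal(items, prod(g$dim))
})
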