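# Generators: determinism, degenerate limits, planted ground truth.

test_that("every generator is deterministic under a fixed seed", {
  expect_identical(simulate_brownian(5, 20, seed = 3),
                   simulate_brownian(5, 20, seed = 3))
  expect_identical(simulate_prw(5, 20, persistence_time = 0.5, seed = 3),
                   simulate_prw(5, 20, persistence_time = 0.5, seed = 3))
  w1 <- simulate_wound(width_px = 60, height_px = 40, initial_gap = 40,
                       pixel_size = 1, n_frames = 5, seed = 3)
  w2 <- simulate_wound(width_px = 60, height_px = 40, initial_gap = 40,
                       pixel_size = 1, n_frames = 5, seed = 3)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  prop <- matrix(10, 2, 36, dimnames = list(c("a", "b"), NULL))
  expect_identical(simulate_ecm_array(prop, 4, seed = 3),
                   simulate_ecm_array(prop, 4, seed = 3))
  expect_identical(simulate_counts(50, 3, seed = 3),
                   simulate_counts(50, 3, seed = 3))
})

test_that("zero-diffusion Brownian tracks are stationary", {
  trk <- simulate_brownian(4, 10, diffusion = 0, seed = 1)
  expect_true(all(trk$x_um == 0) && all(trk$y_um == 0))
})

test_that("trajectory generators reject invalid parameters", {
  expect_error(simulate_brownian(3, 10, diffusion = -1), "diffusion")
  expect_error(simulate_brownian(3, 1), "n_frames")
  expect_error(simulate_prw(3, 10, bias_strength = 1.2), "bias_strength")
  expect_error(simulate_prw(3, 10, persistence_time = -1), "persistence_time")
})

test_that("Brownian ensemble MSD recovers the planted diffusion coefficient", {
  trk <- simulate_brownian(300, 145, 1 / 6, diffusion = 1, seed = 8)
  fit <- estimate_diffusion(ensemble_msd(lapply(split_tracks(trk), compute_msd)))
  expect_gt(fit$slope / 4, 0.9)
  expect_lt(fit$slope / 4, 1.1)
})

test_that("fully biased persistent walk is perfectly straight", {
  trk <- simulate_prw(6, 30, speed = 20, persistence_time = Inf,
                      bias_strength = 1, bias_direction = pi / 4, seed = 2)
  st <- vapply(split_tracks(trk), straightness, numeric(1))
  expect_equal(unname(st), rep(1, 6), tolerance = 1e-12)
})

test_that("uncorrelated unbiased walk has diffusive long-lag MSD scaling", {
  trk <- simulate_prw(300, 145, speed = 20, persistence_time = 0,
                      bias_strength = 0, seed = 5)
  ens <- ensemble_msd(lapply(split_tracks(trk), compute_msd))
  long <- ens[ens$lag_h > 2, ]
  expo <- coef(lm(log(msd_um2) ~ log(lag_h), data = long))[[2]]
  expect_equal(expo, 1, tolerance = 0.1)
})

test_that("wound simulator: flat fronts follow the deterministic update rule", {
  v <- 12; dt <- 1 / 6
  sim <- simulate_wound(width_px = 100, height_px = 30, initial_gap = 80,
                        front_speed = v, roughness_variance = 0,
                        pixel_size = 1, n_frames = 10, frame_interval = dt,
                        seed = 1)
  gap_width <- sim$truth$right_um - sim$truth$left_um
  # per-column gap narrows by exactly 2 v dt per frame until contact
  expect_equal(unique(round(diff(gap_width[1, ]), 10)), -2 * v * dt)
  # frame 0 edge is the straight barrier edge
  expect_equal(var(sim$truth$left_um[, 1]), 0)
  expect_equal(as.numeric(wound_regularity(sim$stack, at_time = 1)), 0)
})

test_that("wound simulator: masks are binary with non-increasing gap area", {
  sim <- simulate_wound(width_px = 120, height_px = 80, initial_gap = 100,
                        front_speed = 15, roughness_variance = 4,
                        pixel_size = 1, n_frames = 20, seed = 9)
  expect_true(all(sim$stack$frames %in% c(TRUE, FALSE)))
  expect_true(all(diff(sim$truth$gap_area_um2) <= 0))
  # emitted truth areas match the masks themselves
  areas <- vapply(seq_len(20), function(i)
    gap_area(sim$stack$frames[, , i], 1), numeric(1))
  expect_equal(areas, sim$truth$gap_area_um2)
})

test_that("wound simulator rejects a gap that closes before frame 1", {
  expect_error(simulate_wound(width_px = 100, initial_gap = 5, front_speed = 100,
                              pixel_size = 1, frame_interval = 1, n_frames = 3),
               "close")
})

test_that("default ECM panel: 36 distinct labels over the nine proteins", {
  panel <- ecm_panel_default()
  expect_length(panel, 36L)
  expect_length(unique(panel), 36L)
  comps <- ecm_panel_components(panel)
  expect_true(all(unlist(comps) %in% ecm_proteins()))
  # no composition repeats a protein or duplicates another as a set
  expect_true(all(vapply(comps, anyDuplicated, 1L) == 0L))
  sets <- vapply(comps, function(x) paste(sort(x), collapse = "|"), "")
  expect_length(unique(sets), 36L)
})

test_that("ECM simulator: zero propensity gives zero counts, Poisson means recover", {
  prop0 <- matrix(0, 2, 36, dimnames = list(c("a", "b"), NULL))
  x0 <- simulate_ecm_array(prop0, 5, seed = 1)
  expect_true(all(x0$count == 0))
  expect_error(simulate_ecm_array(prop0 - 1, 5), "propensit")

  prop <- matrix(rep(c(20, 80), each = 36), 2, 36, byrow = TRUE,
                 dimnames = list(c("lo", "hi"), NULL))
  x <- simulate_ecm_array(prop, n_replicates = 50, seed = 2)
  m <- profile_means(x)
  z <- abs(m - prop) / sqrt(prop / 50)
  # per-cell z-scores: the bulk within 3 SE, none an outright outlier
  expect_gte(mean(z < 3), 0.95)
  expect_true(all(z < 4.5))
})

test_that("planted similarity: identical propensity rows give near-zero distance", {
  set.seed(10)
  base <- runif(36, 10, 200)
  prop <- rbind(ref = base, twin = base)
  x <- simulate_ecm_array(prop, n_replicates = 40, seed = 10)
  s <- pearson_similarity(profile_means(x))
  expect_lt(s$distance["ref", "twin"], 0.02)
})

test_that("counts simulator: planted truth round-trips and errors are raised", {
  planted <- data.frame(gene = c(3L, 7L, 20L), fc = c(4, -4, 2))
  sim <- simulate_counts(50, 3, planted = planted, seed = 6)
  expect_equal(nrow(sim$truth), 3L)
  expect_equal(sort(sim$truth$gene_id), sort(sprintf("gene%04d", planted$gene)))
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  expect_equal(sim$truth$direction, c("up", "down", "up"))
  expect_error(simulate_counts(50, 3, dispersion = 0), "dispersion")
  expect_error(simulate_counts(50, 3, planted = data.frame(gene = 1, fc = 0.5)),
               "fc")
})

test_that("egg chamber: cluster lands at the configured fractional position", {
  for (f in c(0, 0.5, 1)) {
    sim <- simulate_egg_chamber(anterior_pos = 10, oocyte_pos = 110,
                                cluster_fraction = f,
                                cluster_axes = c(6, 5, 4), voxel_size = 0.5)
    expect_equal(migration_index(sim$model), 100 * f, tolerance = 1e-6)
    ctr <- centroid_position(sim$volume)
    expect_equal(ctr[[1]], sim$model$cluster_centroid, tolerance = 0.3)
  }
  expect_error(simulate_egg_chamber(cluster_fraction = 1.5), "cluster_fraction")
  expect_error(simulate_egg_chamber(dims = c(10, 10, 10), cluster_axes = c(20, 20, 20)),
               "contained")
})

test_that("spherical simulated cluster has sphericity near 1", {
  sim <- simulate_egg_chamber(cluster_fraction = 0.5, cluster_axes = c(7, 7, 7),
                              voxel_size = 0.5)
  cm <- cluster_metrics(sim$volume)
  expect_equal(cm$sphericity, 1, tolerance = 0.02)
})
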