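test_that("sim_config validates geometry and resolves density to a count", {
  cfg <- sim_config(radius_nm = 1250, density_per_um2 = 6.4)
  expect_equal(cfg$n_npcs, round(6.4 * 4 * pi * 1.25^2))
  expect_error(sim_config(radius_nm = 1250), "exactly one")
  expect_error(sim_config(radius_nm = 1250, n_npcs = 10, density_per_um2 = 5),
               "exactly one")
  expect_error(sim_config(radius_nm = -1, n_npcs = 10))
  expect_error(sim_config(radius_nm = 200, n_npcs = 5000, min_spacing_nm = 100),
               "packing infeasible")
})

test_that("points land on the sphere with the minimum spacing enforced", {
  cfg1 <- sim_config(radius_nm = 1250, n_npcs = 1, seed = 11)
  t1 <- sample_points_on_sphere(cfg1)
  expect_equal(sqrt(sum(t1$positions[1, ]^2)), 1250, tolerance = 1e-9)

  cfg <- sim_config(radius_nm = 1250, n_npcs = 125, min_spacing_nm = 100,
                    seed = 12)
  tr <- sample_points_on_sphere(cfg)
  expect_equal(nrow(tr$positions), 125)
  radii <- sqrt(rowSums(tr$positions^2))
  expect_true(all(abs(radii - 1250) < 1e-6))
  d <- as.matrix(stats::dist(tr$positions))  # exhaustive pairwise check
  expect_true(all(d[upper.tri(d)] >= 100))
  # implied true density of the standard mid-G2 configuration
  expect_equal(125 / (4 * pi * 1.25^2), 6.4, tolerance = 0.01)
})

test_that("infeasible packings fail loudly, naming the achieved count", {
  # constructor rejects physically impossible coverage outright
  expect_error(sim_config(radius_nm = 300, n_npcs = 220, min_spacing_nm = 100),
               "packing infeasible")
  # a tight-but-legal packing fails when the attempt budget runs out
  cfg <- sim_config(radius_nm = 300, n_npcs = 55, min_spacing_nm = 100,
                    seed = 1)
  expect_error(sample_points_on_sphere(cfg, max_attempts = 3),
               "packing failed: placed")
})

test_that("sphere sampling is uniform (z-coordinate KS test) and seeded", {
  cfg <- sim_config(radius_nm = 1000, n_npcs = 1e4, min_spacing_nm = 0,
                    seed = 99)
  tr <- sample_points_on_sphere(cfg)
  ks <- stats::ks.test(tr$positions[, 3] / 1000, "punif", -1, 1)
  expect_gt(ks$p.value, 0.01)
  tr2 <- sample_points_on_sphere(cfg)
  expect_identical(tr$positions, tr2$positions)
})

test_that("rendering: empty truth, centred peak, fitted lateral FWHM", {
  cfg <- sim_config(radius_nm = 600, n_npcs = 0, seed = 1)
  empty <- structure(list(positions = matrix(numeric(0), 0, 3),
                          intensities = numeric(0),
                          sphere_center = c(0, 0, 0), radius_nm = 600),
                     class = "foci_truth")
  vol0 <- render_volume(empty, cfg)
  expect_true(all(vol0$voxels == 0))

  # one emitter placed exactly on a voxel centre: that voxel reads the peak
  d <- dim(vol0$voxels)
  ctr <- volume_center_nm(vol0)
  pos_vox <- c((round(ctr["x"] / 40 + 0.5) - 0.5) * 40,
               (round(ctr["y"] / 40 + 0.5) - 0.5) * 40,
               (round(ctr["z"] / 125 + 0.5) - 0.5) * 125)
  one <- empty
  one$positions <- matrix(pos_vox - ctr, 1)
  one$intensities <- 100
  vol1 <- render_volume(one, cfg)
  expect_equal(max(vol1$voxels), 100, tolerance = 1e-9)
  iy <- round(pos_vox[2] / 40 + 0.5); ix <- round(pos_vox[1] / 40 + 0.5)
  iz <- round(pos_vox[3] / 125 + 0.5)
  expect_equal(vol1$voxels[iy, ix, iz], 100, tolerance = 1e-9)

  fit <- fit_focus_profile(vol1, pos_vox)
  expect_true(fit$converged)
  expect_equal(fit$fwhm_nm, 100, tolerance = 2 / 100)
})

test_that("rendered photon mass matches the analytic Gaussian integral", {
  cfg <- sim_config(radius_nm = 800, n_npcs = 40, seed = 4)
  tr <- sample_points_on_sphere(cfg)
  vol <- render_volume(tr, cfg)
  sxy <- 100 / 2.355; sz <- 300 / 2.355
  expected <- 40 * 100 * (2 * pi)^1.5 * sxy^2 * sz / (40^2 * 125)
  expect_equal(sum(vol$voxels), expected, tolerance = 0.01)
})

test_that("grid size cap triggers an explicit failure", {
  cfg <- sim_config(radius_nm = 1250, n_npcs = 1, seed = 1)
  tr <- sample_points_on_sphere(cfg)
  expect_error(render_volume(tr, cfg, max_voxels = 1000), "exceeds cap")
})

test_that("camera model: gain, read noise and Poisson sampling", {
  cfg0 <- sim_config(radius_nm = 600, n_npcs = 0, read_noise_sd = 0,
                     shot_noise = FALSE, seed = 1)
  zero <- volume_image(array(0, c(8, 8, 3)), 40, 125)
  out0 <- apply_camera(zero, cfg0)
  expect_true(all(out0$voxels == 0))

  const <- volume_image(array(100, c(10, 10, 10)), 40, 125)
  out <- apply_camera(const, cfg0)
  expect_true(all(out$voxels == 2000))

  cfg1 <- sim_config(radius_nm = 600, n_npcs = 0, read_noise_sd = 0,
                     shot_noise = TRUE, seed = 1)
  big <- volume_image(array(100, c(50, 50, 40)), 40, 125)  # 1e5 voxels
  outp <- apply_camera(big, cfg1, seed = 21)
  se <- 20 * sqrt(100) / sqrt(length(big$voxels))  # CLT: Var = gain^2 * lambda
  expect_lt(abs(mean(outp$voxels) - 2000), 3 * se)
  expect_error(apply_camera(volume_image(array(-1, c(2, 2, 2)), 40, 125), cfg1),
               "non-negative")
})

test_that("SPB channel: separation, edge margin and seeded determinism", {
  cfg <- sim_config(radius_nm = 1250, n_npcs = 10, seed = 31)
  tr <- sample_points_on_sphere(cfg)
  res <- add_spb_channel(tr, cfg, seed = 5, camera = FALSE)
  expect_equal(res$truth$separation_nm, 180, tolerance = 1e-9)
  for (p in list(res$truth$mother_nm, res$truth$daughter_nm)) {
    rho <- sqrt(sum(p[1:2]^2))  # projected distance from nucleus axis
    expect_gte(1250 - rho, 400)
  }
  res2 <- add_spb_channel(tr, cfg, seed = 5, camera = FALSE)
  expect_identical(res$truth, res2$truth)
  small <- sim_config(radius_nm = 450, n_npcs = 5, seed = 1)
  expect_error(place_spb_pair(small), "too small")
})

test_that("full simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(radius_nm = 800, n_npcs = 30, seed = 77)
  s1 <- simulate_nucleus(cfg)
  s2 <- simulate_nucleus(cfg)
  expect_identical(s1$volume$voxels, s2$volume$voxels)
  expect_identical(s1$truth$positions, s2$truth$positions)
})

test_that("condition grid manifest records exact truth", {
  g <- generate_condition_grid(c(600, 1800), c(1, 6.4), 3, seed = 2)
  expect_equal(nrow(g$manifest), 2 * 2 * 3)
  sa600 <- g$manifest$true_SA_um2[g$manifest$radius_nm == 600][1]
  sa1800 <- g$manifest$true_SA_um2[g$manifest$radius_nm == 1800][1]
  expect_equal(sa600, 4.52, tolerance = 0.005 / 4.52)
  expect_equal(sa1800, 40.7, tolerance = 0.05 / 40.7)
  # manifest truth density is exactly count / sphere area
  expect_equal(g$manifest$true_density,
               g$manifest$n_npcs / g$manifest$true_SA_um2)
  # deterministic seed derivation
  g2 <- generate_condition_grid(c(600, 1800), c(1, 6.4), 3, seed = 2)
  expect_identical(g$manifest, g2$manifest)
})

test_that("nucleolar scene construction matches its stated truth", {
  sc0 <- generate_nucleolar_scene(nup_reduction_frac = 0, seed = 3)
  expect_true(all(sc0$profiles$nup == 1))
  sc <- generate_nucleolar_scene(nup_reduction_frac = 0.2, noise_sd = 0,
                                 seed = 3)
  in_arc <- sc$profiles$marker > 0
  expect_true(any(in_arc) && !all(in_arc))
  expect_equal(unique(sc$profiles$nup[in_arc]), 0.8)
  expect_equal(unique(sc$profiles$nup[!in_arc]), 1)
  expect_error(generate_nucleolar_scene(nup_reduction_frac = 1.2))
})
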