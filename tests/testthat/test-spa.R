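spb_test_volume <- function(seed = 1, camera = TRUE, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(radius_nm = 1250, n_npcs = 125)
  set.seed(seed)
  cfg$seed <- NULL
  spb <- place_spb_pair(cfg)
  shell <- structure(list(positions = matrix(numeric(0), 0, 3),
                          intensities = numeric(0),
                          sphere_center = c(0, 0, 0),
                          radius_nm = cfg$radius_nm),
                     class = "foci_truth")
  out <- npcorg:::render_spb_channel(spb, shell, cfg, camera = camera)
  ctr <- volume_center_nm(out$volume)
  list(truth = spb, volume = out$volume,
       seeds = rbind(spb$mother_nm, spb$daughter_nm) + rep(ctr, each = 2),
       center = ctr)
}

test_that("two-Gaussian fit recovers a noiseless 180 nm pair", {
  tv <- spb_test_volume(seed = 2, camera = FALSE)
  pair <- fit_spb_pair(tv$volume, tv$seeds)
  expect_true(pair$converged)
  expect_equal(pair$separation_nm, 180, tolerance = 5 / 180)
  expect_lt(pair$ratio, 1)  # mother is the brighter spot
})

test_that("a single spot with duplicate seeds is flagged, not returned", {
  cfg <- sim_config(radius_nm = 1250, n_npcs = 0, read_noise_sd = 0,
                    shot_noise = FALSE)
  one <- structure(list(positions = matrix(c(0, 0, 1250), 1),
                        intensities = 400,
                        sphere_center = c(0, 0, 0), radius_nm = 1250),
                   class = "foci_truth")
  vol <- render_volume(one, cfg)
  ctr <- volume_center_nm(vol)
  seedpt <- c(0, 0, 1250) + ctr
  pair <- fit_spb_pair(vol, rbind(seedpt, seedpt))
  expect_false(isTRUE(pair$converged))
})

test_that("noisy replicate fits are unbiased for the true separation", {
  res <- run_spb_separation_recovery(n_rep = 12, seed = 5)
  expect_gte(res$n_converged, 10)
  expect_lt(abs(res$mean_separation_nm - 180), 3 * res$se_nm + 1e-9)
})

test_that("realignment: identity case, rotation, and rigid separation", {
  tv <- spb_test_volume(seed = 4, camera = FALSE)
  pair <- fit_spb_pair(tv$volume, tv$seeds)
  al <- realign(tv$volume, pair)
  # rigid motion preserves the pair separation in the transform record
  expect_equal(al$transform$separation_nm, pair$separation_nm)
  # refit in the aligned frame: axis along +x within 1 degree, mother on -x
  ctr <- volume_center_nm(al$volume)
  zmid <- mean(c(pair$mother_nm[3], pair$daughter_nm[3]))
  guess <- rbind(c(ctr[1] - 90, ctr[2], zmid), c(ctr[1] + 90, ctr[2], zmid))
  pair2 <- fit_spb_pair(al$volume, guess)
  expect_true(pair2$converged)
  ang <- atan2(pair2$daughter_nm[2] - pair2$mother_nm[2],
               pair2$daughter_nm[1] - pair2$mother_nm[1])
  expect_lt(abs(ang) * 180 / pi, 1)
  expect_lt(pair2$mother_nm[1], pair2$daughter_nm[1])
  expect_equal(pair2$separation_nm, pair$separation_nm, tolerance = 2 / 180)

  # a pair already on +x through the centre realigns to (near) identity
  d <- dim(tv$volume$voxels)
  cx <- volume_center_nm(tv$volume)
  idpair <- fake_pair(c(cx[1] - 90, cx[2], cx[3]), c(cx[1] + 90, cx[2], cx[3]))
  al2 <- realign(tv$volume, idpair)
  expect_equal(al2$volume$voxels, tv$volume$voxels, tolerance = 1e-9)
})

test_that("realignment and averaging commute with intensity scaling", {
  tv <- spb_test_volume(seed = 6, camera = FALSE)
  pair <- fit_spb_pair(tv$volume, tv$seeds)
  al1 <- realign(tv$volume, pair)
  scaled <- tv$volume; scaled$voxels <- scaled$voxels * 3.7
  al2 <- realign(scaled, pair)
  expect_equal(al2$volume$voxels, 3.7 * al1$volume$voxels, tolerance = 1e-12)
  am1 <- average_maps(list(al1), mirror = TRUE)
  am2 <- average_maps(list(al2), mirror = TRUE)
  expect_equal(am2$map, 3.7 * am1$map, tolerance = 1e-12)
})

test_that("map averaging: idempotence, mirror symmetry, failure on empty", {
  m <- matrix(stats::runif(64 * 64), 64, 64)
  am <- average_maps(list(m), mirror = FALSE, pixel_nm = 40)
  expect_equal(am$map, m)
  amm <- average_maps(list(m), mirror = TRUE, pixel_nm = 40)
  expect_identical(amm$map, amm$map[nrow(amm$map):1, ])  # m(x,y) = m(x,-y)
  expect_error(average_maps(list()), "no aligned")
  expect_error(average_maps(list(m, matrix(0, 3, 3)), pixel_nm = 40),
               "share dimensions")
  expect_equal(amm$display_threshold, 0.25 * max(amm$map))
  thr <- clip_for_display(amm)
  expect_true(all(thr[thr > 0] >= amm$display_threshold))
})

test_that("axis profile of a uniform map is flat at 1", {
  am <- average_maps(list(matrix(5, 60, 60)), mirror = TRUE, pixel_nm = 40)
  pr <- axis_profile(am, width_px = 12, half_length_nm = 300)
  expect_true(all(abs(pr$intensity - 1) < 1e-12))
  expect_true(all(diff(pr$position_nm) > 0))
  expect_error(axis_profile(average_maps(list(matrix(1, 6, 6)),
                                         mirror = FALSE, pixel_nm = 40),
                            width_px = 12), "band width")
})

test_that("exclusion calls: flat profiles pass, synthetic dips are sized", {
  flat <- structure(list(position_nm = seq(-300, 300, 40),
                         intensity = rep(1, 16), width_px = 12,
                         normalized = TRUE), class = "spa_profile")
  ex0 <- exclusion_fwhm(flat)
  expect_false(ex0$excluded)
  expect_null(ex0$fit)

  x <- seq(-580, 580, by = 20)
  dip <- 1 - 0.6 * exp(-x^2 / (2 * 85^2))
  prof <- structure(list(position_nm = x, intensity = dip, width_px = 12,
                         normalized = TRUE), class = "spa_profile")
  ex <- exclusion_fwhm(prof, fit_half_nm = 580)
  expect_true(ex$excluded)
  expect_true(ex$fit$converged)
  expect_equal(ex$fit$fwhm_nm, 2.355 * 85, tolerance = 1e-6)
  expect_identical(ex$fit$fwhm_nm / ex$fit$sd_nm, 2.355)
  expect_equal(ex$fit$center_nm, 0, tolerance = 1)
})

test_that("proximal/distal comparison: calibration, power and degeneracy", {
  pair <- fake_pair(c(-90, 0, 0), c(90, 0, 0))
  set.seed(101)
  # type-I error under identical intensity distributions
  rejections <- vapply(seq_len(200), function(i) {
    xyz <- rbind(matrix(stats::rnorm(20 * 3, sd = 40), 20, 3),       # proximal
                 sweep(matrix(stats::rnorm(40 * 3, sd = 200), 40, 3),
                       2, c(1500, 0, 0), `+`))                        # distal
    f <- make_foci(xyz, intensities = stats::rlnorm(60, 0, 0.3))
    proximal_distal(f, pair)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.03)

  # power: a 50% proximal reduction is detected at n = 30 per group
  xyz <- rbind(matrix(stats::rnorm(30 * 3, sd = 40), 30, 3),
               sweep(matrix(stats::rnorm(30 * 3, sd = 200), 30, 3),
                     2, c(1500, 0, 0), `+`))
  ints <- c(stats::rnorm(30, 0.5, 0.05), stats::rnorm(30, 1, 0.1))
  pd <- proximal_distal(make_foci(xyz, ints), pair)
  expect_lt(pd$p_value, 0.01)
  expect_lt(pd$mean_proximal, pd$mean_distal)

  # all foci distal: flagged, statistics missing
  far <- sweep(matrix(stats::rnorm(30, sd = 100), 10, 3), 2, c(3000, 0, 0), `+`)
  pd2 <- proximal_distal(make_foci(far), pair)
  expect_true(pd2$flagged)
  expect_true(is.na(pd2$p_value))
})

test_that("edge filter enforces the projected distance to the mask boundary", {
  m <- matrix(FALSE, 80, 80)
  ys <- (seq_len(80) - 0.5) * 40; xs <- ys
  disk <- outer(ys, xs, function(y, x) (x - 1600)^2 + (y - 1600)^2 <= 1250^2)
  mask <- npcorg:::new_nucleus_mask(disk, "auto")
  at_centre <- fake_pair(c(1600 - 90, 1600, 0), c(1600 + 90, 1600, 0))
  expect_true(edge_filter(at_centre, mask, 40))
  near_edge <- fake_pair(c(1600 + 950, 1600, 0), c(1600 + 950 + 180, 1600, 0))
  expect_false(edge_filter(near_edge, mask, 40))  # ~120-300 nm from boundary
  expect_true(edge_filter(near_edge, mask, 40, min_nm = 0))
  outside <- fake_pair(c(100, 100, 0), c(280, 100, 0))
  expect_false(edge_filter(outside, mask, 40))
})
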