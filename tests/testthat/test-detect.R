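test_that("segmentation: blank fields, single nuclei, separated nuclei", {
  blank <- matrix(0, 64, 64)
  expect_length(segment_nuclei(blank, 40), 0)

  cfg <- sim_config(radius_nm = 1250, n_npcs = 125, seed = 42)
  sim <- simulate_nucleus(cfg)
  masks <- segment_nuclei(max_project(sim$volume), cfg$pixel_nm)
  expect_length(masks, 1)
  r_eq <- sqrt(masks[[1]]$area_px / pi) * cfg$pixel_nm
  expect_lt(abs(r_eq - 1250) / 1250, 0.20)

  # two spheres 5 um apart rendered into one field
  cfg2 <- sim_config(radius_nm = 3300, n_npcs = 1, seed = 5)
  t1 <- sample_points_on_sphere(sim_config(radius_nm = 800, n_npcs = 60, seed = 6))
  t2 <- sample_points_on_sphere(sim_config(radius_nm = 800, n_npcs = 60, seed = 7))
  both <- structure(list(
    positions = rbind(sweep(t1$positions, 2, c(-2500, 0, 0), `-`),
                      sweep(t2$positions, 2, c(2500, 0, 0), `-`)),
    intensities = rep(100, 120), sphere_center = c(0, 0, 0),
    radius_nm = 3300), class = "foci_truth")
  vol2 <- apply_camera(render_volume(both, cfg2), cfg2, seed = 8)
  masks2 <- segment_nuclei(max_project(vol2), cfg2$pixel_nm)
  expect_length(masks2, 2)
})

test_that("ROI polygon edits add and remove masks", {
  cfg <- sim_config(radius_nm = 1000, n_npcs = 80, seed = 9)
  sim <- simulate_nucleus(cfg)
  proj <- max_project(sim$volume)
  auto <- segment_nuclei(proj, cfg$pixel_nm)
  expect_length(auto, 1)
  ctr <- auto[[1]]$centroid_px
  rm_poly <- list(cbind(x = ctr["x"] + c(-50, 50, 50, -50),
                        y = ctr["y"] + c(-50, -50, 50, 50)))
  expect_length(segment_nuclei(proj, cfg$pixel_nm, roi_remove = rm_poly), 0)
  add_poly <- list(cbind(x = c(2, 12, 12, 2), y = c(2, 2, 12, 12)))
  edited <- segment_nuclei(proj, cfg$pixel_nm, roi_add = add_poly)
  expect_length(edited, 2)
  expect_equal(edited[[2]]$provenance, "manual-added")
})

test_that("detection handles empty volumes and isolated emitters", {
  zero <- volume_image(array(0, c(20, 20, 9)), 40, 125)
  expect_equal(nrow(detect_foci(zero)$coordinates), 0)

  v <- array(0, c(21, 21, 9))
  v[11, 11, 5] <- 100
  vol <- volume_image(v, 40, 125)
  f <- detect_foci(vol)
  expect_equal(nrow(f$coordinates), 1)
  expect_equal(unname(unlist(f$coordinates[1, ])),
               c((11 - 0.5) * 40, (11 - 0.5) * 40, (5 - 0.5) * 125))
  expect_equal(f$intensities, 100)
})

test_that("spheroid masking merges close pairs and resolves separated ones", {
  render_pair <- function(sep_nm) {
    # offsets chosen so both emitters land exactly on voxel centres of the
    # 75 x 75 x 24 grid this configuration produces
    cfg <- sim_config(radius_nm = 600, n_npcs = 2, seed = 1)
    tr <- structure(list(positions = rbind(c(0, 0, -62.5),
                                           c(sep_nm, 0, -62.5)),
                         intensities = c(100, 100),
                         sphere_center = c(0, 0, 0), radius_nm = 600),
                    class = "foci_truth")
    render_volume(tr, cfg)
  }
  # 80 nm apart (2 px): the second peak and its shoulders all fall inside
  # the masking spheroid or below the 25% stop threshold -> merged
  expect_equal(nrow(detect_foci(render_pair(80))$coordinates), 1)
  # 120 nm apart (3 px): the peak voxel is masked but an above-threshold
  # shoulder survives just outside the ellipsoid -> still two detections
  expect_equal(nrow(detect_foci(render_pair(120))$coordinates), 2)
  # 200 nm apart (5 px): outside the lateral masking radius, detected
  expect_equal(nrow(detect_foci(render_pair(200))$coordinates), 2)
  # 400 nm apart: clearly resolved
  expect_equal(nrow(detect_foci(render_pair(400))$coordinates), 2)
})

test_that("detected count is non-increasing in threshold and mask size", {
  cfg <- sim_config(radius_nm = 1250, n_npcs = 125, seed = 33)
  sim <- simulate_nucleus(cfg)
  counts_thr <- vapply(c(0.15, 0.25, 0.4, 0.6), function(ft)
    nrow(detect_foci(sim$volume,
                     params = detection_params(frac_threshold = ft))$coordinates),
    numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_diam <- vapply(c(4, 8, 12), function(dp)
    nrow(detect_foci(sim$volume,
                     params = detection_params(mask_diameter_px = dp))$coordinates),
    numeric(1))
  expect_true(all(diff(counts_diam) <= 0))
})

test_that("focus profile fitting recovers width and flags flat input", {
  x <- seq(-320, 320, by = 40)
  y <- 5 + 90 * exp(-x^2 / (2 * 100^2))
  fit <- fit_gaussian_1d(x, y)
  expect_true(fit$converged)
  expect_equal(fit$sd_nm, 100, tolerance = 1e-6)
  expect_equal(fit$fwhm_nm, 235.5, tolerance = 1e-6)
  expect_identical(fit$fwhm_nm / fit$sd_nm, 2.355)

  flat <- volume_image(array(7, c(15, 15, 5)), 40, 125)
  f2 <- fit_focus_profile(flat, c(7.5 * 40, 7.5 * 40, 2.5 * 125))
  expect_false(f2$converged)
})

test_that("nucleus records: bookkeeping and the density scaling law", {
  pts <- sphere_points(60, 1000, seed = 5)
  foci <- make_foci(pts)
  h <- fit_hull(foci)
  rec <- summarize_nucleus(foci, h)
  expect_equal(rec$npc_count, 60)
  expect_equal(rec$density_per_um2, 60 / h$surface_area_um2)
  expect_equal(rec$npc_count, length(h$retained) + length(h$removed))
  rec_kept <- summarize_nucleus(foci, h, count_retained_only = TRUE)
  expect_equal(rec_kept$npc_count, length(h$retained))
  # doubling the radius: SA x4, density /4 at fixed count
  h2 <- fit_hull(make_foci(pts * 2), eps_nm = 40)
  rec2 <- summarize_nucleus(make_foci(pts * 2), h2)
  expect_equal(rec2$surface_area_um2 / rec$surface_area_um2, 4, tolerance = 1e-6)
  expect_equal(rec2$density_per_um2 / rec$density_per_um2, 0.25, tolerance = 1e-6)
})

test_that("co-detection fractions, threshold bracketing and oracle", {
  A <- sphere_points(10, 900, seed = 61)
  cd_self <- codetect(A, A, 250)
  expect_equal(cd_self$fraction_a, 1)
  expect_equal(cd_self$fraction_b, 1)

  one_a <- matrix(c(0, 0, 0), 1)
  expect_equal(codetect(one_a, matrix(c(240, 0, 0), 1), 250)$fraction_a, 1)
  expect_equal(codetect(one_a, matrix(c(260, 0, 0), 1), 250)$fraction_a, 0)

  # A subset of B, extra B points isolated
  B <- rbind(A, sweep(sphere_points(5, 900, seed = 62), 2, c(1e5, 0, 0), `+`))
  cd <- codetect(A, B, 250)
  expect_equal(cd$fraction_a, 1)
  expect_equal(cd$fraction_b, 10 / 15)

  # brute-force double-loop oracle on random sets
  set.seed(63)
  X <- matrix(stats::rnorm(30, sd = 400), 10, 3)
  Y <- matrix(stats::rnorm(45, sd = 400), 15, 3)
  cd2 <- codetect(X, Y, 250)
  frac_x <- mean(vapply(seq_len(10), function(i)
    any(sqrt(colSums((t(Y) - X[i, ])^2)) <= 250), logical(1)))
  frac_y <- mean(vapply(seq_len(15), function(j)
    any(sqrt(colSums((t(X) - Y[j, ])^2)) <= 250), logical(1)))
  expect_equal(cd2$fraction_a, frac_x)
  expect_equal(cd2$fraction_b, frac_y)

  # limiting radii
  expect_equal(codetect(X, Y, Inf)$fraction_a, 1)
  expect_equal(codetect(X, rbind(X[1, ], Y), 0)$fraction_a, 0.1)
  # empty channel: undefined, not zero
  expect_true(is.na(codetect(matrix(numeric(0), 0, 3), Y, 250)$fraction_a))
})

test_that("intensity per area: closed form and size independence", {
  m <- matrix(FALSE, 30, 30); m[10:20, 10:20] <- TRUE
  mask <- npcorg:::new_nucleus_mask(m, "auto")
  zero <- volume_image(array(0, c(30, 30, 4)), 40, 125)
  expect_equal(intensity_per_area(zero, mask, 10), 0)
  v <- array(0, c(30, 30, 4)); v[10:20, 10:20, 2] <- 3
  vol <- volume_image(v, 40, 125)
  expect_equal(intensity_per_area(vol, mask, 5, background = 0),
               3 * 121 / 5)
  expect_error(intensity_per_area(vol, mask, 0), "> 0")

  # equal true density at different radii gives equal intensity per area
  ipa <- vapply(c(1000, 1500), function(r) {
    cfg <- sim_config(radius_nm = r, density_per_um2 = 6.4, seed = r)
    sim <- simulate_nucleus(cfg)
    mk <- segment_nuclei(max_project(sim$volume), cfg$pixel_nm)[[1]]
    h <- fit_hull(detect_foci(sim$volume, mk))
    intensity_per_area(sim$volume, mk, h$surface_area_um2)
  }, numeric(1))
  expect_lt(abs(ipa[1] - ipa[2]) / ipa[2], 0.10)
})
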