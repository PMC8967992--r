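#' Default analysis parameters
#'
#' Collects every physically meaningful default of the pipeline in one
#' record so runs can echo their configuration verbatim into output
#' metadata.
#'
#' @param seed master seed.
#' @param pixel_nm,zstep_nm voxel calibration.
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 1, pixel_nm = 40, zstep_nm = 125) {
  structure(list(
    seed = seed, pixel_nm = pixel_nm, zstep_nm = zstep_nm,
    frac_threshold = 0.25, mask_diameter_px = 8, mask_slices = 5,
    max_removal_frac = 0.10, codetect_radius_nm = 250,
    min_edge_nm = 400, profile_width_px = 12,
    exclusion_threshold = 0.8, proximal_radius_nm = 100,
    fwhm_factor = fwhm_factor()),
    class = "run_config")
}

#' Quantify one nucleus: detection, hull, density
#'
#' @param volume a [volume_image()] (NPC channel).
#' @param mask optional `nucleus_mask`.
#' @param params a [detection_params()].
#' @param max_removal_frac hull outlier-removal cap.
#' @param raw_volume optional raw stack for [intensity_per_area()].
#' @return list: `foci`, `hull` (NULL if too few foci), `record` (one-row
#'   data.frame; NA geometry when the hull is undefined).
#' @export
quantify_nucleus <- function(volume, mask = NULL, params = detection_params(),
                             max_removal_frac = 0.10, raw_volume = NULL) {
  foci <- detect_foci(volume, mask, params)
  n <- nrow(foci$coordinates)
  if (n < 4) {
    rec <- data.frame(npc_count = n, surface_area_um2 = NA_real_,
                      volume_um3 = NA_real_, density_per_um2 = NA_real_,
                      intensity_per_area = NA_real_, stage = NA_character_)
    return(list(foci = foci, hull = NULL, record = rec))
  }
  hull <- fit_hull(foci, max_removal_frac = max_removal_frac)
  ipa <- NA_real_
  if (!is.null(raw_volume) && !is.null(mask))
    ipa <- intensity_per_area(raw_volume, mask, hull$surface_area_um2)
  rec <- summarize_nucleus(foci, hull, intensity_per_area = ipa)
  list(foci = foci, hull = hull, record = rec)
}

#' Segment a field and quantify every nucleus
#'
#' Max-projects the stack, segments nuclei, and runs detection + hull +
#' density per nucleus.
#'
#' @param volume a [volume_image()].
#' @param params a [detection_params()].
#' @param ... passed to [segment_nuclei()].
#' @return list: `masks`, `results` (per-nucleus list as from
#'   [quantify_nucleus()]), `records` (row-bound data.frame).
#' @export
quantify_field <- function(volume, params = detection_params(), ...) {
  masks <- segment_nuclei(max_project(volume), volume$pixel_nm, ...)
  results <- lapply(masks, function(m) quantify_nucleus(volume, m, params))
  records <- do.call(rbind, lapply(results, `[[`, "record"))
  list(masks = masks, results = results, records = records)
}

#' Density-recovery calibration against simulated ground truth
#'
#' Simulates nuclei over a grid of radii and true NPC densities, runs the
#' full measurement pipeline (segmentation of the max projection, spot
#' detection, hull fit, density), and compares measured with true values.
#' Reproduces the density-dependent undercounting of diffraction-limited
#' detection.
#'
#' @param radii_nm sphere radii.
#' @param densities_per_um2 true densities.
#' @param n_per_condition nuclei per condition.
#' @param seed master seed.
#' @param ... forwarded to [sim_config()].
#' @return list with `per_image` (one row per nucleus: truth, measured
#'   count/SA/density, percent errors) and `per_condition` (means per
#'   radius x density cell, including `mean_abs_pct_error_density`).
#' @export
run_density_calibration <- function(radii_nm = c(1000, 1250, 1500),
                                    densities_per_um2 = c(4, 5, 6, 7),
                                    n_per_condition = 20, seed = 1, ...) {
  grid <- generate_condition_grid(radii_nm, densities_per_um2,
                                  n_per_condition, seed = seed, ...)
  rows <- vector("list", nrow(grid$manifest))
  for (i in seq_len(nrow(grid$manifest))) {
    cfg <- grid$configs[[i]]
    sim <- simulate_nucleus(cfg)
    masks <- segment_nuclei(max_project(sim$volume), cfg$pixel_nm)
    mask <- if (length(masks)) masks[[which.max(vapply(masks, `[[`, 0, "area_px"))]]
    else NULL
    q <- quantify_nucleus(sim$volume, mask)
    mrow <- grid$manifest[i, ]
    rows[[i]] <- cbind(mrow, data.frame(
      measured_count = q$record$npc_count,
      measured_SA_um2 = q$record$surface_area_um2,
      measured_density = q$record$density_per_um2))
  }
  per_image <- do.call(rbind, rows)
  per_image$pct_error_density <-
    100 * (per_image$measured_density - per_image$true_density) /
    per_image$true_density
  per_image$pct_error_SA <-
    100 * (per_image$measured_SA_um2 - per_image$true_SA_um2) /
    per_image$true_SA_um2
  agg <- stats::aggregate(
    cbind(measured_density, true_density, pct_error_density, pct_error_SA) ~
      radius_nm + requested_density, data = per_image, FUN = mean)
  # error of the condition-mean density (the calibration curve quantity)
  agg$abs_pct_error_density <- abs(agg$pct_error_density)
  list(per_image = per_image, per_condition = agg)
}

#' Simulate one nucleus for single-particle averaging
#'
#' Draws the SPB landmark pair first (top polar cap, tangent axis), then
#' samples NPC positions - optionally excluding a ball of
#' `exclusion_radius_nm` around the SPB midpoint to construct a
#' ground-truth exclusion zone - and renders both channels through the
#' camera model.
#'
#' @param config a [sim_config()].
#' @param exclusion_radius_nm radius of the constructed NPC-free zone
#'   around the SPB midpoint (0 = fully random null).
#' @param seed seed for this nucleus.
#' @param ... passed to [place_spb_pair()].
#' @return list: `truth`, `spb_truth`, `npc` and `spb` camera
#'   [volume_image()]s, `center_nm`.
#' @export
simulate_spa_nucleus <- function(config, exclusion_radius_nm = 0, seed = NULL,
                                 ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  cfg$seed <- NULL
  spb_truth <- place_spb_pair(cfg, ...)
  truth <- sample_points_on_sphere(cfg, exclude_center = spb_truth$midpoint_nm,
                                   exclude_radius_nm = exclusion_radius_nm)
  npc <- apply_camera(render_volume(truth, cfg), cfg)
  npc$channel <- "npc"
  spb <- render_spb_channel(spb_truth, truth, cfg)$volume
  list(truth = truth, spb_truth = spb_truth, npc = npc, spb = spb,
       center_nm = volume_center_nm(npc))
}

#' Full single-particle-averaging chain over simulated nuclei
#'
#' For each simulated nucleus: fit the two-Gaussian SPB pair (seeded at
#' the truth plus jitter), apply the nucleus-edge filter, realign the NPC
#' channel into the pair frame, and sum-project a z-slab of
#' `+/- z_slab_half_nm` around the fitted pair's z-plane (the top-down
#' optical slab containing the SPB-proximal nuclear envelope cap; a full-z
#' sum would mix in the bottom hemisphere and the limb-brightened edge of
#' the projected shell). Accepted slab projections are averaged (with
#' x-axis mirroring) and the 12-pixel axis profile computed and normalized
#' to its maximum.
#'
#' @param n_nuclei number of simulated nuclei.
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param exclusion_radius_nm constructed exclusion-zone radius (0 = null).
#' @param seed_jitter_nm SD of the Gaussian jitter applied to the truth
#'   positions used as fit seeds (emulates manual clicking).
#' @param min_edge_nm edge-filter threshold.
#' @param width_px,half_length_nm axis-profile band width and half extent.
#' @param z_slab_half_nm half extent of the projected z-slab around the
#'   fitted SPB z-plane.
#' @return list: `profile` (`spa_profile`), `map` (`average_map`),
#'   `value_at_spb` (min of the normalized profile at the two SPB
#'   positions), `separations_nm` (fitted pair separations), `n_used`,
#'   `n_failed`.
#' @export
run_spa_chain <- function(n_nuclei = 100, config = sim_config(n_npcs = 125),
                          seed = 1, exclusion_radius_nm = 0,
                          seed_jitter_nm = 20, min_edge_nm = 400,
                          width_px = 12, half_length_nm = 300,
                          z_slab_half_nm = 300) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_nuclei)
  maps <- list(); seps <- numeric(0); n_failed <- 0L
  for (i in seq_len(n_nuclei)) {
    sim <- simulate_spa_nucleus(config, exclusion_radius_nm, seed = seeds[i])
    ctr <- sim$center_nm
    truth_pos <- rbind(sim$spb_truth$mother_nm, sim$spb_truth$daughter_nm) +
      rep(ctr, each = 2)
    jit <- matrix(stats::rnorm(6, 0, seed_jitter_nm), 2, 3)
    pair <- fit_spb_pair(sim$spb, truth_pos + jit)
    if (!isTRUE(pair$converged)) { n_failed <- n_failed + 1L; next }
    mask <- disk_mask(dim(sim$npc$voxels)[1:2], config$pixel_nm,
                      center_nm = ctr[c("x", "y")],
                      radius_nm = config$radius_nm)
    if (!edge_filter(pair, mask, config$pixel_nm, min_nm = min_edge_nm)) {
      n_failed <- n_failed + 1L; next
    }
    al <- realign(sim$npc, pair)
    zc <- mean(c(pair$mother_nm["z"], pair$daughter_nm["z"]))
    zcts <- (seq_len(dim(al$volume$voxels)[3]) - 0.5) * al$volume$zstep_nm
    sel <- abs(zcts - zc) <= z_slab_half_nm
    maps[[length(maps) + 1L]] <-
      apply(al$volume$voxels[, , sel, drop = FALSE], c(1, 2), sum)
    seps <- c(seps, pair$separation_nm)
  }
  if (!length(maps)) stop("no nuclei passed the SPA filters")
  am <- average_maps(maps, mirror = TRUE, pixel_nm = config$pixel_nm)
  prof <- axis_profile(am, width_px = width_px, half_length_nm = half_length_nm)
  spb_x <- c(-1, 1) * config$spb_separation_nm / 2
  list(profile = prof, map = am,
       value_at_spb = min(profile_value_at(prof, spb_x)),
       separations_nm = seps, n_used = length(maps), n_failed = n_failed)
}

# circular nucleus mask used when ground truth geometry is known
disk_mask <- function(dims_yx, pixel_nm, center_nm, radius_nm) {
  ys <- (seq_len(dims_yx[1]) - 0.5) * pixel_nm
  xs <- (seq_len(dims_yx[2]) - 0.5) * pixel_nm
  m <- outer(ys, xs, function(y, x)
    (x - center_nm[1])^2 + (y - center_nm[2])^2 <= radius_nm^2)
  new_nucleus_mask(m, "auto")
}

#' SPB separation recovery from repeated simulated fits
#'
#' Simulates SPB-channel volumes with the configured landmark separation
#' and camera model, fits each with the two-3D-Gaussian model seeded near
#' the truth, and summarizes the fitted centre-to-centre distances.
#'
#' @param n_rep number of replicate volumes.
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param seed_jitter_nm SD of seed jitter.
#' @return list: `mean_separation_nm`, `se_nm`, `separations_nm`,
#'   `n_converged`.
#' @export
run_spb_separation_recovery <- function(n_rep = 50,
                                        config = sim_config(n_npcs = 125),
                                        seed = 1, seed_jitter_nm = 20) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  seps <- numeric(0)
  for (i in seq_len(n_rep)) {
    set.seed(seeds[i])
    cfg <- config
    cfg$seed <- NULL
    spb_truth <- place_spb_pair(cfg)
    shell <- structure(list(positions = matrix(numeric(0), 0, 3),
                            intensities = numeric(0),
                            sphere_center = c(0, 0, 0),
                            radius_nm = cfg$radius_nm),
                       class = "foci_truth")
    vol <- render_spb_channel(spb_truth, shell, cfg)$volume
    ctr <- volume_center_nm(vol)
    truth_pos <- rbind(spb_truth$mother_nm, spb_truth$daughter_nm) +
      rep(ctr, each = 2)
    jit <- matrix(stats::rnorm(6, 0, seed_jitter_nm), 2, 3)
    pair <- fit_spb_pair(vol, truth_pos + jit)
    if (isTRUE(pair$converged)) seps <- c(seps, pair$separation_nm)
  }
  if (!length(seps)) stop("no replicate fit converged")
  list(mean_separation_nm = mean(seps),
       se_nm = stats::sd(seps) / sqrt(length(seps)),
       separations_nm = seps, n_converged = length(seps))
}

#' Run the simulate-and-count pipeline to files
#'
#' Simulates a condition grid, optionally writes the image stacks, runs
#' per-nucleus quantitation on every simulated image and writes the truth
#' manifest and per-nucleus records as CSV with configuration headers.
#' Deterministic for a fixed seed: same seed, byte-identical CSV bodies.
#'
#' @param out_dir output directory (created if needed).
#' @param radii_nm,densities_per_um2,n_per_condition condition grid.
#' @param seed master seed.
#' @param write_stacks also write each simulated stack as TIFF.
#' @param ... forwarded to [sim_config()].
#' @return invisibly, list with `records`, `manifest` and the output paths.
#' @export
run_pipeline <- function(out_dir, radii_nm = 1250, densities_per_um2 = 6.4,
                         n_per_condition = 2, seed = 1, write_stacks = FALSE,
                         ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cal <- run_density_calibration(radii_nm, densities_per_um2,
                                 n_per_condition, seed = seed, ...)
  cfg <- run_config(seed = seed)
  manifest_path <- file.path(out_dir, "manifest.csv")
  records_path <- file.path(out_dir, "records.csv")
  write_csv_with_header(cal$per_image[, c("image_id", "seed", "radius_nm",
                                          "n_npcs", "true_density",
                                          "true_SA_um2")],
                        manifest_path, cfg)
  write_csv_with_header(cal$per_image, records_path, cfg)
  if (write_stacks) {
    grid <- generate_condition_grid(radii_nm, densities_per_um2,
                                    n_per_condition, seed = seed, ...)
    for (i in seq_len(nrow(grid$manifest))) {
      sim <- simulate_nucleus(grid$configs[[i]])
      write_volume(list(npc = sim$volume),
                   file.path(out_dir, paste0(grid$manifest$image_id[i], ".tif")))
    }
  }
  invisible(list(records = cal$per_image, manifest = cal$per_image,
                 paths = c(manifest = manifest_path, records = records_path)))
}
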