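#' Simulation configuration for synthetic nuclei
#'
#' Defines the geometry, optics and camera model used to render synthetic
#' 3D-SIM-like nuclei: NPCs are anisotropic 3D Gaussian puncta placed
#' uniformly at random on a sphere with a minimum centre-to-centre spacing,
#' rendered on a calibrated voxel grid, then passed through a
#' Poisson/gain/read-noise camera.
#'
#' Exactly one of `n_npcs` and `density_per_um2` must be given; when a
#' density is given the emitter count is `round(density * 4 * pi * r_um^2)`.
#'
#' @param radius_nm sphere radius in nm.
#' @param n_npcs number of NPC emitters (alternative to `density_per_um2`).
#' @param density_per_um2 target NPC density in NPCs/um^2.
#' @param min_spacing_nm minimum centre-to-centre distance between emitters (nm).
#' @param psf_fwhm_xy_nm lateral Gaussian FWHM of an emitter (nm).
#' @param psf_fwhm_z_nm axial Gaussian FWHM (nm).
#' @param peak_photons peak expected photon count of one emitter.
#' @param gain multiplicative camera gain applied to (possibly Poisson-sampled)
#'   photon counts.
#' @param read_noise_sd SD of additive Gaussian read noise, in output
#'   intensity units.
#' @param shot_noise logical; Poisson-sample photons before gain.
#' @param pixel_nm lateral voxel size (nm).
#' @param zstep_nm axial voxel spacing (nm).
#' @param spb_separation_nm centre-to-centre distance of the two spindle pole
#'   body (SPB) landmarks in the optional second channel (nm).
#' @param seed optional RNG seed used by the simulation entry points.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(radius_nm = 1250, n_npcs = NULL, density_per_um2 = NULL,
                       min_spacing_nm = 100, psf_fwhm_xy_nm = 100,
                       psf_fwhm_z_nm = 300, peak_photons = 100, gain = 20,
                       read_noise_sd = 40, shot_noise = TRUE, pixel_nm = 40,
                       zstep_nm = 125, spb_separation_nm = 180, seed = NULL) {
  if (!is.finite(radius_nm) || radius_nm <= 0) stop("radius_nm must be > 0")
  if (min_spacing_nm < 0) stop("min_spacing_nm must be >= 0")
  if (is.null(n_npcs) == is.null(density_per_um2))
    stop("give exactly one of n_npcs and density_per_um2")
  sa_um2 <- 4 * pi * (radius_nm / 1000)^2
  if (is.null(n_npcs)) n_npcs <- round(density_per_um2 * sa_um2)
  n_npcs <- as.integer(n_npcs)
  if (n_npcs < 0) stop("n_npcs must be >= 0")
  for (p in c(peak_photons, gain, read_noise_sd))
    if (!is.finite(p) || p < 0) stop("noise/gain parameters must be >= 0")
  # feasibility of packing: spacing disks must not come close to covering the sphere
  if (n_npcs > 0 && min_spacing_nm > 0) {
    covered <- n_npcs * pi * (min_spacing_nm / 2)^2
    if (covered > 0.5 * 4 * pi * radius_nm^2)
      stop(sprintf("packing infeasible: %d emitters at %g nm spacing on a %g nm sphere",
                   n_npcs, min_spacing_nm, radius_nm))
  }
  structure(list(radius_nm = radius_nm, n_npcs = n_npcs,
                 density_per_um2 = n_npcs / sa_um2,
                 min_spacing_nm = min_spacing_nm,
                 psf_fwhm_xy_nm = psf_fwhm_xy_nm, psf_fwhm_z_nm = psf_fwhm_z_nm,
                 peak_photons = peak_photons, gain = gain,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 pixel_nm = pixel_nm, zstep_nm = zstep_nm,
                 spb_separation_nm = spb_separation_nm, seed = seed),
            class = "sim_config")
}

#' Sample emitter positions uniformly on a sphere with minimum spacing
#'
#' Rejection sampling: candidate positions are drawn uniformly on the sphere
#' (normalised Gaussian triples) and accepted only if at least
#' `min_spacing_nm` from every previously accepted emitter. Positions are
#' centred on the origin (the sphere centre).
#'
#' @param config a [sim_config()].
#' @param max_attempts rejection-sampling cap per point; if exceeded the
#'   sampler fails naming the count achieved.
#' @param exclude_center optional length-3 point (nm, sphere-centre frame);
#'   candidates within `exclude_radius_nm` of it are rejected (used to
#'   construct ground-truth exclusion zones).
#' @param exclude_radius_nm radius of the optional exclusion region.
#' @return an object of class `foci_truth` with fields `positions` (n x 3
#'   matrix, nm, columns x/y/z), `intensities`, `sphere_center` and `radius_nm`.
#' @export
sample_points_on_sphere <- function(config, max_attempts = 1e4,
                                    exclude_center = NULL,
                                    exclude_radius_nm = 0) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_npcs
  r <- config$radius_nm
  pos <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  i <- 0L
  while (i < n) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf("packing failed: placed %d of %d emitters (min spacing %g nm)",
                     i, n, config$min_spacing_nm))
      v <- stats::rnorm(3)
      p <- v / sqrt(sum(v^2)) * r
      if (!is.null(exclude_center) && exclude_radius_nm > 0 &&
          sum((p - exclude_center)^2) < exclude_radius_nm^2) next
      if (i == 0L) break
      d2 <- (pos[seq_len(i), 1] - p[1])^2 + (pos[seq_len(i), 2] - p[2])^2 +
        (pos[seq_len(i), 3] - p[3])^2
      if (min(d2) >= config$min_spacing_nm^2) break
    }
    i <- i + 1L
    pos[i, ] <- p
  }
  structure(list(positions = pos,
                 intensities = rep(config$peak_photons, n),
                 sphere_center = c(x = 0, y = 0, z = 0),
                 radius_nm = r),
            class = "foci_truth")
}

# Gaussian SD from FWHM using the package-wide convention FWHM = 2.355 * SD
fwhm_factor <- function() 2.355

# Grid dimensions for a sphere of the configured radius: diameter plus a
# margin of 3 x axial FWHM on every side, so emitter mass truncation < 1%.
sim_grid_dims <- function(config) {
  margin <- 3 * config$psf_fwhm_z_nm
  ext_xy <- 2 * config$radius_nm + 2 * margin
  ext_z <- 2 * config$radius_nm + 2 * margin
  c(ny = ceiling(ext_xy / config$pixel_nm),
    nx = ceiling(ext_xy / config$pixel_nm),
    nz = ceiling(ext_z / config$zstep_nm))
}

#' Render emitters as anisotropic 3D Gaussians into a noiseless photon image
#'
#' The expected-photon image is the sum of 3D Gaussians (SD = FWHM / 2.355
#' per axis) evaluated at voxel centres. The grid is auto-sized to the sphere
#' diameter plus a 3 x axial-FWHM margin per side and the sphere centre is
#' placed at the grid centre; each Gaussian is evaluated on a +/- 4.5 SD
#' window so that the truncated mass is negligible.
#'
#' @param truth a `foci_truth` (positions relative to the sphere centre).
#' @param config a [sim_config()].
#' @param max_voxels guard against accidental huge grids.
#' @return a noiseless [volume_image()] of expected photons.
#' @export
render_volume <- function(truth, config, max_voxels = 4e7) {
  d <- sim_grid_dims(config)
  if (prod(d) > max_voxels)
    stop(sprintf("voxel grid %d x %d x %d exceeds cap of %g voxels",
                 d[1], d[2], d[3], max_voxels))
  vol <- array(0, dim = unname(d))
  n <- if (is.null(truth$positions)) 0L else nrow(truth$positions)
  if (n > 0L) {
    center <- c((d["nx"] / 2) * config$pixel_nm,
                (d["ny"] / 2) * config$pixel_nm,
                (d["nz"] / 2) * config$zstep_nm)
    sxy <- config$psf_fwhm_xy_nm / fwhm_factor()
    sz <- config$psf_fwhm_z_nm / fwhm_factor()
    wx <- ceiling(4.5 * sxy / config$pixel_nm)
    wz <- ceiling(4.5 * sz / config$zstep_nm)
    for (k in seq_len(n)) {
      p <- truth$positions[k, ] + center  # volume-frame nm
      amp <- truth$intensities[k]
      cx <- p[1] / config$pixel_nm + 0.5  # fractional voxel indices
      cy <- p[2] / config$pixel_nm + 0.5
      cz <- p[3] / config$zstep_nm + 0.5
      xs <- max(1L, floor(cx - wx)):min(d["nx"], ceiling(cx + wx))
      ys <- max(1L, floor(cy - wx)):min(d["ny"], ceiling(cy + wx))
      zs <- max(1L, floor(cz - wz)):min(d["nz"], ceiling(cz + wz))
      if (!length(xs) || !length(ys) || !length(zs)) next
      gx <- exp(-((xs - 0.5) * config$pixel_nm - p[1])^2 / (2 * sxy^2))
      gy <- exp(-((ys - 0.5) * config$pixel_nm - p[2])^2 / (2 * sxy^2))
      gz <- exp(-((zs - 0.5) * config$zstep_nm - p[3])^2 / (2 * sz^2))
      blk <- outer(gy, gx)
      for (j in seq_along(zs))
        vol[ys, xs, zs[j]] <- vol[ys, xs, zs[j]] + amp * gz[j] * blk
    }
  }
  volume_image(vol, config$pixel_nm, config$zstep_nm, channel = "photons")
}

#' Apply the camera model: shot noise, gain and Gaussian read noise
#'
#' `output = gain * (Poisson(expected) if shot_noise else expected)
#'  + Normal(0, read_noise_sd)` per voxel.
#'
#' @param photon_image noiseless expected-photon [volume_image()].
#' @param config a [sim_config()].
#' @param seed optional seed applied before sampling.
#' @return a [volume_image()] in camera intensity units.
#' @export
apply_camera <- function(photon_image, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- photon_image$voxels
  if (any(v < 0)) stop("photon image must be non-negative")
  nvox <- length(v)
  out <- if (isTRUE(config$shot_noise)) stats::rpois(nvox, lambda = v) else as.vector(v)
  out <- config$gain * out
  if (config$read_noise_sd > 0) out <- out + stats::rnorm(nvox, 0, config$read_noise_sd)
  volume_image(array(out, dim = dim(v)), photon_image$pixel_nm,
               photon_image$zstep_nm, channel = photon_image$channel)
}

#' Add a spindle pole body landmark pair in a second channel
#'
#' Places the duplicated SPB pair in the top polar cap of the sphere with
#' the pair axis tangent to the sphere and random in-plane orientation, so
#' that a top-down view is obtained and both landmarks project at least
#' `edge_margin_nm` inside the projected nucleus edge by construction.
#'
#' @param truth the NPC `foci_truth` (defines sphere radius / centre).
#' @param config a [sim_config()].
#' @param spb_peak_photons peak photon count for the mother SPB; landmarks
#'   are rendered brighter than single NPCs.
#' @param daughter_fraction daughter/mother peak intensity ratio.
#' @param edge_margin_nm required projected distance to the nucleus edge.
#' @param seed optional seed.
#' @param camera logical; apply the camera model to the rendered channel.
#' @return list with `truth` (class `spb_truth`: `mother_nm`, `daughter_nm`
#'   positions relative to sphere centre, `separation_nm`, intensities) and
#'   `volume` (the rendered second channel).
#' @export
add_spb_channel <- function(truth, config, spb_peak_photons = 4 * config$peak_photons,
                            daughter_fraction = 0.7, edge_margin_nm = 400,
                            seed = NULL, camera = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  spb_truth <- place_spb_pair(config, radius_nm = truth$radius_nm,
                              spb_peak_photons = spb_peak_photons,
                              daughter_fraction = daughter_fraction,
                              edge_margin_nm = edge_margin_nm)
  render_spb_channel(spb_truth, truth, config, camera = camera)
}

#' Draw an SPB landmark pair placement (without rendering)
#'
#' @inheritParams add_spb_channel
#' @param radius_nm sphere radius (nm).
#' @return an `spb_truth` (positions relative to the sphere centre).
#' @export
place_spb_pair <- function(config, radius_nm = config$radius_nm,
                           spb_peak_photons = 4 * config$peak_photons,
                           daughter_fraction = 0.7, edge_margin_nm = 400) {
  r <- radius_nm
  half_sep <- config$spb_separation_nm / 2
  max_rho <- r - edge_margin_nm - half_sep  # projected midpoint radius bound
  if (max_rho <= 0)
    stop(sprintf("nucleus radius %g nm too small for %g nm edge margin", r, edge_margin_nm))
  sin_max <- max_rho / r
  cos_min <- sqrt(1 - sin_max^2)
  # uniform on the admissible polar cap (z = r cos(theta), cos(theta) uniform)
  cth <- stats::runif(1, cos_min, 1)
  sth <- sqrt(1 - cth^2)
  phi <- stats::runif(1, 0, 2 * pi)
  mid <- r * c(sth * cos(phi), sth * sin(phi), cth)
  # orthonormal tangent basis at mid
  e1 <- c(-sin(phi), cos(phi), 0)
  e2 <- c(cth * cos(phi), cth * sin(phi), -sth)
  ang <- stats::runif(1, 0, 2 * pi)
  u <- cos(ang) * e1 + sin(ang) * e2
  mother <- mid - half_sep * u
  daughter <- mid + half_sep * u
  structure(list(
    mother_nm = mother, daughter_nm = daughter,
    midpoint_nm = mid,
    separation_nm = sqrt(sum((mother - daughter)^2)),
    mother_photons = spb_peak_photons,
    daughter_photons = spb_peak_photons * daughter_fraction),
    class = "spb_truth")
}

# render an spb_truth into the second channel on the same grid as the NPCs
render_spb_channel <- function(spb_truth, truth, config, camera = TRUE) {
  spb_peak_photons <- spb_truth$mother_photons
  pair_truth <- structure(list(
    positions = rbind(spb_truth$mother_nm, spb_truth$daughter_nm),
    intensities = c(spb_truth$mother_photons, spb_truth$daughter_photons),
    sphere_center = truth$sphere_center, radius_nm = truth$radius_nm),
    class = "foci_truth")
  vol <- render_volume(pair_truth, config)
  vol$channel <- "spb"
  if (camera) vol <- apply_camera(vol, config)
  list(truth = spb_truth, volume = vol)
}

#' Simulate one nucleus end to end
#'
#' Seeds the RNG from `config$seed` (when set), samples emitter positions,
#' renders the noiseless photon image, applies the camera model, and
#' optionally adds the SPB landmark channel.
#'
#' @param config a [sim_config()].
#' @param spb logical; also simulate the SPB landmark channel.
#' @param keep_photons logical; keep the noiseless photon image.
#' @param ... passed to [add_spb_channel()].
#' @return list with `truth`, `volume` (camera image), `center_nm` (sphere
#'   centre in the volume frame), optionally `photons` and `spb`.
#' @export
simulate_nucleus <- function(config, spb = FALSE, keep_photons = FALSE, ...) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL  # RNG already seeded; let stages draw sequentially
  truth <- sample_points_on_sphere(cfg)
  photons <- render_volume(truth, cfg)
  vol <- apply_camera(photons, cfg)
  vol$channel <- "npc"
  out <- list(truth = truth, volume = vol,
              center_nm = volume_center_nm(vol), config = config)
  if (keep_photons) out$photons <- photons
  if (spb) out$spb <- add_spb_channel(truth, cfg, ...)
  out
}

#' Build a simulation condition grid and its truth manifest
#'
#' One row per simulated image over the cross of radii and densities, with
#' deterministic per-image seeds derived from the master seed.
#'
#' @param radii_nm vector of sphere radii (nm).
#' @param densities_per_um2 vector of target NPC densities.
#' @param n_per_condition replicate images per condition.
#' @param seed master seed.
#' @param ... further arguments forwarded to [sim_config()].
#' @return list with `manifest` (data.frame: image_id, seed, radius_nm,
#'   n_npcs, true_density, true_SA_um2, requested_density) and `configs`
#'   (list of `sim_config`, one per row).
#' @export
generate_condition_grid <- function(radii_nm, densities_per_um2,
                                    n_per_condition, seed = 1, ...) {
  set.seed(seed)
  grid <- expand.grid(radius_nm = radii_nm, density = densities_per_um2,
                      rep = seq_len(n_per_condition))
  n <- nrow(grid)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  configs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- sim_config(radius_nm = grid$radius_nm[i],
                      density_per_um2 = grid$density[i],
                      seed = seeds[i], ...)
    sa <- 4 * pi * (cfg$radius_nm / 1000)^2
    configs[[i]] <- cfg
    rows[[i]] <- data.frame(image_id = sprintf("sim_%04d", i), seed = seeds[i],
                            radius_nm = cfg$radius_nm, n_npcs = cfg$n_npcs,
                            true_density = cfg$n_npcs / sa, true_SA_um2 = sa,
                            requested_density = grid$density[i])
  }
  list(manifest = do.call(rbind, rows), configs = configs)
}

#' Synthetic nucleolar scene: paired Nup / nucleolar-marker inputs
#'
#' Emulates a mid-plane view of a nucleus whose nucleolus faces one side:
#' the nuclear envelope is a circle carrying Nup signal, reduced by
#' `nup_reduction_frac` over a nucleolar arc where the nucleolar marker is
#' present. Returns exact analytic line profiles (for oracle tests) plus a
#' rendered 2-channel 2D image with the circular trace polyline (for the
#' profile-extraction machinery).
#'
#' @param ne_radius_nm nuclear envelope radius (nm).
#' @param nucleolar_arc_deg angular width of the nucleolar arc (degrees).
#' @param nup_reduction_frac fractional Nup reduction over the arc, in [0, 1].
#' @param noise_sd SD of additive Gaussian noise on the profiles (flank
#'   Nup level is 1).
#' @param seed optional seed.
#' @param pixel_nm raster pixel size for the rendered image.
#' @param ring_sd_nm radial Gaussian cross-section SD of the rendered ring.
#' @return list with `profiles` (class `ne_profile_pair`), `image` (list of
#'   `nup` and `marker` matrices), `polyline` (k x 2 pixel coordinates,
#'   closed), `pixel_nm` and `truth`.
#' @export
generate_nucleolar_scene <- function(ne_radius_nm = 1250, nucleolar_arc_deg = 90,
                                     nup_reduction_frac = 0.2, noise_sd = 0,
                                     seed = NULL, pixel_nm = 40, ring_sd_nm = 80) {
  if (nup_reduction_frac < 0 || nup_reduction_frac > 1)
    stop("nup_reduction_frac must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  arc_center <- stats::runif(1, 0, 2 * pi)
  half_arc <- nucleolar_arc_deg / 2 * pi / 180
  n_theta <- max(16L, round(2 * pi * ne_radius_nm / pixel_nm))
  theta <- (seq_len(n_theta) - 1) / n_theta * 2 * pi
  dtheta <- abs(((theta - arc_center + pi) %% (2 * pi)) - pi)
  in_arc <- dtheta <= half_arc
  nup <- ifelse(in_arc, 1 - nup_reduction_frac, 1)
  marker <- as.numeric(in_arc)
  if (noise_sd > 0) {
    nup <- nup + stats::rnorm(n_theta, 0, noise_sd)
    marker <- marker + stats::rnorm(n_theta, 0, noise_sd)
  }
  profiles <- structure(list(positions_nm = theta * ne_radius_nm,
                             nup = nup, marker = marker,
                             circumference_nm = 2 * pi * ne_radius_nm,
                             closed = TRUE, id = "scene"),
                        class = "ne_profile_pair")
  # rendered raster: ring with Gaussian radial cross-section, amplitude
  # modulated by the same angular profiles
  half_ext <- ne_radius_nm + 5 * ring_sd_nm
  npx <- ceiling(2 * half_ext / pixel_nm)
  ctr <- npx / 2 * pixel_nm
  xs <- (seq_len(npx) - 0.5) * pixel_nm - ctr
  X <- matrix(xs, npx, npx, byrow = TRUE)
  Y <- matrix(xs, npx, npx)
  R <- sqrt(X^2 + Y^2)
  TH <- atan2(Y, X) %% (2 * pi)
  radial <- exp(-(R - ne_radius_nm)^2 / (2 * ring_sd_nm^2))
  amp_at <- function(prof) {
    idx <- pmin(n_theta, pmax(1L, round(TH / (2 * pi) * n_theta) + 1L))
    idx[idx > n_theta] <- 1L
    matrix(prof[idx], npx, npx)
  }
  img_nup <- radial * amp_at(nup)
  img_marker <- radial * amp_at(marker)
  k <- 180L
  ang <- seq(0, 2 * pi, length.out = k + 1L)
  polyline <- cbind(x = (ne_radius_nm * cos(ang) + ctr) / pixel_nm,
                    y = (ne_radius_nm * sin(ang) + ctr) / pixel_nm)
  list(profiles = profiles,
       image = list(nup = img_nup, marker = img_marker),
       polyline = polyline, pixel_nm = pixel_nm,
       truth = list(reduction = nup_reduction_frac,
                    arc_center_rad = arc_center,
                    arc_deg = nucleolar_arc_deg,
                    ne_radius_nm = ne_radius_nm))
}
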