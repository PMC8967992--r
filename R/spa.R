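#' Jointly fit two 3D Gaussians to an SPB landmark pair
#'
#' Least-squares fit of two anisotropic 3D Gaussians with shared widths and
#' a shared constant baseline to a subvolume around two approximate
#' centres (manual clicks or simulator truth plus jitter). The brighter
#' fitted spot is labelled the mother SPB.
#'
#' @param volume a [volume_image()] (the SPB channel).
#' @param seeds 2 x 3 matrix of approximate centres (x, y, z nm).
#' @param crop_margin_nm box margin around the seeds used for fitting.
#' @param psf_fwhm_xy_nm,psf_fwhm_z_nm starting widths (FWHM, nm).
#' @return an object of class `spb_pair`: `mother_nm`, `daughter_nm`,
#'   `amplitudes` (mother, daughter), `sd_xy_nm`, `sd_z_nm`, `baseline`,
#'   `separation_nm`, `ratio` (daughter/mother amplitude), `converged`.
#'   Non-convergence, a center swap (both centres nearest the same seed) or
#'   a collapsed pair is flagged with `converged = FALSE`.
#' @export
fit_spb_pair <- function(volume, seeds, crop_margin_nm = 400,
                         psf_fwhm_xy_nm = 100, psf_fwhm_z_nm = 300) {
  seeds <- as.matrix(seeds)
  dimnames(seeds) <- NULL
  stopifnot(nrow(seeds) == 2, ncol(seeds) == 3)
  d <- dim(volume$voxels)
  px <- volume$pixel_nm; zs <- volume$zstep_nm
  xr <- range(seeds[, 1]) + c(-1, 1) * crop_margin_nm
  yr <- range(seeds[, 2]) + c(-1, 1) * crop_margin_nm
  zr <- range(seeds[, 3]) + c(-1, 1) * crop_margin_nm
  xs <- max(1, floor(xr[1] / px)):min(d[2], ceiling(xr[2] / px))
  ys <- max(1, floor(yr[1] / px)):min(d[1], ceiling(yr[2] / px))
  zvs <- max(1, floor(zr[1] / zs)):min(d[3], ceiling(zr[2] / zs))
  sub <- volume$voxels[ys, xs, zvs, drop = FALSE]
  dat <- data.frame(
    v = as.vector(sub),
    x = rep((xs - 0.5) * px, each = length(ys), times = length(zvs)),
    y = rep((ys - 0.5) * px, times = length(xs) * length(zvs)),
    z = rep((zvs - 0.5) * zs, each = length(ys) * length(xs)))
  b0 <- stats::median(dat$v)
  peak_at <- function(s) {
    i <- which.min((dat$x - s[1])^2 + (dat$y - s[2])^2 + (dat$z - s[3])^2)
    max(dat$v[i] - b0, 1e-3)
  }
  start <- list(a1 = peak_at(seeds[1, ]), a2 = peak_at(seeds[2, ]),
                x1 = seeds[1, 1], y1 = seeds[1, 2], z1 = seeds[1, 3],
                x2 = seeds[2, 1], y2 = seeds[2, 2], z2 = seeds[2, 3],
                sxy = psf_fwhm_xy_nm / fwhm_factor(),
                sz = psf_fwhm_z_nm / fwhm_factor(), b = b0)
  failed <- structure(list(converged = FALSE), class = "spb_pair")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b +
        a1 * exp(-((x - x1)^2 + (y - y1)^2) / (2 * sxy^2) - (z - z1)^2 / (2 * sz^2)) +
        a2 * exp(-((x - x2)^2 + (y - y2)^2) / (2 * sxy^2) - (z - z2)^2 / (2 * sz^2)),
      data = dat, start = start,
      lower = c(a1 = 0, a2 = 0, x1 = -Inf, y1 = -Inf, z1 = -Inf,
                x2 = -Inf, y2 = -Inf, z2 = -Inf, sxy = 1, sz = 1, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) return(failed)
  c1 <- cf[c("x1", "y1", "z1")]; c2 <- cf[c("x2", "y2", "z2")]
  sep <- sqrt(sum((c1 - c2)^2))
  # centre-swap / collapse checks: each fitted centre must be nearest its
  # own seed, and the pair must not have merged into a single spot
  d11 <- sum((c1 - seeds[1, ])^2); d12 <- sum((c1 - seeds[2, ])^2)
  d21 <- sum((c2 - seeds[1, ])^2); d22 <- sum((c2 - seeds[2, ])^2)
  if (sep < px / 2) return(failed)
  if (d11 > d12 || d22 > d21) return(failed)
  if (cf["a1"] <= 0 || cf["a2"] <= 0) return(failed)
  mother_first <- cf["a1"] >= cf["a2"]
  mother <- if (mother_first) c1 else c2
  daughter <- if (mother_first) c2 else c1
  amps <- if (mother_first) cf[c("a1", "a2")] else cf[c("a2", "a1")]
  structure(list(
    mother_nm = stats::setNames(as.numeric(mother), c("x", "y", "z")),
    daughter_nm = stats::setNames(as.numeric(daughter), c("x", "y", "z")),
    amplitudes = stats::setNames(as.numeric(amps), c("mother", "daughter")),
    sd_xy_nm = unname(cf["sxy"]), sd_z_nm = unname(cf["sz"]),
    baseline = unname(cf["b"]), separation_nm = sep,
    ratio = unname(amps[2] / amps[1]), converged = TRUE),
    class = "spb_pair")
}

#' @export
print.spb_pair <- function(x, ...) {
  if (!isTRUE(x$converged)) cat("<spb_pair> fit not converged\n")
  else cat(sprintf("<spb_pair> separation %.1f nm, daughter/mother ratio %.2f\n",
                   x$separation_nm, x$ratio))
  invisible(x)
}

#' Nucleus-edge distance filter for SPA
#'
#' A nucleus passes if both projected SPB centres lie at least `min_nm`
#' inside the boundary of the projected nucleus mask (centres outside the
#' mask fail). Guarantees a top-down view of the SPB region.
#'
#' @param pair an `spb_pair` (fitted centres in the volume frame, nm).
#' @param mask a `nucleus_mask` in the same frame.
#' @param pixel_nm lateral pixel size of the mask's image.
#' @param min_nm minimum distance to the mask boundary.
#' @return logical; attribute `distances_nm` carries the two distances.
#' @export
edge_filter <- function(pair, mask, pixel_nm, min_nm = 400) {
  stopifnot(isTRUE(pair$converged))
  dm <- EBImage::distmap(EBImage::Image(mask$mask * 1))
  dmm <- EBImage::imageData(dm)
  dim(dmm) <- dim(mask$mask)
  dist_at <- function(p) {
    iy <- round(p[2] / pixel_nm + 0.5); ix <- round(p[1] / pixel_nm + 0.5)
    if (iy < 1 || iy > nrow(dmm) || ix < 1 || ix > ncol(dmm)) return(0)
    dmm[iy, ix] * pixel_nm
  }
  dists <- c(dist_at(pair$mother_nm), dist_at(pair$daughter_nm))
  structure(all(dists >= min_nm), distances_nm = dists)
}

#' Realign a volume into the SPB pair frame
#'
#' In-plane rotation so that the mother-to-daughter axis lies along +x
#' (mother on the -x side) and translation placing the pair midpoint at the
#' frame centre; lateral bilinear interpolation, z untouched.
#'
#' @param volume a [volume_image()].
#' @param pair a converged `spb_pair` fitted on this volume.
#' @return an `aligned_volume`: the resampled [volume_image()] plus a
#'   `transform` record (rotation angle, midpoint, and the pair positions
#'   in the new frame).
#' @export
realign <- function(volume, pair) {
  stopifnot(isTRUE(pair$converged))
  mo <- pair$mother_nm; da <- pair$daughter_nm
  delta <- da - mo
  if (sqrt(sum(delta[1:2]^2)) < 1e-9) stop("zero lateral separation; cannot realign")
  phi <- atan2(delta[2], delta[1])
  mid <- (mo + da) / 2
  d <- dim(volume$voxels)
  px <- volume$pixel_nm
  ctr <- volume_center_nm(volume)
  qx <- (seq_len(d[2]) - 0.5) * px - ctr["x"]
  qy <- (seq_len(d[1]) - 0.5) * px - ctr["y"]
  QX <- matrix(qx, d[1], d[2], byrow = TRUE)
  QY <- matrix(qy, d[1], d[2])
  sx <- mid[1] + cos(phi) * QX - sin(phi) * QY
  sy <- mid[2] + sin(phi) * QX + cos(phi) * QY
  out <- array(0, dim = d)
  interp <- bilinear_weights(sx / px + 0.5, sy / px + 0.5, d[1], d[2])
  for (iz in seq_len(d[3])) {
    sl <- volume$voxels[, , iz]
    out[, , iz] <- bilinear_apply(sl, interp, d[1], d[2])
  }
  vol <- volume_image(out, volume$pixel_nm, volume$zstep_nm, volume$channel)
  structure(list(
    volume = vol,
    transform = list(angle_rad = -phi, midpoint_nm = mid,
                     mother_aligned_nm = c(x = unname(ctr["x"] - pair$separation_nm / 2),
                                           y = unname(ctr["y"])),
                     daughter_aligned_nm = c(x = unname(ctr["x"] + pair$separation_nm / 2),
                                             y = unname(ctr["y"])),
                     separation_nm = pair$separation_nm)),
    class = "aligned_volume")
}

# precompute bilinear gather indices/weights for fractional pixel coords
# (ix, iy in voxel-centre units); out-of-bounds samples contribute 0
bilinear_weights <- function(ix, iy, ny, nx) {
  x0 <- floor(ix); y0 <- floor(iy)
  wx <- ix - x0; wy <- iy - y0
  idx <- function(yy, xx) {
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    i <- ifelse(ok, (xx - 1) * ny + yy, 1L)
    list(i = i, ok = ok)
  }
  list(p00 = idx(y0, x0), p01 = idx(y0, x0 + 1),
       p10 = idx(y0 + 1, x0), p11 = idx(y0 + 1, x0 + 1),
       w00 = (1 - wy) * (1 - wx), w01 = (1 - wy) * wx,
       w10 = wy * (1 - wx), w11 = wy * wx)
}

bilinear_apply <- function(slice, w, ny, nx) {
  v <- slice[w$p00$i] * w$w00 * w$p00$ok + slice[w$p01$i] * w$w01 * w$p01$ok +
    slice[w$p10$i] * w$w10 * w$p10$ok + slice[w$p11$i] * w$w11 * w$p11$ok
  matrix(v, ny, nx)
}

#' Average realigned volumes into a single-particle map
#'
#' Takes the voxelwise mean of the z sum-projections of realigned volumes
#' and, when `mirror = TRUE`, averages the mean map with its mirror across
#' the x-axis to cancel directional bias in y. The 25%-of-maximum display
#' threshold is recorded for rendering only and never used in quantitation.
#'
#' @param aligned list of `aligned_volume` objects, [volume_image()]s or 2D
#'   matrices (pre-projected maps); all must share dimensions.
#' @param mirror average with the x-axis mirrored map.
#' @param pixel_nm lateral pixel size; taken from the first element when it
#'   carries calibration.
#' @param display_frac display threshold as a fraction of the map maximum.
#' @return an `average_map`: `map` matrix, `n`, `mirrored`,
#'   `display_threshold`, `pixel_nm`.
#' @export
average_maps <- function(aligned, mirror = TRUE, pixel_nm = NULL,
                         display_frac = 0.25) {
  if (!length(aligned)) stop("no aligned volumes to average")
  as_map <- function(a) {
    if (inherits(a, "aligned_volume")) {
      if (is.null(pixel_nm)) pixel_nm <<- a$volume$pixel_nm
      sum_project(a$volume)
    } else if (inherits(a, "volume_image")) {
      if (is.null(pixel_nm)) pixel_nm <<- a$pixel_nm
      sum_project(a)
    } else as.matrix(a)
  }
  maps <- lapply(aligned, as_map)
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("aligned maps must share dimensions")
  avg <- Reduce(`+`, maps) / length(maps)
  if (mirror) avg <- (avg + avg[nrow(avg):1, , drop = FALSE]) / 2
  structure(list(map = avg, n = length(maps), mirrored = mirror,
                 display_threshold = display_frac * max(avg),
                 pixel_nm = pixel_nm),
            class = "average_map")
}

#' Display-thresholded copy of an average map
#'
#' @param am an `average_map`.
#' @return matrix with values below the display threshold set to zero.
#' @export
clip_for_display <- function(am) {
  m <- am$map
  m[m < am$display_threshold] <- 0
  m
}

#' Axis intensity profile across the SPB pair
#'
#' Averages the map over a band of `width_px` rows centred on the SPB axis
#' and returns the profile along x over `+/- half_length_nm` around the
#' pair midpoint, normalized to the profile maximum.
#'
#' @param am an `average_map` centred on the SPB midpoint.
#' @param width_px band width in pixels.
#' @param half_length_nm profile half extent along x.
#' @param normalize divide by the profile maximum.
#' @param smooth_w boxcar width (samples) applied to the band-averaged
#'   profile before normalization; 120 nm at the default calibration,
#'   small against the ~200 nm structures quantified.
#' @return a `spa_profile`: `position_nm` (0 at the pair midpoint),
#'   `intensity`, `width_px`, `normalized`.
#' @export
axis_profile <- function(am, width_px = 12, half_length_nm = 300,
                         normalize = TRUE, smooth_w = 3) {
  m <- am$map
  px <- am$pixel_nm
  ny <- nrow(m); nx <- ncol(m)
  cy <- ny / 2 * px; cx <- nx / 2 * px
  ycent <- (seq_len(ny) - 0.5) * px
  rows <- which(abs(ycent - cy) <= width_px / 2 * px)
  if (length(rows) < width_px) stop("band width exceeds map extent")
  xcent <- (seq_len(nx) - 0.5) * px - cx
  cols <- which(abs(xcent) <= half_length_nm)
  if (!length(cols)) stop("profile extent exceeds map")
  full <- boxcar_smooth(colMeans(m[rows, , drop = FALSE]), smooth_w)
  intensity <- full[cols]
  if (normalize) intensity <- intensity / max(intensity)
  structure(list(position_nm = xcent[cols], intensity = intensity,
                 width_px = width_px, normalized = normalize),
            class = "spa_profile")
}

#' Interpolated profile value at a position
#'
#' @param profile a `spa_profile`.
#' @param x_nm position(s) along the axis.
#' @return numeric values by linear interpolation.
#' @export
profile_value_at <- function(profile, x_nm) {
  stats::approx(profile$position_nm, profile$intensity, xout = x_nm,
                rule = 2)$y
}

#' Exclusion-zone call and FWHM from an axis profile
#'
#' A protein is called excluded if the normalized intensity at the SPB
#' positions falls below `threshold` (the threshold is anchored to the
#' value observed in no-exclusion random simulations). For excluded
#' profiles an inverted Gaussian with constant baseline is fitted over the
#' central window and the zone size reported as FWHM = 2.355 x SD with a
#' 95% CI from the fit covariance.
#'
#' @param profile a normalized `spa_profile`.
#' @param threshold exclusion call threshold.
#' @param spb_x_nm positions of the two SPBs along the axis (nm); the call
#'   uses the smaller of the two profile values there.
#' @param fit_half_nm half width of the central fitting window (nm).
#' @return list of class `exclusion_result`: `excluded`, `fit`
#'   (a `gaussian_fit` or NULL), `spb_intensity`, `min_intensity`,
#'   `threshold`.
#' @export
exclusion_fwhm <- function(profile, threshold = 0.8, spb_x_nm = c(-90, 90),
                           fit_half_nm = 300) {
  stopifnot(isTRUE(profile$normalized))
  at_spb <- min(profile_value_at(profile, spb_x_nm))
  excluded <- at_spb < threshold
  fit <- NULL
  if (excluded) {
    sel <- abs(profile$position_nm) <= fit_half_nm
    fit <- fit_gaussian_1d(profile$position_nm[sel], profile$intensity[sel],
                           inverted = TRUE)
  }
  structure(list(excluded = excluded, fit = fit, spb_intensity = at_spb,
                 min_intensity = min(profile$intensity), threshold = threshold),
            class = "exclusion_result")
}

#' Compare SPB-proximal and SPB-distal focus intensities
#'
#' Partitions foci by their minimum 3D distance to either fitted SPB
#' centre (proximal: distance < `radius_nm`), normalizes intensities by the
#' grand mean, and compares the two groups with a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction).
#'
#' @param foci a `foci_set` with intensities.
#' @param pair a converged `spb_pair` in the same frame.
#' @param radius_nm proximal radius.
#' @return list of class `proximal_distal_result`: group sizes, mean
#'   normalized intensities, `p_value`, `statistic` and `flagged`
#'   (TRUE when a group is empty; statistics are then NA).
#' @export
proximal_distal <- function(foci, pair, radius_nm = 100) {
  stopifnot(isTRUE(pair$converged))
  xyz <- foci_coords(foci)
  dm <- sqrt(rowSums(sweep(xyz, 2, pair$mother_nm)^2))
  dd <- sqrt(rowSums(sweep(xyz, 2, pair$daughter_nm)^2))
  dmin <- pmin(dm, dd)
  ints <- foci$intensities / mean(foci$intensities)
  prox <- ints[dmin < radius_nm]
  dist <- ints[dmin >= radius_nm]
  flagged <- length(prox) == 0 || length(dist) == 0
  if (flagged) {
    p <- NA_real_; w <- NA_real_
  } else {
    wt <- stats::wilcox.test(prox, dist, alternative = "two.sided", exact = FALSE)
    p <- wt$p.value; w <- unname(wt$statistic)
  }
  structure(list(n_proximal = length(prox), n_distal = length(dist),
                 mean_proximal = if (length(prox)) mean(prox) else NA_real_,
                 mean_distal = if (length(dist)) mean(dist) else NA_real_,
                 p_value = p, statistic = w, flagged = flagged,
                 radius_nm = radius_nm),
            class = "proximal_distal_result")
}
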