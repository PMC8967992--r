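#' Spot-detection parameters
#'
#' Defaults reproduce the standard 3D-SIM geometry at 40 nm pixels /
#' 125 nm z-steps: the iterative detector stops at 25% of the original
#' image maximum and masks a spheroid of 8 pixels (320 nm) lateral diameter
#' and 5 slices (625 nm) axial extent around each recorded maximum.
#'
#' @param frac_threshold stop fraction of the original image maximum.
#' @param mask_diameter_px lateral spheroid diameter in pixels.
#' @param mask_slices axial spheroid extent in z-slices.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(frac_threshold = 0.25, mask_diameter_px = 8,
                             mask_slices = 5) {
  if (frac_threshold <= 0 || frac_threshold >= 1)
    stop("frac_threshold must be in (0, 1)")
  stopifnot(mask_diameter_px >= 1, mask_slices >= 1)
  structure(list(frac_threshold = frac_threshold,
                 mask_diameter_px = mask_diameter_px,
                 mask_slices = mask_slices),
            class = "detection_params")
}

#' Segment nuclei in a maximum-intensity projection
#'
#' Local mean thresholding (window about twice the expected nucleus
#' diameter), hole filling, connected components and an area filter.
#' Watershed splitting of touching nuclei is not attempted; instead,
#' user-supplied ROI polygons can add missed nuclei or remove bad masks
#' (semi-automated curation).
#'
#' @param projection 2D matrix (y, x), typically from [max_project()].
#' @param pixel_nm lateral pixel size (nm).
#' @param window_nm local-mean window (nm); default twice a typical
#'   interphase nucleus diameter.
#' @param offset threshold offset above the local mean; default
#'   `3 * mad(projection)` (robust to the sparse bright foreground).
#' @param min_area_um2 minimum accepted mask area.
#' @param close_nm diameter of the disc used for morphological closing
#'   before hole filling; bridges the gaps between punctate NPC signal
#'   (about the typical inter-NPC spacing).
#' @param roi_add list of polygons (k x 2 pixel coordinates) to add as masks.
#' @param roi_remove list of polygons; auto masks whose centroid falls
#'   inside any of them are dropped.
#' @return list of `nucleus_mask` objects (fields: `mask` full-size logical
#'   matrix, `bbox` = c(y0, y1, x0, x1), `area_px`, `centroid_px`,
#'   `provenance`).
#' @export
segment_nuclei <- function(projection, pixel_nm, window_nm = 5000,
                           offset = NULL, min_area_um2 = 0.5, close_nm = 450,
                           roi_add = NULL, roi_remove = NULL) {
  stopifnot(is.matrix(projection), pixel_nm > 0)
  if (is.null(offset)) offset <- 3 * stats::mad(projection)
  w <- max(3L, round(window_nm / pixel_nm))
  w <- min(w, min(dim(projection)))  # window cannot exceed the image
  if (w %% 2 == 0) w <- w - 1L
  kern <- matrix(1 / w^2, w, w)
  local_mean <- EBImage::filter2(projection, kern, boundary = "replicate")
  binary <- projection > local_mean + offset
  if (!any(binary)) {
    masks <- list()
  } else {
    bs <- 2L * floor(close_nm / pixel_nm / 2) + 1L
    closed <- if (bs >= 3L)
      EBImage::closing(EBImage::Image(binary * 1), EBImage::makeBrush(bs, "disc"))
    else EBImage::Image(binary * 1)
    filled <- EBImage::fillHull(closed)
    labels <- EBImage::bwlabel(filled)
    lab <- as.integer(round(EBImage::imageData(labels)))
    dim(lab) <- dim(projection)
    min_area_px <- min_area_um2 * 1e6 / pixel_nm^2
    masks <- list()
    for (l in setdiff(sort(unique(as.vector(lab))), 0L)) {
      m <- lab == l
      if (sum(m) < min_area_px) next
      masks[[length(masks) + 1L]] <- new_nucleus_mask(m, "auto")
    }
  }
  if (!is.null(roi_remove) && length(masks)) {
    keep <- vapply(masks, function(mk) {
      ctr <- matrix(mk$centroid_px[c("x", "y")], 1)
      !any(vapply(roi_remove, function(poly)
        point_in_polygon(ctr, as.matrix(poly)), logical(1)))
    }, logical(1))
    masks <- masks[keep]
    for (i in seq_along(masks))
      if (masks[[i]]$provenance == "auto" && !all(keep))
        masks[[i]]$provenance <- "auto"
  }
  if (!is.null(roi_add)) {
    for (poly in roi_add) {
      m <- rasterize_polygon(as.matrix(poly), dim(projection))
      if (any(m)) masks[[length(masks) + 1L]] <- new_nucleus_mask(m, "manual-added")
    }
  }
  masks
}

new_nucleus_mask <- function(m, provenance) {
  idx <- which(m, arr.ind = TRUE)
  structure(list(mask = m,
                 bbox = c(y0 = min(idx[, 1]), y1 = max(idx[, 1]),
                          x0 = min(idx[, 2]), x1 = max(idx[, 2])),
                 area_px = nrow(idx),
                 centroid_px = c(x = mean(idx[, 2]), y = mean(idx[, 1])),
                 provenance = provenance),
            class = "nucleus_mask")
}

# even-odd test via mgcv's in/out routine
point_in_polygon <- function(pts, poly) {
  as.logical(mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                          matrix(as.numeric(pts), ncol = 2)))
}

rasterize_polygon <- function(poly, dims) {
  ys <- seq_len(dims[1]); xs <- seq_len(dims[2])
  grid <- cbind(rep(xs, each = dims[1]), rep(ys, dims[2]))
  inside <- point_in_polygon(grid, poly)
  matrix(inside, dims[1], dims[2])
}

#' Detect foci by iterative maximum tracking with spheroid masking
#'
#' "Track max, not mask": find the brightest voxel, record it, zero a
#' spheroid (lateral diameter `mask_diameter_px`, axial extent
#' `mask_slices`, ellipsoidal inclusion in voxel units) centred on it, and
#' repeat while the next maximum is at least `frac_threshold` times the
#' ORIGINAL image maximum (computed once, before any masking). Coordinates
#' are voxel centres in nm in the full-volume frame.
#'
#' @param volume a [volume_image()].
#' @param mask optional `nucleus_mask`; the volume is cropped to its
#'   bounding box and the mask applied laterally.
#' @param params a [detection_params()].
#' @param max_foci safety cap on iterations.
#' @return an object of class `foci_set` with `coordinates` (data.frame
#'   x_nm, y_nm, z_nm), `intensities` (peak voxel values), calibration and
#'   the source channel.
#' @export
detect_foci <- function(volume, mask = NULL, params = detection_params(),
                        max_foci = 10000L) {
  v <- volume$voxels
  off_yx <- c(0L, 0L)
  if (!is.null(mask)) {
    bb <- mask$bbox
    v <- v[bb["y0"]:bb["y1"], bb["x0"]:bb["x1"], , drop = FALSE]
    m <- mask$mask[bb["y0"]:bb["y1"], bb["x0"]:bb["x1"]]
    v <- v * array(as.numeric(m), dim = dim(v))
    off_yx <- c(bb["y0"] - 1L, bb["x0"] - 1L)
  }
  d <- dim(v)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  M0 <- max(v)
  empty <- structure(list(coordinates = data.frame(x_nm = numeric(0),
                                                   y_nm = numeric(0),
                                                   z_nm = numeric(0)),
                          intensities = numeric(0),
                          pixel_nm = volume$pixel_nm, zstep_nm = volume$zstep_nm,
                          source = volume$channel),
                     class = "foci_set")
  if (M0 <= 0) return(empty)
  thr <- params$frac_threshold * M0
  rx <- params$mask_diameter_px / 2
  rz <- params$mask_slices / 2
  dmax_x <- floor(rx); dmax_z <- floor((params$mask_slices - 1) / 2)
  offs <- expand.grid(dy = -dmax_x:dmax_x, dx = -dmax_x:dmax_x, dz = -dmax_z:dmax_z)
  offs <- offs[(offs$dx / rx)^2 + (offs$dy / rx)^2 + (offs$dz / rz)^2 <= 1, ]
  iy0 <- offs$dy; ix0 <- offs$dx; iz0 <- offs$dz
  res_i <- integer(0); res_val <- numeric(0)
  repeat {
    m <- which.max(v)
    val <- v[m]
    if (val < thr || val <= 0 || length(res_i) >= max_foci) break
    res_i <- c(res_i, m); res_val <- c(res_val, val)
    m0 <- m - 1L
    iy <- m0 %% ny + 1L
    ix <- (m0 %/% ny) %% nx + 1L
    iz <- m0 %/% (ny * nx) + 1L
    yy <- iy + iy0; xx <- ix + ix0; zz <- iz + iz0
    ok <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx & zz >= 1L & zz <= nz
    v[(zz[ok] - 1L) * (ny * nx) + (xx[ok] - 1L) * ny + yy[ok]] <- -Inf
  }
  if (!length(res_i)) return(empty)
  m0 <- res_i - 1L
  iy <- m0 %% ny + 1L + off_yx[1]
  ix <- (m0 %/% ny) %% nx + 1L + off_yx[2]
  iz <- m0 %/% (ny * nx) + 1L
  structure(list(coordinates = data.frame(x_nm = (ix - 0.5) * volume$pixel_nm,
                                          y_nm = (iy - 0.5) * volume$pixel_nm,
                                          z_nm = (iz - 0.5) * volume$zstep_nm),
                 intensities = res_val,
                 pixel_nm = volume$pixel_nm, zstep_nm = volume$zstep_nm,
                 source = volume$channel),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> %d foci (%s)\n", nrow(x$coordinates),
              if (is.null(x$source)) "unlabelled" else x$source))
  invisible(x)
}

#' Fit a 1D Gaussian to the lateral intensity profile through a focus
#'
#' Extracts the x-line profile through the voxel nearest the focus and fits
#' a Gaussian with constant baseline; used for single-NPC apparent size.
#'
#' @param volume a [volume_image()].
#' @param focus_nm length-3 numeric (x, y, z) in nm.
#' @param halfwidth_px profile half width in pixels.
#' @return a `gaussian_fit` (see [fit_gaussian_1d()]); non-convergent fits
#'   are flagged with `converged = FALSE`.
#' @export
fit_focus_profile <- function(volume, focus_nm, halfwidth_px = 8) {
  d <- dim(volume$voxels)
  idx <- nm_to_voxel(matrix(as.numeric(focus_nm[1:3]), 1), volume$pixel_nm,
                     volume$zstep_nm)
  iy <- round(idx[1, "iy"]); ix <- round(idx[1, "ix"]); iz <- round(idx[1, "iz"])
  if (iy < 1 || iy > d[1] || ix < 1 || ix > d[2] || iz < 1 || iz > d[3])
    stop("focus outside volume")
  xs <- max(1, ix - halfwidth_px):min(d[2], ix + halfwidth_px)
  y <- volume$voxels[iy, xs, iz]
  x <- (xs - 0.5) * volume$pixel_nm
  fit_gaussian_1d(x, y)
}

#' Per-nucleus summary record
#'
#' Density is count / hull surface area. By default the count uses ALL
#' detected foci, including any removed by the hull optimizer (removed
#' points model noise in the surface fit, not rejected detections); set
#' `count_retained_only = TRUE` to count only hull-retained foci.
#'
#' @param foci a `foci_set`.
#' @param hull the matching [fit_hull()] result.
#' @param intensity_per_area optional scalar from [intensity_per_area()].
#' @param stage optional stage label.
#' @param count_retained_only see above.
#' @return one-row data.frame: `npc_count`, `surface_area_um2`,
#'   `volume_um3`, `density_per_um2`, `intensity_per_area`, `stage`.
#' @export
summarize_nucleus <- function(foci, hull, intensity_per_area = NA_real_,
                              stage = NA_character_,
                              count_retained_only = FALSE) {
  n <- nrow(foci$coordinates)
  count <- if (count_retained_only) length(hull$retained) else n
  data.frame(row.names = NULL,
             npc_count = count,
             surface_area_um2 = hull$surface_area_um2,
             volume_um3 = hull$volume_um3,
             density_per_um2 = count / hull$surface_area_um2,
             intensity_per_area = intensity_per_area,
             stage = stage)
}

#' Two-channel co-detection of foci
#'
#' A focus in one channel is co-detected if any focus of the other channel
#' lies within `radius_nm` (many-to-one matching allowed). Fractions are
#' reported per channel; an empty channel yields `NA` (undefined), not zero.
#'
#' @param foci_a,foci_b `foci_set` objects (or n x 3 coordinate matrices)
#'   in a common frame.
#' @param radius_nm co-detection radius.
#' @return list of class `codetect_result`: `fraction_a`, `fraction_b`,
#'   `pairs_a` (for each focus of A, index of the nearest focus of B within
#'   the radius, else NA), `pairs_b`, `n_a`, `n_b`, `radius_nm`.
#' @export
codetect <- function(foci_a, foci_b, radius_nm = 250) {
  A <- foci_coords_or_empty(foci_a)
  B <- foci_coords_or_empty(foci_b)
  na <- nrow(A); nb <- nrow(B)
  out <- list(fraction_a = NA_real_, fraction_b = NA_real_,
              pairs_a = rep(NA_integer_, na), pairs_b = rep(NA_integer_, nb),
              n_a = na, n_b = nb, radius_nm = radius_nm)
  if (na > 0 && nb > 0) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    d <- sqrt(pmax(d2, 0))
    near_a <- apply(d, 1, which.min)
    near_b <- apply(d, 2, which.min)
    hit_a <- d[cbind(seq_len(na), near_a)] <= radius_nm
    hit_b <- d[cbind(near_b, seq_len(nb))] <= radius_nm
    out$pairs_a <- ifelse(hit_a, near_a, NA_integer_)
    out$pairs_b <- ifelse(hit_b, near_b, NA_integer_)
    out$fraction_a <- mean(hit_a)
    out$fraction_b <- mean(hit_b)
  }
  structure(out, class = "codetect_result")
}

foci_coords_or_empty <- function(x) {
  if (inherits(x, "foci_set") && nrow(x$coordinates) == 0)
    return(matrix(numeric(0), 0, 3))
  foci_coords(x)
}

#' Intensity per unit nuclear surface area
#'
#' Sum-projects a raw (non-reconstructed or simulated) stack, subtracts a
#' background level, integrates over the nucleus mask and divides by the
#' hull surface area. Provides a segmentation-free proxy for NPC density.
#'
#' @param raw_volume a [volume_image()].
#' @param mask a `nucleus_mask`.
#' @param surface_area_um2 hull surface area of the same nucleus.
#' @param background background level per projected pixel; default is the
#'   median of the sum projection outside the mask.
#' @return scalar intensity per um^2.
#' @export
intensity_per_area <- function(raw_volume, mask, surface_area_um2,
                               background = NULL) {
  if (!is.finite(surface_area_um2) || surface_area_um2 <= 0)
    stop("surface_area_um2 must be > 0")
  sp <- sum_project(raw_volume)
  if (is.null(background))
    background <- if (all(mask$mask)) 0 else stats::median(sp[!mask$mask])
  sum(sp[mask$mask] - background) / surface_area_um2
}
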