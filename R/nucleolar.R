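#' Extract a two-channel line profile along a traced nuclear envelope
#'
#' Samples both channels along a polyline (an NE trace) with a band of
#' `width_px` perpendicular to the local tangent, averaging across the
#' band. Arc-length positions are returned in nm. A polyline whose band
#' samples leave the image is an error.
#'
#' @param nup_img,marker_img 2D matrices (y, x), e.g. sum projections of
#'   the Nup and nucleolar-marker channels.
#' @param polyline k x 2 matrix of (x, y) pixel coordinates; a closed trace
#'   repeats its first vertex at the end.
#' @param width_px band width (pixels, >= 1).
#' @param pixel_nm lateral pixel size.
#' @param id profile identifier.
#' @return an `ne_profile_pair`: `positions_nm` (arc length), `nup`,
#'   `marker`, `closed`, `circumference_nm` (closed traces), `id`.
#' @export
extract_profile_pair <- function(nup_img, marker_img, polyline, width_px = 3,
                                 pixel_nm = 40, id = NULL) {
  stopifnot(is.matrix(nup_img), all(dim(nup_img) == dim(marker_img)),
            width_px >= 1)
  poly <- as.matrix(polyline)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 2)
  closed <- sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) < 1e-6
  seglen <- sqrt(rowSums(diff(poly)^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  n_samp <- max(2L, ceiling(total))  # ~1 px steps
  s <- seq(0, total, length.out = n_samp + 1L)
  if (closed) s <- s[-length(s)]  # avoid duplicating the seam point
  sx <- stats::approx(arc, poly[, 1], xout = s)$y
  sy <- stats::approx(arc, poly[, 2], xout = s)$y
  # tangents by central differences (wrapping when closed)
  k <- length(s)
  ip <- if (closed) c(2:k, 1L) else c(2:k, k)
  im <- if (closed) c(k, 1:(k - 1L)) else c(1L, 1:(k - 1L))
  tx <- sx[ip] - sx[im]; ty <- sy[ip] - sy[im]
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  nxv <- -ty / tl; nyv <- tx / tl
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, by = 1)
  acc_nup <- numeric(k); acc_mk <- numeric(k)
  dims <- dim(nup_img)
  for (o in offs) {
    px_x <- sx + o * nxv; px_y <- sy + o * nyv
    if (any(px_x < 0.5 | px_x > dims[2] + 0.5 | px_y < 0.5 | px_y > dims[1] + 0.5))
      stop("profile band leaves the image")
    w <- bilinear_weights(px_x, px_y, dims[1], dims[2])
    acc_nup <- acc_nup + as.vector(bilinear_apply(nup_img, w, 1, k))
    acc_mk <- acc_mk + as.vector(bilinear_apply(marker_img, w, 1, k))
  }
  structure(list(positions_nm = s * pixel_nm,
                 nup = acc_nup / length(offs), marker = acc_mk / length(offs),
                 closed = closed,
                 circumference_nm = if (closed) total * pixel_nm else NA_real_,
                 id = id),
            class = "ne_profile_pair")
}

#' Align NE profile pairs at the nucleolar-marker peak and average
#'
#' Per nucleus: boxcar-smooth the marker profile, threshold at half of its
#' maximum, take the (longest) above-threshold run and define its circular
#' midpoint as the peak centre; shift arc positions so the centre maps to
#' 0; normalize the Nup profile by its mean over the arc OUTSIDE the
#' marker run (dilated by `dilate_steps` samples); resample onto a common
#' uniform grid by linear interpolation; average across nuclei. Nuclei
#' with no above-threshold marker run are dropped with a logged reason.
#'
#' @param pairs list of `ne_profile_pair` objects.
#' @param boxcar_w boxcar width in samples (odd recommended).
#' @param grid_nm common grid spacing; default the median sample spacing of
#'   the first profile.
#' @param dilate_steps samples added to each side of the marker run before
#'   defining the normalization region.
#' @return an `aligned_profile_set`: `position_nm` grid (0 at the marker
#'   centre), `profiles` (nuclei x grid matrix of normalized Nup
#'   intensity), `mean`, `sd`, `n`, `dropped` (named reasons).
#' @export
align_and_average <- function(pairs, boxcar_w = 5, grid_nm = NULL,
                              dilate_steps = 2) {
  stopifnot(length(pairs) >= 1)
  if (is.null(grid_nm))
    grid_nm <- stats::median(diff(pairs[[1]]$positions_nm))
  half_span <- min(vapply(pairs, function(p) {
    if (isTRUE(p$closed)) p$circumference_nm / 2 else diff(range(p$positions_nm)) / 2
  }, numeric(1)))
  ngrid <- floor((half_span - grid_nm) / grid_nm)
  grid <- seq(-ngrid, ngrid) * grid_nm
  rows <- list(); dropped <- character(0)
  ids <- vapply(seq_along(pairs), function(i) {
    id <- pairs[[i]]$id
    if (is.null(id)) paste0("nucleus_", i) else as.character(id)
  }, character(1))
  ids <- make.unique(ids)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    id <- ids[i]
    k <- length(p$marker)
    sm <- boxcar_smooth(p$marker, boxcar_w, circular = isTRUE(p$closed))
    thr <- max(sm) / 2
    above <- sm > thr
    if (!any(above) || all(above) || max(sm) <= 0) {
      dropped[id] <- "no defined marker peak (no half-max crossing)"
      next
    }
    run <- longest_run(above, circular = isTRUE(p$closed))
    mid_idx <- run$start + (run$length - 1) / 2
    mid_idx <- ((mid_idx - 1) %% k) + 1  # circular index in [1, k+1)
    i0 <- floor(mid_idx); fr <- mid_idx - i0
    if (i0 < k) {
      center_pos <- (1 - fr) * p$positions_nm[i0] + fr * p$positions_nm[i0 + 1]
    } else {  # wraps past the seam (closed traces)
      nxt <- if (isTRUE(p$closed)) p$positions_nm[1] + p$circumference_nm
      else p$positions_nm[k]
      center_pos <- (1 - fr) * p$positions_nm[k] + fr * nxt
    }
    pos <- p$positions_nm - center_pos
    if (isTRUE(p$closed)) {
      C <- p$circumference_nm
      pos <- ((pos + C / 2) %% C) - C / 2
    }
    # normalization region: outside the dilated marker run
    in_run <- logical(k)
    idx <- (run$start - 1 - dilate_steps):(run$start - 1 + run$length + dilate_steps - 1)
    in_run[(idx %% k) + 1] <- TRUE
    if (all(in_run)) {
      dropped[id] <- "marker run covers the whole profile"
      next
    }
    ref <- mean(p$nup[!in_run])
    if (!is.finite(ref) || ref <= 0) {
      dropped[id] <- "non-positive normalization reference"
      next
    }
    nup_n <- p$nup / ref
    ord <- order(pos)
    xs <- pos[ord]; ys <- nup_n[ord]
    if (isTRUE(p$closed)) {  # pad the seam so interpolation wraps
      C <- p$circumference_nm
      xs <- c(xs[length(xs)] - C, xs, xs[1] + C)
      ys <- c(ys[length(ys)], ys, ys[1])
    }
    rows[[id]] <- stats::approx(xs, ys, xout = grid)$y
  }
  if (!length(rows)) stop("all nuclei dropped: no usable marker profiles")
  profiles <- do.call(rbind, rows)
  structure(list(position_nm = grid, profiles = profiles,
                 mean = colMeans(profiles),
                 sd = apply(profiles, 2, stats::sd),
                 n = nrow(profiles), dropped = dropped),
            class = "aligned_profile_set")
}

boxcar_smooth <- function(x, w, circular = FALSE) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  if (circular) {
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE))
  } else {
    k <- length(x)
    h <- (w - 1) %/% 2
    pad <- c(rep(x[1], h), x, rep(x[k], w - 1 - h))
    as.numeric(stats::filter(pad, rep(1 / w, w), sides = 2))[(h + 1):(h + k)]
  }
}

# longest run of TRUE, optionally treating the vector as circular;
# returns start index and length (start in 1..k, may wrap)
longest_run <- function(x, circular = FALSE) {
  k <- length(x)
  xx <- if (circular) c(x, x) else x
  r <- rle(xx)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  if (circular) {
    cand <- cand[starts[cand] <= k]
    r$lengths[cand] <- pmin(r$lengths[cand], k)
  }
  best <- cand[which.max(r$lengths[cand])]
  list(start = starts[best], length = min(r$lengths[best], k))
}

#' Normalized Nup intensity at the nucleolar centre
#'
#' The mean (over nuclei) of the aligned, normalized Nup profile at grid
#' position 0 (the centre of the nucleolar-marker peak), with the SD
#' across nuclei. A value of 1 means no reduction relative to the NE
#' outside the nucleolus.
#'
#' @param aligned an `aligned_profile_set`.
#' @return list: `value`, `sd`, `n`.
#' @export
nup_reduction_at_center <- function(aligned) {
  if (!aligned$n) stop("empty aligned profile set")
  j0 <- which(abs(aligned$position_nm) < 1e-9)
  stopifnot(length(j0) == 1)
  list(value = aligned$mean[j0], sd = aligned$sd[j0], n = aligned$n)
}
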