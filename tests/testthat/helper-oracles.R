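# Independent oracles used to validate the implementation.

# Brute-force 3D convex hull by facet enumeration: a triple is a hull facet
# iff every other point lies on one side of its plane. O(n^4); intended for
# n <= ~25 points in generic position. Returns surface area and volume.
bf_hull_area_volume <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  tol <- tol * scale
  area <- 0; volume <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn < tol) next
    d <- as.vector(sweep(pts[-c(i, j, k), , drop = FALSE], 2, a) %*% nrm)
    if (all(d <= tol)) {
      outward <- nrm
    } else if (all(d >= -tol)) {
      outward <- -nrm
    } else next
    area <- area + nn / 2
    v6 <- a[1] * (b[2] * c[3] - b[3] * c[2]) -
      a[2] * (b[1] * c[3] - b[3] * c[1]) +
      a[3] * (b[1] * c[2] - b[2] * c[1])
    # orient the tetra (origin, a, b, c) consistently with the outward normal
    sgn <- if (sum(outward * nrm) > 0) 1 else -1
    volume <- volume + sgn * v6 / 6
  }
  list(area = area, volume = abs(volume))
}

# Exhaustive search over all removal subsets of size <= cap, maximizing the
# on-surface fraction of the remaining points (same membership rule as
# fit_hull: hull vertex or within eps_nm of a facet).
bf_best_removal_fraction <- function(pts, cap, eps_nm = 20) {
  n <- nrow(pts)
  frac_of <- function(keep) {
    h <- convex_hull_3d(pts[keep, , drop = FALSE])
    depth <- hull_depth(pts[keep, , drop = FALSE], h)
    on <- seq_along(keep) %in% h$vertices | depth <= eps_nm
    mean(on)
  }
  best <- frac_of(seq_len(n))
  for (k in seq_len(cap)) {
    combs <- utils::combn(n, k)
    for (ci in seq_len(ncol(combs))) {
      keep <- setdiff(seq_len(n), combs[, ci])
      if (length(keep) >= 4) {
        f <- tryCatch(frac_of(keep), error = function(e) NA_real_)
        if (is.finite(f)) best <- max(best, f)
      }
    }
  }
  best
}

# uniform points on a sphere (no spacing constraint), seeded
sphere_points <- function(n, r, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2)) * r
}

rotate_z <- function(pts, angle) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  pts %*% R
}

# minimal converged spb_pair object for tests that need only geometry
fake_pair <- function(mother, daughter) {
  structure(list(mother_nm = mother, daughter_nm = daughter,
                 separation_nm = sqrt(sum((mother - daughter)^2)),
                 converged = TRUE),
            class = "spb_pair")
}

# foci_set from a coordinate matrix (+ optional intensities)
make_foci <- function(xyz, intensities = NULL, pixel_nm = 40, zstep_nm = 125) {
  xyz <- as.matrix(xyz)
  structure(list(coordinates = data.frame(x_nm = xyz[, 1], y_nm = xyz[, 2],
                                          z_nm = xyz[, 3]),
                 intensities = if (is.null(intensities)) rep(1, nrow(xyz))
                 else intensities,
                 pixel_nm = pixel_nm, zstep_nm = zstep_nm, source = "test"),
            class = "foci_set")
}
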