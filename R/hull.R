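#' 3D convex hull by incremental insertion
#'
#' Computes the convex hull of a 3D point cloud with consistently outward
#' oriented triangular facets, total surface area and enclosed volume.
#' Written for the modest point counts of per-nucleus NPC sets (tens to a
#' few hundred points).
#'
#' @param pts numeric n x 3 matrix.
#' @param tol visibility tolerance; default scales with the point cloud extent.
#' @return list with `faces` (m x 3 vertex indices, outward oriented),
#'   `vertices` (sorted unique vertex indices), `normals` (m x 3 outward unit
#'   normals), `offsets` (m plane offsets, `normals[f,] %*% v = offsets[f]`
#'   on facet f), `area` and `volume` (in the squared / cubed input units).
#' @export
convex_hull_3d <- function(pts, tol = NULL) {
  pts <- as.matrix(pts)
  dimnames(pts) <- NULL
  stopifnot(ncol(pts) == 3, is.numeric(pts))
  n <- nrow(pts)
  if (n < 4) stop("convex hull needs at least 4 points")
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1)
  if (is.null(tol)) tol <- 1e-9 * scale

  # --- initial non-degenerate tetrahedron ---
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (d1[i2] <= tol^2) stop("degenerate input: all points coincide")
  ab <- pts[i2, ] - pts[i1, ]
  ap <- sweep(pts, 2, pts[i1, ])
  crs <- cbind(ap[, 2] * ab[3] - ap[, 3] * ab[2],
               ap[, 3] * ab[1] - ap[, 1] * ab[3],
               ap[, 1] * ab[2] - ap[, 2] * ab[1])
  dline <- rowSums(crs^2)
  i3 <- which.max(dline)
  if (dline[i3] <= (tol * sqrt(sum(ab^2)))^2) stop("degenerate input: points are collinear")
  nrm <- crossp(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  dplane <- abs(ap %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] <= tol) stop("degenerate input: points are coplanar")

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(pts[c(i1, i2, i3, i4), ])
  for (f in 1:4) {  # orient outward w.r.t. tetra centroid
    v <- faces[f, ]
    nn <- crossp(pts[v[2], ] - pts[v[1], ], pts[v[3], ] - pts[v[1], ])
    if (sum(nn * (ctr - pts[v[1], ])) > 0) faces[f, ] <- v[c(1, 3, 2)]
  }

  # --- incremental insertion ---
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    m <- nrow(faces)
    vis <- logical(m)
    for (f in seq_len(m)) {
      v <- faces[f, ]
      nn <- crossp(pts[v[2], ] - pts[v[1], ], pts[v[3], ] - pts[v[1], ])
      nn <- nn / sqrt(sum(nn^2))
      vis[f] <- sum(nn * (pts[p, ] - pts[v[1], ])) > tol
    }
    if (!any(vis)) next
    # horizon: directed edges of visible faces whose reverse lies in a kept face
    vf <- faces[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rev_keys %in% keys), , drop = FALSE]
    faces <- rbind(faces[!vis, , drop = FALSE],
                   cbind(horizon[, 1], horizon[, 2], p))
  }

  # --- facet geometry ---
  m <- nrow(faces)
  normals <- matrix(0, m, 3)
  offsets <- numeric(m)
  area <- 0
  volume <- 0
  for (f in seq_len(m)) {
    v0 <- pts[faces[f, 1], ]; v1 <- pts[faces[f, 2], ]; v2 <- pts[faces[f, 3], ]
    cr <- crossp(v1 - v0, v2 - v0)
    a <- sqrt(sum(cr^2))
    area <- area + a / 2
    volume <- volume + (v0[1] * (v1[2] * v2[3] - v1[3] * v2[2]) -
                          v0[2] * (v1[1] * v2[3] - v1[3] * v2[1]) +
                          v0[3] * (v1[1] * v2[2] - v1[2] * v2[1])) / 6
    if (a > 0) {
      normals[f, ] <- cr / a
      offsets[f] <- sum(normals[f, ] * v0)
    }
  }
  list(faces = faces, vertices = sort(unique(as.vector(faces))),
       normals = normals, offsets = offsets, area = area, volume = volume)
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Signed interior depth of points relative to a hull
#'
#' For each point, the minimum over facets of the plane distance
#' (offset - normal . p). For points inside a convex polytope this equals
#' the exact distance to the hull surface; it is negative outside.
#'
#' @param pts n x 3 matrix.
#' @param hull result of [convex_hull_3d()].
#' @return numeric vector of depths.
#' @export
hull_depth <- function(pts, hull) {
  pts <- as.matrix(pts)
  d <- sweep(-pts %*% t(hull$normals), 2, hull$offsets, `+`)
  apply(d, 1, min)
}

#' Fit the nuclear envelope as an outlier-tolerant convex hull
#'
#' Computes the convex hull of detected NPC positions, then removes, one at
#' a time, the interior point lying deepest inside the hull (ties broken by
#' lowest index), as long as removal increases the fraction of points on the
#' hull surface, up to `floor(max_removal_frac * n)` removals. A point
#' counts as on the surface if it is a hull vertex or within `eps_nm` of a
#' hull facet. Since removing a strictly interior point leaves the facets
#' unchanged and always raises the on-surface fraction, the greedy pass
#' reduces to removing the deepest off-surface points up to the cap;
#' equivalence with exhaustive subset search is exercised in the test suite.
#'
#' @param foci a `foci_set` (see [detect_foci()]), a `foci_truth`, or an
#'   n x 3 coordinate matrix in nm.
#' @param max_removal_frac maximum fraction of points that may be removed.
#' @param eps_nm facet-distance tolerance for on-surface membership
#'   (default half a pixel at the standard 40 nm calibration).
#' @return an object of class `hull_result` with retained / removed indices,
#'   hull vertex indices (into the input), `surface_area_um2`, `volume_um3`,
#'   `on_hull_fraction` (final) and `on_hull_fraction_initial`.
#' @export
fit_hull <- function(foci, max_removal_frac = 0.10, eps_nm = 20) {
  pts <- foci_coords(foci)
  n <- nrow(pts)
  if (n < 4) stop(sprintf("hull fit needs >= 4 points, got %d", n))
  hull <- convex_hull_3d(pts)
  depth <- hull_depth(pts, hull)
  is_vertex <- seq_len(n) %in% hull$vertices
  on_surface <- is_vertex | depth <= eps_nm
  frac0 <- mean(on_surface)
  off <- which(!on_surface)
  cap <- floor(max_removal_frac * n)
  removed <- integer(0)
  if (length(off) && cap > 0) {
    ord <- off[order(-depth[off], off)]
    removed <- ord[seq_len(min(length(ord), cap))]
  }
  retained <- setdiff(seq_len(n), removed)
  final <- convex_hull_3d(pts[retained, , drop = FALSE])
  fdepth <- hull_depth(pts[retained, , drop = FALSE], final)
  fvert <- seq_along(retained) %in% final$vertices
  fon <- fvert | fdepth <= eps_nm
  structure(list(
    retained = retained, removed = removed,
    hull_vertices = retained[final$vertices],
    faces = matrix(retained[final$faces], ncol = 3),
    surface_area_um2 = final$area / 1e6,
    volume_um3 = final$volume / 1e9,
    on_hull_fraction = mean(fon),
    on_hull_fraction_initial = frac0,
    eps_nm = eps_nm, n_points = n),
    class = "hull_result")
}

#' @export
print.hull_result <- function(x, ...) {
  cat(sprintf("<hull_result> %d points (%d removed), SA %.3f um^2, V %.3f um^3, on-hull %.2f\n",
              x$n_points, length(x$removed), x$surface_area_um2, x$volume_um3,
              x$on_hull_fraction))
  invisible(x)
}

# coordinate extraction shared by hull / co-detection / SPA helpers
foci_coords <- function(foci) {
  if (inherits(foci, "foci_set"))
    return(as.matrix(foci$coordinates[, c("x_nm", "y_nm", "z_nm")]))
  if (inherits(foci, "foci_truth")) return(unname(foci$positions))
  m <- as.matrix(foci)
  stopifnot(ncol(m) == 3)
  unname(m)
}
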