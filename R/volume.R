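#' Calibrated 3D volume
#'
#' Container for a single channel's voxel grid with physical calibration.
#' Voxels are stored as a numeric array with dimensions (y, x, z); the voxel
#' with index (iy, ix, iz) has its centre at physical position
#' ((ix - 0.5) * pixel_nm, (iy - 0.5) * pixel_nm, (iz - 0.5) * zstep_nm),
#' so the volume corner is the coordinate origin.
#'
#' @param voxels numeric 3D array, dimensions (y, x, z).
#' @param pixel_nm lateral voxel size in nm (> 0).
#' @param zstep_nm axial voxel spacing in nm (> 0).
#' @param channel optional channel label.
#' @return an object of class `volume_image`.
#' @export
volume_image <- function(voxels, pixel_nm, zstep_nm, channel = NULL) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3L, is.numeric(voxels))
  if (!is.finite(pixel_nm) || pixel_nm <= 0 || !is.finite(zstep_nm) || zstep_nm <= 0)
    stop("pixel_nm and zstep_nm must be strictly positive")
  if (any(!is.finite(voxels))) stop("voxel intensities must be finite")
  structure(list(voxels = voxels, pixel_nm = pixel_nm, zstep_nm = zstep_nm,
                 channel = channel),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels (y,x,z), %g nm px, %g nm z-step%s\n",
              d[1], d[2], d[3], x$pixel_nm, x$zstep_nm,
              if (is.null(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

#' Physical centre of a volume (nm)
#'
#' @param vol a `volume_image`.
#' @return numeric length-3 vector (x, y, z) in nm.
#' @export
volume_center_nm <- function(vol) {
  d <- unname(dim(vol$voxels))
  c(x = d[2] / 2 * vol$pixel_nm,
    y = d[1] / 2 * vol$pixel_nm,
    z = d[3] / 2 * vol$zstep_nm)
}

# voxel index (iy, ix, iz) -> physical nm coordinates of voxel centre
voxel_to_nm <- function(idx, pixel_nm, zstep_nm) {
  cbind(x_nm = (idx[, 2] - 0.5) * pixel_nm,
        y_nm = (idx[, 1] - 0.5) * pixel_nm,
        z_nm = (idx[, 3] - 0.5) * zstep_nm)
}

# physical nm -> fractional voxel index (iy, ix, iz)
nm_to_voxel <- function(xyz, pixel_nm, zstep_nm) {
  cbind(iy = xyz[, 2] / pixel_nm + 0.5,
        ix = xyz[, 1] / pixel_nm + 0.5,
        iz = xyz[, 3] / zstep_nm + 0.5)
}

#' Maximum-intensity z-projection
#'
#' @param vol a `volume_image`.
#' @return matrix (y, x).
#' @export
max_project <- function(vol) apply(vol$voxels, c(1, 2), max)

#' Sum z-projection
#'
#' @param vol a `volume_image`.
#' @return matrix (y, x).
#' @export
sum_project <- function(vol) apply(vol$voxels, c(1, 2), sum)
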