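#' Write volumes to a multi-page TIFF with a calibration sidecar
#'
#' Channels are written as consecutive z-major page blocks in one 32-bit
#' TIFF. Because TIFF float pages are stored on [0, 1], intensities are
#' affinely rescaled for storage and the offset/scale recorded, together
#' with the voxel calibration and channel names, in a JSON sidecar
#' (`<path>.json`) that [read_volume()] uses to restore values.
#'
#' @param volumes a [volume_image()] or a named list of them (channels);
#'   all must share dimensions and calibration.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volumes, path) {
  if (inherits(volumes, "volume_image")) volumes <- list(volumes)
  stopifnot(length(volumes) >= 1)
  d <- dim(volumes[[1]]$voxels)
  px <- volumes[[1]]$pixel_nm; zs <- volumes[[1]]$zstep_nm
  for (v in volumes) stopifnot(all(dim(v$voxels) == d),
                               v$pixel_nm == px, v$zstep_nm == zs)
  lo <- min(vapply(volumes, function(v) min(v$voxels), numeric(1)))
  hi <- max(vapply(volumes, function(v) max(v$voxels), numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  pages <- list()
  for (v in volumes)
    for (iz in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- (v$voxels[, , iz] - lo) / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  chn <- names(volumes)
  if (is.null(chn)) chn <- vapply(seq_along(volumes), function(i) {
    ch <- volumes[[i]]$channel
    if (is.null(ch)) paste0("channel_", i) else as.character(ch)
  }, character(1))
  meta <- list(pixel_nm = px, zstep_nm = zs, n_z = d[3],
               channels = chn, offset = lo, scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated volume from TIFF
#'
#' Reads a TIFF stack written by [write_volume()] (calibration and channel
#' layout from the JSON sidecar) or any plain multi-page TIFF, in which
#' case the calibration must be supplied via the overrides.
#'
#' @param path TIFF path.
#' @param pixel_nm,zstep_nm calibration overrides (take precedence over
#'   sidecar values).
#' @param channel channel name or index to extract; `NULL` returns a named
#'   list of all channels (or the single channel directly).
#' @return a [volume_image()] or a named list of them.
#' @export
read_volume <- function(path, pixel_nm = NULL, zstep_nm = NULL, channel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else NULL
  if (is.null(pixel_nm)) pixel_nm <- meta$pixel_nm
  if (is.null(zstep_nm)) zstep_nm <- meta$zstep_nm
  if (is.null(pixel_nm) || is.null(zstep_nm))
    stop("no voxel calibration: supply pixel_nm and zstep_nm ",
         "(no sidecar metadata found at ", sidecar, ")")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  n_z <- if (!is.null(meta$n_z)) meta$n_z else n_pages
  n_ch <- n_pages / n_z
  stopifnot(n_ch == round(n_ch))
  chn <- if (!is.null(meta$channels)) meta$channels else paste0("channel_", seq_len(n_ch))
  offset <- if (!is.null(meta$offset)) meta$offset else 0
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  vols <- list()
  for (ci in seq_len(n_ch)) {
    arr <- array(0, dim = c(dim(pages[[1]]), n_z))
    for (iz in seq_len(n_z))
      arr[, , iz] <- pages[[(ci - 1L) * n_z + iz]] * scale + offset
    vols[[chn[ci]]] <- volume_image(arr, pixel_nm, zstep_nm, channel = chn[ci])
  }
  if (!is.null(channel)) {
    v <- if (is.character(channel)) vols[[channel]] else vols[[as.integer(channel)]]
    if (is.null(v)) stop("channel not found: ", channel)
    return(v)
  }
  if (length(vols) == 1L) vols[[1]] else vols
}

#' Write a foci set to CSV
#'
#' @param foci a `foci_set`.
#' @param path output CSV path.
#' @param config optional configuration list echoed into `# ` header
#'   comments (with a content hash) for provenance.
#' @return `path`, invisibly.
#' @export
write_foci_csv <- function(foci, path, config = NULL) {
  df <- cbind(foci$coordinates, intensity = foci$intensities)
  write_csv_with_header(df, path, config)
}

#' Read a foci set from CSV
#'
#' @param path CSV path (columns x_nm, y_nm, z_nm, intensity).
#' @param pixel_nm,zstep_nm calibration to attach.
#' @return a `foci_set`.
#' @export
read_foci_csv <- function(path, pixel_nm = NA_real_, zstep_nm = NA_real_) {
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(coordinates = df[, c("x_nm", "y_nm", "z_nm")],
                 intensities = if ("intensity" %in% names(df)) df$intensity
                 else rep(NA_real_, nrow(df)),
                 pixel_nm = pixel_nm, zstep_nm = zstep_nm, source = path),
            class = "foci_set")
}

#' Write a CSV with provenance header comments
#'
#' Prepends `# `-prefixed lines carrying the JSON-encoded run configuration
#' and its content hash, so every table records the parameters that
#' produced it. Read back with `read.csv(..., comment.char = "#")`.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config optional configuration list (e.g. [run_config()]).
#' @return `path`, invisibly.
#' @export
write_csv_with_header <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
    writeLines(sprintf("# config_hash: %s", json_hash(js)), con)
    writeLines(sprintf("# config: %s", js), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

json_hash <- function(js) {
  tf <- tempfile()
  writeLines(as.character(js), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}
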