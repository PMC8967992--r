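#' Cell-cycle stage from cell morphology
#'
#' Deterministic staging of fission yeast cells from length, nuclear count
#' and septation: septated cells are G1/S regardless of other features;
#' binucleate cells of length >= 11 um are late mitosis; mononucleate cells
#' are early G2 (< 9.5 um), mid G2 (9.5 to < 11 um) or late G2/early
#' mitosis (>= 11 um). Binucleate cells shorter than 11 um have no defined
#' stage and are labelled "unclassified".
#'
#' @param length_um cell length(s) in um (> 0).
#' @param n_nuclei 1 or 2.
#' @param septated logical.
#' @return character vector of stage labels, one of `early_G2`, `mid_G2`,
#'   `lateG2_earlyM`, `late_mitosis`, `G1_S`, `unclassified`.
#' @export
stage_cell <- function(length_um, n_nuclei, septated) {
  k <- max(length(length_um), length(n_nuclei), length(septated))
  length_um <- rep_len(length_um, k)
  n_nuclei <- rep_len(as.integer(n_nuclei), k)
  septated <- rep_len(as.logical(septated), k)
  if (any(!is.finite(length_um) | length_um <= 0)) stop("length_um must be > 0")
  if (any(!n_nuclei %in% c(1L, 2L))) stop("n_nuclei must be 1 or 2")
  out <- character(k)
  out[septated] <- "G1_S"
  bi <- !septated & n_nuclei == 2L
  out[bi & length_um >= 11] <- "late_mitosis"
  out[bi & length_um < 11] <- "unclassified"
  mono <- !septated & n_nuclei == 1L
  out[mono & length_um < 9.5] <- "early_G2"
  out[mono & length_um >= 9.5 & length_um < 11] <- "mid_G2"
  out[mono & length_um >= 11] <- "lateG2_earlyM"
  out
}

#' SPB duplication stage from daughter/mother intensity ratio
#'
#' The daughter/mother SPB marker intensity ratio indexes cell-cycle
#' progression: ratio < 0.5 is G1/S, 0.5 to < 0.8 is early/mid G2, and
#' >= 0.8 is late G2/mitosis. The upper band is explicitly closed at 0.8;
#' the remaining bands are half-open for exhaustiveness.
#'
#' @param daughter_intensity,mother_intensity non-negative intensities;
#'   `mother_intensity` must be > 0.
#' @return character vector of labels among `G1_S`, `early_mid_G2`,
#'   `lateG2_mitosis`.
#' @export
spb_stage <- function(daughter_intensity, mother_intensity) {
  k <- max(length(daughter_intensity), length(mother_intensity))
  daughter_intensity <- rep_len(daughter_intensity, k)
  mother_intensity <- rep_len(mother_intensity, k)
  if (any(daughter_intensity < 0 | mother_intensity < 0))
    stop("intensities must be non-negative")
  if (any(mother_intensity <= 0)) stop("mother_intensity must be > 0")
  ratio <- daughter_intensity / mother_intensity
  ifelse(ratio < 0.5, "G1_S",
         ifelse(ratio < 0.8, "early_mid_G2", "lateG2_mitosis"))
}

#' Stage a table of cell measurements
#'
#' Convenience wrapper adding `stage` (and, when SPB intensities are
#' present, `spb_stage`) columns to a measurement table, e.g. one read from
#' CSV with columns `length_um`, `n_nuclei`, `septated` and optionally
#' `daughter_intensity`, `mother_intensity`.
#'
#' @param df data.frame of measurements.
#' @return the data.frame with stage columns appended.
#' @export
stage_table <- function(df) {
  df$stage <- stage_cell(df$length_um, df$n_nuclei, df$septated)
  if (all(c("daughter_intensity", "mother_intensity") %in% names(df)))
    df$spb_stage <- spb_stage(df$daughter_intensity, df$mother_intensity)
  df
}
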