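# Gel-dosimetry occupancy and luminescence viability arithmetic.
#
# Band intensities from silver-stained SDS-PAGE gels enter as plain
# numbers (mean pixel intensities over equal-sized band areas); peptide
# amounts are referenced to a peptide-only lane of known amount, and the
# protrusion-site occupancy follows from the amount of origami loaded and
# its number of protruding sites. Units of the origami and peptide
# amounts only need to be mutually consistent.

#' Gel-dosimetry site occupancy
#'
#' Per lane, the peptide amount is
#' `known_peptide_amount * band_intensity / reference_band_intensity`,
#' and the protrusion-site occupancy percentage is
#' `100 * peptide_amount / (origami_amount * n_sites)`.
#' Occupancies are not clipped: values above 100% (possible under
#' measurement noise) are reported with a warning.
#'
#' @param lanes Data frame with one row per gel lane and columns `label`,
#'   `band_intensity` (mean pixel intensity, a.u., >= 0), `n_sites`
#'   (protruding sites; >= 1 on sample lanes), `origami_amount` (molar
#'   amount, any consistent unit), `is_peptide_reference` (logical; exactly
#'   one `TRUE`), and `known_peptide_amount` (required on the reference
#'   lane).
#' @return `lanes` with added columns `peptide_amount` and `occupancy_pct`
#'   (`NA` on the reference lane).
#' @export
gel_occupancy <- function(lanes) {
  lanes <- as.data.frame(lanes)
  req <- c("label", "band_intensity", "n_sites", "origami_amount",
           "is_peptide_reference")
  missing <- setdiff(req, names(lanes))
  if (length(missing)) {
    stop("lane table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(lanes$band_intensity < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  ref <- which(lanes$is_peptide_reference)
  if (length(ref) != 1) {
    stop("exactly one reference (peptide-only) lane is required", call. = FALSE)
  }
  ref_int <- lanes$band_intensity[ref]
  if (ref_int <= 0) {
    stop("reference lane band intensity must be positive", call. = FALSE)
  }
  known <- lanes$known_peptide_amount[ref]
  if (is.null(known) || is.na(known) || known <= 0) {
    stop("reference lane needs a positive known_peptide_amount", call. = FALSE)
  }
  sample_rows <- setdiff(seq_len(nrow(lanes)), ref)
  if (any(lanes$n_sites[sample_rows] < 1)) {
    stop("sample lanes must have n_sites >= 1", call. = FALSE)
  }
  lanes$peptide_amount <- known * lanes$band_intensity / ref_int
  lanes$occupancy_pct <- NA_real_
  lanes$occupancy_pct[sample_rows] <- 100 * lanes$peptide_amount[sample_rows] /
    (lanes$origami_amount[sample_rows] * lanes$n_sites[sample_rows])
  if (any(lanes$occupancy_pct[sample_rows] > 100)) {
    warning("occupancy above 100% in lane(s): ",
            paste(lanes$label[sample_rows][
              lanes$occupancy_pct[sample_rows] > 100], collapse = ", "),
            call. = FALSE)
  }
  lanes
}

#' Luminescence cell-viability percentage
#'
#' `100 * (sample - background) / (PBS - background)`: the PBS-treated
#' control defines 100% viability and the cell-free background 0%.
#'
#' @param lum_sample Sample luminescence (a.u.); vectorized.
#' @param lum_background Background (cell-free) luminescence.
#' @param lum_pbs PBS-control luminescence; must exceed the background.
#' @return Percent viable cells.
#' @export
viability_percent <- function(lum_sample, lum_background, lum_pbs) {
  if (any(lum_pbs <= lum_background)) {
    stop("PBS-control luminescence must exceed the background", call. = FALSE)
  }
  100 * (lum_sample - lum_background) / (lum_pbs - lum_background)
}

#' Percent increase between two values
#'
#' Convenience for sanity arithmetic such as the relative molecular-weight
#' change of an origami upon conjugate hybridization.
#'
#' @param from Baseline value (nonzero).
#' @param to New value.
#' @return `100 * (to - from) / from`.
#' @export
percent_increase <- function(from, to) {
  if (any(from == 0)) stop("baseline value must be nonzero", call. = FALSE)
  100 * (to - from) / from
}
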