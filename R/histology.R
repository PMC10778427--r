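# Histology quantification: per-biopsy vessel density, mean vessel
# diameter, and HIF-1alpha H-score from tabulated vessel/staining records.

#' One biopsy's tabulated histology measurements
#'
#' Inputs are per-hotspot-ROI measurements as exported from slide-analysis
#' software (or generated by the phantom): segmented vessel records and the
#' distribution of HIF-1alpha staining intensity over cells.
#'
#' @param sample_id,subject_id identifiers (join keys to the targets
#'   table).
#' @param voi_label one of "nonenhancing", "enhancing", "necrosis".
#' @param vessel_records data frame with `area` (um^2) and/or `diameter`
#'   (um) per vessel; may have zero rows (avascular sample).
#' @param tissue_area total hotspot tissue area (um^2), > 0.
#' @param hif_cells named numeric vector over intensity levels "0".."3"
#'   with percentages of cells, summing to 100 +/- 0.5.
#' @return object of class `histology_sample`.
#' @export
histology_sample <- function(sample_id, subject_id, voi_label,
                             vessel_records, tissue_area, hif_cells) {
  voi_label <- match.arg(voi_label,
                         c("nonenhancing", "enhancing", "necrosis",
                           "edema", "contra_GM", "contra_WM"))
  if (tissue_area <= 0) stop_input("tissue_area must be > 0")
  if (!is.null(vessel_records) && nrow(vessel_records)) {
    if ("diameter" %in% names(vessel_records) &&
        any(vessel_records$diameter <= 0, na.rm = TRUE))
      stop_input("vessel diameters must be > 0")
    if ("area" %in% names(vessel_records) &&
        sum(vessel_records$area) > tissue_area)
      stop_input("total vessel area exceeds tissue area")
  }
  if (!setequal(names(hif_cells), c("0", "1", "2", "3")))
    stop_input("hif_cells must be named over intensity levels 0..3")
  if (abs(sum(hif_cells) - 100) > 0.5)
    stop_input("hif_cells percentages must sum to 100 +/- 0.5")
  structure(list(sample_id = sample_id, subject_id = subject_id,
                 voi_label = voi_label, vessel_records = vessel_records,
                 tissue_area = tissue_area,
                 hif_cells = hif_cells[c("0", "1", "2", "3")]),
            class = "histology_sample")
}

#' Vessel density of a biopsy sample
#'
#' Total vessel area divided by total tissue area over the sample's
#' hotspot ROIs; a fraction in [0, 1]. Zero when the sample has no vessels.
#'
#' @param sample a [histology_sample()].
#' @export
vessel_density <- function(sample) {
  stopifnot(inherits(sample, "histology_sample"))
  vr <- sample$vessel_records
  if (is.null(vr) || nrow(vr) == 0L) return(0)
  if (!"area" %in% names(vr)) stop_input("vessel_records lack areas")
  sum(vr$area) / sample$tissue_area
}

#' Mean vessel diameter of a biopsy sample
#'
#' Unweighted mean of per-vessel diameters; when only segmentation areas
#' are recorded, the equivalent-circle diameter `2 sqrt(area / pi)` is
#' used. Samples without vessels return NA (flagged, not an error).
#'
#' @param sample a [histology_sample()].
#' @return diameter in um, or NA for an avascular sample.
#' @export
mean_vessel_diameter <- function(sample) {
  stopifnot(inherits(sample, "histology_sample"))
  vr <- sample$vessel_records
  if (is.null(vr) || nrow(vr) == 0L) return(NA_real_)
  d <- if ("diameter" %in% names(vr) && !all(is.na(vr$diameter))) {
    vr$diameter
  } else {
    2 * sqrt(vr$area / pi)
  }
  mean(d)
}

#' HIF-1alpha H-score of a biopsy sample
#'
#' The standard immunohistochemistry H-score: the sum over intensity
#' levels of (level x percent positive cells), ranging 0-300.
#'
#' @param sample a [histology_sample()].
#' @export
hif_score <- function(sample) {
  stopifnot(inherits(sample, "histology_sample"))
  sum(as.numeric(names(sample$hif_cells)) * sample$hif_cells)
}

#' Quantify a list of histology samples into the per-biopsy table
#'
#' @param samples list of [histology_sample()]s.
#' @return data frame with sample_id, subject_id, voi_label,
#'   vessel_density, vessel_diameter, hif_score.
#' @export
histology_table <- function(samples) {
  rows <- lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, subject_id = s$subject_id,
               voi_label = s$voi_label,
               vessel_density = vessel_density(s),
               vessel_diameter = mean_vessel_diameter(s),
               hif_score = hif_score(s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
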