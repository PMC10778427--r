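# VOI handling: probability-map binarization, VOI-averaged baseline-aligned
# FLAIR-ASE decay curves, and per-VOI summary statistics with error-mask
# exclusion.

TUMOR_VOIS <- c("edema", "nonenhancing", "enhancing", "necrosis")
ALL_VOIS <- c(TUMOR_VOIS, "contra_GM", "contra_WM")

#' Validate a named set of VOI masks
#'
#' All masks must share the reference grid; tumor masks must be pairwise
#' disjoint (each voxel belongs to at most one tumor compartment).
#'
#' @param masks named list of logical/0-1 3D arrays over (a subset of)
#'   edema, nonenhancing, enhancing, necrosis, contra_GM, contra_WM.
#' @param source provenance tag.
#' @return object of class `voi_mask_set`.
#' @export
voi_mask_set <- function(masks, source = c("provided", "derived")) {
  source <- match.arg(source)
  if (is.null(names(masks)) || !all(names(masks) %in% ALL_VOIS))
    stop_input("masks must be named among: ", paste(ALL_VOIS, collapse = ", "))
  dims <- lapply(masks, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop_input("all masks must share the reference grid")
  tumor <- intersect(names(masks), TUMOR_VOIS)
  if (length(tumor) > 1L) {
    total <- Reduce(`+`, lapply(masks[tumor], function(m) (m > 0) * 1L))
    if (any(total > 1L))
      stop_input("tumor masks must be pairwise disjoint")
  }
  structure(list(masks = lapply(masks, function(m) m > 0), source = source),
            class = "voi_mask_set")
}

#' VOI mask set from a phantom's label volume
#' @param truth a `ground_truth`.
#' @export
phantom_voi_masks <- function(truth) {
  present <- intersect(names(truth$spec$region_params), ALL_VOIS)
  masks <- lapply(present, function(rn) phantom_region_mask(truth, rn))
  names(masks) <- present
  voi_mask_set(masks, source = "provided")
}

#' Binarize GM/WM probability maps into contralateral masks
#'
#' Strictly-greater thresholding (`prob > threshold`, default 0.9, chosen to
#' minimize partial-volume effects) intersected with the contralateral
#' hemisphere mask.
#'
#' @param gm_prob,wm_prob probability arrays in [0, 1].
#' @param hemisphere_mask logical array of the contralateral hemisphere.
#' @param threshold probability cutoff (strict inequality).
#' @return list with logical `contra_GM`, `contra_WM`.
#' @export
binarize_probability_maps <- function(gm_prob, wm_prob, hemisphere_mask,
                                      threshold = 0.9) {
  for (p in list(gm_prob, wm_prob)) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stop_input("probabilities must lie in [0, 1]")
  }
  hemi <- hemisphere_mask > 0
  out <- list(contra_GM = (gm_prob > threshold) & hemi,
              contra_WM = (wm_prob > threshold) & hemi)
  if (!any(out$contra_WM))
    warning("empty contra_WM mask: CBV normalization will refuse it")
  if (!any(out$contra_GM))
    warning("empty contra_GM mask")
  out
}

#' VOI-averaged, baseline-aligned FLAIR-ASE decay curve
#'
#' Mean and SD of the log signal per tau over the unflagged voxels of a
#' VOI; the mean curve is shifted by an additive offset so that its tau = 0
#' value equals the reference (contralateral GM) curve's tau = 0 value.
#' SDs are left unshifted (the offset is an additive constant on the mean
#' only). Alignment is idempotent: aligning an aligned curve again yields a
#' zero additional offset.
#'
#' @param series an [ase_series()].
#' @param mask logical/0-1 3D array, non-empty after error-mask exclusion.
#' @param error_mask optional binary array of voxels to exclude.
#' @param contra_gm_curve optional `voi_curve` used as the baseline
#'   reference; NULL leaves the curve unaligned (offset 0).
#' @param voi_name label stored with the curve.
#' @return object of class `voi_curve`: `taus_ms`, `mean_ln_signal`,
#'   `sd_ln_signal`, `n_voxels`, `baseline_offset`, `voi_name`.
#' @export
voi_curve <- function(series, mask, error_mask = NULL,
                      contra_gm_curve = NULL, voi_name = "VOI") {
  stopifnot(inherits(series, "ase_series"))
  sel <- as.vector(mask > 0)
  if (!is.null(error_mask)) sel <- sel & !(as.vector(error_mask) > 0)
  if (!any(sel)) stop_input("VOI '", voi_name, "' is empty after exclusion")
  dm <- dim(series$data)
  lnY <- matrix(log_signal(series), prod(dm[1:3]), dm[4])[sel, , drop = FALSE]
  m <- colMeans(lnY)
  s <- apply(lnY, 2L, stats::sd)
  offset <- 0
  if (!is.null(contra_gm_curve)) {
    offset <- contra_gm_curve$mean_ln_signal[1] - m[1]
    m <- m + offset
  }
  structure(list(voi_name = voi_name, taus_ms = series$taus_ms,
                 mean_ln_signal = m, sd_ln_signal = s,
                 n_voxels = sum(sel), baseline_offset = offset),
            class = "voi_curve")
}

#' Curves for every VOI of a subject, aligned to the contra-GM baseline
#'
#' @param series an [ase_series()].
#' @param voi_set a [voi_mask_set()] containing `contra_GM`.
#' @param error_mask optional binary exclusion array.
#' @return named list of [voi_curve()]s (contra-GM first, offset 0).
#' @export
voi_curves <- function(series, voi_set, error_mask = NULL) {
  stopifnot(inherits(voi_set, "voi_mask_set"))
  if (!"contra_GM" %in% names(voi_set$masks))
    stop_input("voi_set must contain contra_GM (baseline reference)")
  ref <- voi_curve(series, voi_set$masks$contra_GM, error_mask,
                   voi_name = "contra_GM")
  others <- setdiff(names(voi_set$masks), "contra_GM")
  out <- c(list(contra_GM = ref),
           lapply(others, function(v) {
             voi_curve(series, voi_set$masks[[v]], error_mask,
                       contra_gm_curve = ref, voi_name = v)
           }))
  names(out) <- c("contra_GM", others)
  out
}

#' Median / IQR summaries of parameter maps per VOI
#'
#' For each (VOI, metric): the median and interquartile range (Q3 - Q1,
#' linear-interpolation percentiles) over the VOI's voxels after removing
#' error-mask voxels and non-finite values. `n_excluded` counts exactly the
#' error-mask voxels intersecting the VOI.
#'
#' @param maps named list of 3D metric arrays (e.g. R2prime, DBV, OEF, CBV,
#'   vessel_size); NA entries are treated as flagged.
#' @param voi_set a [voi_mask_set()].
#' @param error_mask optional binary exclusion array.
#' @param subject subject identifier carried into the table.
#' @return data frame with columns subject, voi, metric, median, iqr,
#'   n_voxels, n_excluded.
#' @export
voi_summary <- function(maps, voi_set, error_mask = NULL,
                        subject = "phantom") {
  stopifnot(inherits(voi_set, "voi_mask_set"))
  rows <- list()
  for (v in names(voi_set$masks)) {
    mask <- as.vector(voi_set$masks[[v]])
    excl <- if (!is.null(error_mask)) as.vector(error_mask) > 0 else
      rep(FALSE, length(mask))
    keep <- mask & !excl
    for (mn in names(maps)) {
      vals <- as.vector(maps[[mn]])[keep]
      vals <- vals[is.finite(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, voi = v, metric = mn,
        median = if (length(vals)) pctl(vals, 0.5) else NA_real_,
        iqr = if (length(vals)) pctl(vals, 0.75) - pctl(vals, 0.25)
              else NA_real_,
        n_voxels = sum(keep), n_excluded = sum(mask & excl))
    }
  }
  do.call(rbind, rows)
}

#' Group-level aggregation of per-subject VOI summaries
#'
#' Mean and SD across subjects of the per-subject medians, the convention
#' used for group tables (median within subject, then mean across the
#' cohort).
#'
#' @param summaries data frame from [voi_summary()] rows over subjects.
#' @return data frame with columns voi, metric, mean_of_medians,
#'   sd_of_medians, n_subjects.
#' @export
group_voi_summary <- function(summaries) {
  key <- interaction(summaries$voi, summaries$metric, drop = TRUE)
  out <- lapply(split(summaries, key), function(d) {
    data.frame(voi = d$voi[1], metric = d$metric[1],
               mean_of_medians = mean(d$median, na.rm = TRUE),
               sd_of_medians = stats::sd(d$median[!is.na(d$median)]),
               n_subjects = sum(!is.na(d$median)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plot baseline-aligned VOI decay curves
#'
#' Mean log signal against tau with +/- SD error bars per VOI, the standard
#' visual check that a compartment's decay follows the sqBOLD pattern.
#'
#' @param curves named list of [voi_curve()]s.
#' @param main plot title.
#' @export
plot_voi_curves <- function(curves, main = "VOI-averaged FLAIR-ASE signal") {
  cols <- grDevices::hcl.colors(length(curves), "Dark 3")
  ylim <- range(vapply(curves, function(cu)
    range(cu$mean_ln_signal + cu$sd_ln_signal,
          cu$mean_ln_signal - cu$sd_ln_signal), numeric(2)))
  graphics::plot(NA, xlim = range(curves[[1]]$taus_ms), ylim = ylim,
                 xlab = expression(tau ~ "(ms)"),
                 ylab = "ln signal (baseline-aligned)", main = main)
  for (i in seq_along(curves)) {
    cu <- curves[[i]]
    graphics::lines(cu$taus_ms, cu$mean_ln_signal, col = cols[i], type = "b",
                    pch = 16, cex = 0.6)
    graphics::arrows(cu$taus_ms, cu$mean_ln_signal - cu$sd_ln_signal,
                     cu$taus_ms, cu$mean_ln_signal + cu$sd_ln_signal,
                     length = 0.02, angle = 90, code = 3, col = cols[i])
  }
  graphics::legend("bottomleft", legend = names(curves), col = cols,
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(NULL)
}
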