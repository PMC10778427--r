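# Synthetic brain phantom: labelled geometry with known ground truth, and
# forward simulators for every raw input the pipeline consumes (FLAIR-ASE,
# dual-echo DSC, DWI, histology tables).

PHANTOM_REGIONS <- c(
  contra_GM = 1L, contra_WM = 2L, CSF = 3L, edema = 4L,
  nonenhancing = 5L, enhancing = 6L, necrosis = 7L
)

TUMOR_REGIONS <- c("edema", "nonenhancing", "enhancing", "necrosis")

PARAM_NAMES <- c("R2prime", "DBV", "R2", "S0", "CBV_true",
                 "vessel_size_true", "ADC", "leakage_K2")

#' Default per-region ground-truth parameters
#'
#' Region means for R2' (s^-1), DBV (fraction), normalized CBV and vessel
#' size (um) follow published group values for contralateral gray matter and
#' the four tumor compartments of glioma/metastasis patients; contralateral
#' white matter is the CBV normalization reference (CBV_true = 1 by
#' definition). R2, S0 and ADC are literature-plausible tissue values; the
#' FLAIR preparation is emulated by a strongly suppressed CSF S0. Leakage
#' (K2, s^-1) is nonzero only in the enhancing compartment, where the
#' blood-brain barrier is disrupted.
#'
#' @return named list of per-region parameter lists.
#' @export
default_region_params <- function() {
  list(
    contra_GM = list(R2prime = 5.13, DBV = 0.0430, R2 = 12.5, S0 = 100,
                     CBV_true = 1.66, vessel_size_true = 16.24,
                     ADC = 0.80e-3, leakage_K2 = 0),
    contra_WM = list(R2prime = 3.50, DBV = 0.0250, R2 = 11.0, S0 = 90,
                     CBV_true = 1.00, vessel_size_true = 10.00,
                     ADC = 0.70e-3, leakage_K2 = 0),
    CSF = list(R2prime = 1.00, DBV = 0.0050, R2 = 2.0, S0 = 5,
               CBV_true = 0.00, vessel_size_true = 0.00,
               ADC = 3.00e-3, leakage_K2 = 0),
    edema = list(R2prime = 3.21, DBV = 0.0743, R2 = 10.0, S0 = 100,
                 CBV_true = 0.71, vessel_size_true = 16.78,
                 ADC = 1.40e-3, leakage_K2 = 0),
    nonenhancing = list(R2prime = 2.56, DBV = 0.0748, R2 = 11.0, S0 = 100,
                        CBV_true = 1.04, vessel_size_true = 12.97,
                        ADC = 1.10e-3, leakage_K2 = 0),
    enhancing = list(R2prime = 7.90, DBV = 0.0644, R2 = 12.0, S0 = 100,
                     CBV_true = 1.78, vessel_size_true = 25.73,
                     ADC = 0.95e-3, leakage_K2 = 0.05),
    necrosis = list(R2prime = 7.36, DBV = 0.0672, R2 = 10.0, S0 = 100,
                    CBV_true = 0.70, vessel_size_true = 16.61,
                    ADC = 1.60e-3, leakage_K2 = 0)
  )
}

#' Specify a digital brain phantom
#'
#' @param grid_shape integer length-3, voxel counts per axis (each >= 16).
#' @param voxel_size mm per axis.
#' @param region_params per-region ground truth; see
#'   [default_region_params()] for the fields each region must supply.
#' @param noise list with `model` ("gaussian" or "rician") and `sigma`
#'   (noise SD as a fraction of the maximum tissue S0).
#' @param seed integer seed controlling every stochastic simulator applied
#'   to this phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size = c(2, 2, 2),
                         region_params = default_region_params(),
                         noise = list(model = "gaussian", sigma = 0.01),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop_input("grid_shape must be three integers, each >= 16")
  if (!all(names(region_params) %in% names(PHANTOM_REGIONS)))
    stop_input("unknown region name(s): ",
               paste(setdiff(names(region_params), names(PHANTOM_REGIONS)),
                     collapse = ", "))
  if (!"contra_WM" %in% names(region_params))
    stop_input("contra_WM region is required (CBV normalization reference)")
  for (rn in names(region_params)) {
    p <- region_params[[rn]]
    missing <- setdiff(PARAM_NAMES, names(p))
    if (length(missing))
      stop_input("region ", rn, " lacks parameter(s): ",
                 paste(missing, collapse = ", "))
    if (p$DBV <= 0 || p$DBV >= 1) stop_input(rn, ": DBV must be in (0,1)")
    if (p$R2prime <= 0) stop_input(rn, ": R2prime must be > 0")
    if (p$ADC <= 0) stop_input(rn, ": ADC must be > 0")
    if (p$CBV_true < 0) stop_input(rn, ": CBV_true must be >= 0")
  }
  if (region_params$contra_WM$CBV_true <= 0)
    stop_input("contra_WM CBV_true must be > 0 (normalization reference)")
  noise$model <- match.arg(noise$model %||% "gaussian", c("gaussian", "rician"))
  noise$sigma <- noise$sigma %||% 0
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 region_params = region_params, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Region geometry as fractions of the grid: a tumor hemisphere holding
# nested ellipsoids (necrosis inside enhancing inside edema) plus a separate
# nonenhancing blob, a contralateral hemisphere with a GM shell around a WM
# core, and a mid-sagittal CSF slab. Later paints overwrite earlier ones.
phantom_geometry <- function(dim, regions) {
  paint <- list(
    CSF = list(center = c(0.50, 0.50, 0.50), radii = c(0.035, 0.45, 0.45)),
    contra_GM = list(center = c(0.72, 0.50, 0.50), radii = c(0.20, 0.30, 0.30)),
    contra_WM = list(center = c(0.72, 0.50, 0.50), radii = c(0.11, 0.17, 0.17)),
    edema = list(center = c(0.30, 0.50, 0.50), radii = c(0.20, 0.25, 0.25)),
    nonenhancing = list(center = c(0.30, 0.13, 0.50), radii = c(0.09, 0.09, 0.09)),
    enhancing = list(center = c(0.30, 0.50, 0.50), radii = c(0.12, 0.16, 0.16)),
    necrosis = list(center = c(0.30, 0.50, 0.50), radii = c(0.06, 0.08, 0.08))
  )
  labels <- array(0L, dim)
  for (rn in names(paint)) {
    if (!rn %in% names(regions)) next
    g <- paint[[rn]]
    m <- ellipsoid_mask(dim, center = g$center * dim, radii = pmax(g$radii * dim, 1))
    labels[m] <- PHANTOM_REGIONS[[rn]]
  }
  labels
}

#' Build the labelled phantom and its ground-truth parameter maps
#'
#' Deterministic given the spec (geometry is analytic; the seed only matters
#' for the downstream simulators). Tumor compartments are nested concentric
#' ellipsoids (necrosis inside enhancing inside edema) with a separate
#' nonenhancing blob; contralateral GM forms a shell around the WM core.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `ground_truth`: `label_volume` (integer array,
#'   coded per `PHANTOM_REGIONS`, 0 = background), `parameter_maps` (one 3D
#'   array per ground-truth parameter, 0 outside the brain), `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_geometry(spec$grid_shape, spec$region_params)
  # drop painted-over regions that ended up empty is impossible by geometry;
  # but a requested region must exist in the label volume
  maps <- lapply(PARAM_NAMES, function(pn) array(0, spec$grid_shape))
  names(maps) <- PARAM_NAMES
  for (rn in names(spec$region_params)) {
    sel <- labels == PHANTOM_REGIONS[[rn]]
    if (!any(sel))
      stop_input("region ", rn, " is empty on this grid")
    for (pn in PARAM_NAMES) maps[[pn]][sel] <- spec$region_params[[rn]][[pn]]
  }
  structure(list(label_volume = labels, parameter_maps = maps, spec = spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("phantom ground truth:", paste(dim(x$label_volume), collapse = "x"),
      "grid\n")
  tab <- table(factor(x$label_volume, levels = PHANTOM_REGIONS,
                      labels = names(PHANTOM_REGIONS)))
  print(tab)
  invisible(x)
}

#' Brain mask (any labelled voxel) of a phantom
#' @param truth a `ground_truth`.
#' @export
phantom_brain_mask <- function(truth) truth$label_volume > 0L

#' Binary mask of one phantom region
#' @param truth a `ground_truth`.
#' @param region region name, e.g. `"enhancing"`.
#' @export
phantom_region_mask <- function(truth, region) {
  region <- match.arg(region, names(PHANTOM_REGIONS))
  truth$label_volume == PHANTOM_REGIONS[[region]]
}

#' Evaluate the sqBOLD log-signal model
#'
#' Piecewise decay of the FLAIR-ASE log signal: a quadratic regime for
#' tau < tau_c, `c0 - 0.3 * (R2' * tau)^2 / DBV`, and a linear regime for
#' tau >= tau_c, `c0 + DBV - R2' * tau`, where `c0 = ln S0 - R2 * TE`. The
#' transition point tau_c is assigned to the linear branch.
#'
#' @param tau_s tau values in seconds.
#' @param c0 intercept `ln S0 - R2 * TE` (vector over voxels).
#' @param R2prime,DBV model parameters (vectors over voxels).
#' @param tau_c_s transition time in seconds (default 0.016).
#' @return matrix voxels x taus of log signal.
#' @export
sqbold_log_signal <- function(tau_s, c0, R2prime, DBV, tau_c_s = 0.016) {
  nv <- length(c0)
  out <- matrix(NA_real_, nv, length(tau_s))
  for (j in seq_along(tau_s)) {
    tj <- tau_s[j]
    out[, j] <- if (tj < tau_c_s) {
      c0 - 0.3 * (R2prime * tj)^2 / DBV
    } else {
      c0 + DBV - R2prime * tj
    }
  }
  out
}

#' Simulate a FLAIR-ASE acquisition from phantom ground truth
#'
#' Each labelled voxel follows the sqBOLD piecewise decay with its region's
#' parameters; background voxels stay at zero. Optional corruption injects a
#' shifted signal peak (decay driven by |tau - tau_peak| instead of tau) in
#' selected regions, emulating tumors whose FLAIR-ASE signal peaks at
#' tau > 0 and must be caught by the error mask.
#'
#' @param truth a `ground_truth`.
#' @param taus_ms tau scheme in ms; must contain 0, all others > 0.
#' @param TE_ms echo time, must exceed max(taus_ms).
#' @param noise list(model, sigma); defaults to the phantom spec's noise.
#'   `sigma` is the magnitude-noise SD as a fraction of the maximum tissue
#'   S0 (so low-S0 tissue such as FLAIR-suppressed CSF has low SNR).
#' @param seed RNG seed; defaults to the phantom spec's seed.
#' @param corrupt NULL, or list(regions = character vector of region names,
#'   tau_peak_ms = 28) requesting the shifted-peak corruption.
#' @return an [ase_series()].
#' @export
simulate_flair_ase <- function(truth,
                               taus_ms = c(0, seq(16, 60, by = 4)),
                               TE_ms = 74,
                               noise = NULL,
                               seed = NULL,
                               corrupt = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!0 %in% taus_ms) stop_input("taus_ms must include 0")
  if (any(taus_ms < 0) || any(taus_ms[taus_ms != 0] <= 0))
    stop_input("tau values other than 0 must be > 0")
  if (TE_ms <= max(taus_ms)) stop_input("TE_ms must exceed max(taus_ms)")
  taus_ms <- sort(taus_ms)
  noise <- noise %||% truth$spec$noise
  seed <- seed %||% truth$spec$seed

  dm <- dim(truth$label_volume)
  nvox <- prod(dm)
  pm <- truth$parameter_maps
  c0 <- log(pmax(as.vector(pm$S0), .Machine$double.xmin)) -
    as.vector(pm$R2) * (TE_ms / 1000)
  tau_s <- taus_ms / 1000
  lnS <- sqbold_log_signal(tau_s, c0, as.vector(pm$R2prime),
                           as.vector(pm$DBV))

  if (!is.null(corrupt)) {
    tau_pk_s <- (corrupt$tau_peak_ms %||% 28) / 1000
    sel <- as.vector(truth$label_volume) %in%
      PHANTOM_REGIONS[corrupt$regions]
    if (any(sel)) {
      lnS[sel, ] <- sqbold_log_signal(
        abs(tau_s - tau_pk_s), c0[sel],
        as.vector(pm$R2prime)[sel], as.vector(pm$DBV)[sel])
    }
  }

  S <- exp(lnS)
  S[as.vector(truth$label_volume) == 0L, ] <- 0
  if (noise$sigma > 0) {
    sd_abs <- noise$sigma * max(as.vector(pm$S0))
    S <- with_seed(seed, {
      array(add_noise(S, sd_abs, noise$model), dim = dim(S))
    })
    S[S < 0] <- 0
  }
  ase_series(array(S, c(dm, length(taus_ms))), taus_ms = taus_ms,
             TE_ms = TE_ms)
}

#' Normalized gamma-variate bolus shape (unit peak)
#'
#' `g(t) = ((t-t0)/(alpha*beta))^alpha * exp(alpha - (t-t0)/beta)` for
#' t > t0, else 0; peak value 1 at `t0 + alpha*beta`.
#' @param t times in seconds.
#' @param onset_s bolus arrival time t0.
#' @param alpha,beta_s shape and scale.
#' @export
gamma_variate <- function(t, onset_s = 20, alpha = 3, beta_s = 1.5) {
  u <- pmax(t - onset_s, 0)
  ifelse(u > 0, (u / (alpha * beta_s))^alpha * exp(alpha - u / beta_s), 0)
}

#' Simulate a dual-echo DSC acquisition from phantom ground truth
#'
#' The gradient-echo relaxation response of each voxel is a gamma-variate
#' scaled by its ground-truth CBV, so that the bolus-window trapezoidal
#' integral normalized to contralateral WM recovers `CBV_true` exactly. The
#' spin-echo response is scaled so that the Kiselev vessel-size relation
#' applied to the (grid-sampled) curve peaks returns `vessel_size_true`.
#' Voxels with leakage (`leakage_K2 > 0`, the enhancing compartment)
#' additionally see their measured gradient-echo response reduced by
#' `K2 * int_0^t mean-reference response dt'`, the extravasation term the
#' BSW correction is designed to remove. The first `n_discard` volumes are
#' emitted in a non-steady state (elevated baseline) and must be dropped.
#'
#' @param truth a `ground_truth`.
#' @param TR_s repetition time (s).
#' @param TE_gre_ms,TE_se_ms gradient-/spin-echo TE (ms).
#' @param n_volumes total volumes (>= 30).
#' @param bolus list(onset_s, alpha, beta_s, amp) — `amp` is the peak
#'   gradient-echo dR2* (s^-1) of a voxel with CBV_true = 1.
#' @param noise,seed as in [simulate_flair_ase()]; noise sigma is a fraction
#'   of the baseline signal.
#' @param n_discard leading non-steady-state volumes (default 4).
#' @return a [dsc_series()].
#' @export
simulate_dsc <- function(truth,
                         TR_s = 1.5,
                         TE_gre_ms = 18.6,
                         TE_se_ms = 69,
                         n_volumes = 122L,
                         bolus = list(onset_s = 20, alpha = 3, beta_s = 1.5,
                                      amp = 20),
                         noise = NULL,
                         seed = NULL,
                         n_discard = 4L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_volumes < 30L) stop_input("n_volumes must be >= 30")
  noise <- noise %||% truth$spec$noise
  seed <- seed %||% truth$spec$seed
  t_all <- (seq_len(n_volumes) - 1L) * TR_s
  peak_t <- (bolus$onset_s %||% 20) + (bolus$alpha %||% 3) * (bolus$beta_s %||% 1.5)
  if (peak_t >= max(t_all)) stop_input("bolus peak outside acquisition window")
  g <- gamma_variate(t_all, bolus$onset_s %||% 20, bolus$alpha %||% 3,
                     bolus$beta_s %||% 1.5)
  g_pk <- max(g)  # grid-sampled peak, shared by simulator and estimator

  dm <- dim(truth$label_volume)
  nvox <- prod(dm)
  pm <- truth$parameter_maps
  labels_v <- as.vector(truth$label_volume)
  cbv_t <- as.vector(pm$CBV_true)
  wm_ref <- truth$spec$region_params$contra_WM$CBV_true
  cbv_norm <- cbv_t / wm_ref
  amp <- bolus$amp %||% 20

  # true GRE response
  A <- amp * cbv_t
  dr2s_true <- outer(A, g)

  # SE response calibrated against the vessel-size relation
  vs_mm <- as.vector(pm$vessel_size_true) / 1000
  dr2se_pk <- numeric(nvox)
  ok <- vs_mm > 0 & cbv_norm > 0
  bad <- vs_mm <= 0 & cbv_norm > 0 & labels_v > 0
  if (any(bad))
    stop_input("vessel_size_true must be > 0 wherever CBV_true > 0")
  dr2se_pk[ok] <- (0.867 * sqrt(cbv_norm[ok] * as.vector(pm$ADC)[ok]) *
                     A[ok] * g_pk / vs_mm[ok])^(2 / 3)
  dr2se <- outer(dr2se_pk / g_pk, g)

  # leakage on the measured GRE response (reference = non-enhancing brain)
  ref_sel <- labels_v > 0 & labels_v != PHANTOM_REGIONS[["enhancing"]] &
    labels_v != PHANTOM_REGIONS[["CSF"]]
  ref_curve <- colMeans(dr2s_true[ref_sel, , drop = FALSE])
  leak <- outer(as.vector(pm$leakage_K2), cumtrapz(t_all, ref_curve))
  dr2s_meas <- dr2s_true - leak

  # emit signals; non-steady-state lead-in on the first n_discard volumes
  s_base <- as.vector(pm$S0)
  gre <- s_base * exp(-dr2s_meas * (TE_gre_ms / 1000))
  se <- s_base * exp(-dr2se * (TE_se_ms / 1000))
  if (n_discard > 0L) {
    lead <- 1 + 0.5 * exp(-(seq_len(n_discard) - 1L))
    for (j in seq_len(n_discard)) {
      gre[, j] <- gre[, j] * lead[j]
      se[, j] <- se[, j] * lead[j]
    }
  }
  if (noise$sigma > 0) {
    sd_abs <- noise$sigma * max(s_base)
    noisy <- with_seed(seed + 1L, {
      list(g = add_noise(gre, sd_abs, noise$model),
           s = add_noise(se, sd_abs, noise$model))
    })
    gre <- array(noisy$g, dim = dim(gre))
    se <- array(noisy$s, dim = dim(se))
    gre[gre < 0] <- 0
    se[se < 0] <- 0
  }
  dsc_series(array(gre, c(dm, n_volumes)), array(se, c(dm, n_volumes)),
             TR_s = TR_s, TE_gre_ms = TE_gre_ms, TE_se_ms = TE_se_ms,
             n_discard = n_discard)
}

#' Simulate diffusion-weighted volumes from phantom ground truth
#'
#' Mono-exponential decay `S(b) = S(0) exp(-b * ADC)` per voxel.
#'
#' @param truth a `ground_truth`.
#' @param b_values s/mm^2, must include 0 and be nonnegative.
#' @param noise,seed as in [simulate_flair_ase()].
#' @return list with `data` (4D array x,y,z,b) and `b_values`.
#' @export
simulate_dwi <- function(truth, b_values = c(0, 10, 1000),
                         noise = NULL, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!0 %in% b_values) stop_input("b_values must include 0")
  if (any(b_values < 0)) stop_input("b_values must be >= 0")
  noise <- noise %||% truth$spec$noise
  seed <- seed %||% truth$spec$seed
  dm <- dim(truth$label_volume)
  s0 <- as.vector(truth$parameter_maps$S0)
  adc <- as.vector(truth$parameter_maps$ADC)
  S <- outer(s0, rep(1, length(b_values))) * exp(-outer(adc, b_values))
  if (noise$sigma > 0) {
    sd_abs <- noise$sigma * max(s0)
    S <- with_seed(seed + 2L, {
      array(add_noise(S, sd_abs, noise$model), dim = dim(S))
    })
    S[S < 0] <- 0
  }
  list(data = array(S, c(dm, length(b_values))), b_values = b_values)
}

#' Simulate per-biopsy histology measurements coupled to the ground truth
#'
#' For each biopsy target, draws raw histology records whose quantified
#' summaries (vessel density, mean vessel diameter, HIF-1alpha H-score) are
#' monotone noisy functions of the local ground truth: diameter tracks
#' `vessel_size_true`, density tracks normalized `CBV_true`, and the H-score
#' tracks the ground-truth OEF. With zero noise the induced Spearman
#' correlations are exactly 1.
#'
#' @param truth a `ground_truth`.
#' @param targets data frame with columns `x`, `y`, `z` (voxel indices of
#'   target centers), optionally `voi_label` and `subject_id`; typically
#'   from [prioritize_targets()] via [targets_table()].
#' @param coupling list of per-quantity `c(intercept, slope)` links plus
#'   `noise_sd = c(diameter, density, hif)`; slopes of 0 decouple histology
#'   from the maps (null simulation).
#' @param consts [qbold_constants()] used for the ground-truth OEF.
#' @param seed RNG seed (defaults to the phantom spec's).
#' @return list with `samples` (list of [histology_sample()]) and `table`
#'   (the quantified [histology_table()] data frame).
#' @export
simulate_histology <- function(truth, targets,
                               coupling = list(
                                 diameter = c(0, 1),
                                 density = c(0, 0.02),
                                 hif = c(0, 250),
                                 noise_sd = c(0, 0, 0)),
                               consts = qbold_constants(),
                               seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(targets) || nrow(targets) == 0L)
    stop_input("targets must be non-empty")
  seed <- seed %||% truth$spec$seed
  pm <- truth$parameter_maps
  wm_ref <- truth$spec$region_params$contra_WM$CBV_true
  oef_true <- compute_oef(pm$R2prime, pm$DBV, consts)

  local_mean <- function(map, x, y, z) {
    dm <- dim(map)
    xs <- max(1, x - 1):min(dm[1], x + 1)
    ys <- max(1, y - 1):min(dm[2], y + 1)
    zs <- max(1, z - 1):min(dm[3], z + 1)
    mean(map[xs, ys, zs], na.rm = TRUE)
  }

  n <- nrow(targets)
  with_seed(seed + 3L, {
    samples <- vector("list", n)
    for (i in seq_len(n)) {
      x <- targets$x[i]; y <- targets$y[i]; z <- targets$z[i]
      vs <- local_mean(pm$vessel_size_true, x, y, z)
      cbv <- local_mean(pm$CBV_true, x, y, z) / wm_ref
      oef <- local_mean(oef_true, x, y, z)
      d <- coupling$diameter[1] + coupling$diameter[2] * vs +
        stats::rnorm(1, 0, coupling$noise_sd[1])
      rho <- coupling$density[1] + coupling$density[2] * cbv +
        stats::rnorm(1, 0, coupling$noise_sd[2])
      hif <- coupling$hif[1] + coupling$hif[2] * oef +
        stats::rnorm(1, 0, coupling$noise_sd[3])
      d <- max(d, 0.5)
      rho <- min(max(rho, 0), 0.95)
      hif <- min(max(hif, 0), 300)
      tissue_area <- 1e6  # um^2 hotspot ROI
      k <- 5L             # vessels per hotspot
      vessel_records <- data.frame(
        area = rep(rho * tissue_area / k, k),
        diameter = rep(d, k))
      # distribute HIF mass between level 3 and level 0 to hit the score
      p3 <- hif / 3
      hif_cells <- c(`0` = 100 - p3, `1` = 0, `2` = 0, `3` = p3)
      samples[[i]] <- histology_sample(
        sample_id = sprintf("S%02d", i),
        subject_id = if ("subject_id" %in% names(targets))
          targets$subject_id[i] else "phantom",
        voi_label = if ("voi_label" %in% names(targets))
          targets$voi_label[i] else
            names(PHANTOM_REGIONS)[match(truth$label_volume[x, y, z],
                                         PHANTOM_REGIONS)],
        vessel_records = vessel_records,
        tissue_area = tissue_area,
        hif_cells = hif_cells)
    }
    list(samples = samples, table = histology_table(samples))
  })
}
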