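# End-to-end orchestration: simulate -> fit -> map -> target -> quantify ->
# stats from a single serializable config, with a manifest and cached
# resume.

#' Build a pipeline run configuration
#'
#' All module parameters in one serializable list. Every stage can be
#' toggled; `seed` drives all stochastic stages.
#'
#' @param grid_shape,voxel_size,region_params,noise,seed phantom settings,
#'   see [phantom_spec()].
#' @param taus_ms,TE_ms FLAIR-ASE acquisition scheme.
#' @param estimator "loglinear" (closed form) or "nls" (bounded nonlinear
#'   least squares).
#' @param thresholds [failure_thresholds()].
#' @param dsc list of DSC settings passed to [simulate_dsc()].
#' @param b_values DWI b-values (s/mm^2).
#' @param high_pct,low_pct,min_voxels,cluster_shape clustering settings,
#'   see [cluster_criteria()].
#' @param neighborhood target-value neighborhood, see
#'   [extract_target_values()].
#' @param max_targets ranked-target truncation (default 4).
#' @param coupling histology coupling, see [simulate_histology()].
#' @param stages named logical list toggling phantom/ase/qbold/perfusion/
#'   voi/targeting/histology/stats.
#' @return list of class `run_config`.
#' @export
run_config <- function(grid_shape = c(32L, 32L, 32L),
                       voxel_size = c(2, 2, 2),
                       region_params = default_region_params(),
                       noise = list(model = "gaussian", sigma = 0.01),
                       seed = 1L,
                       taus_ms = c(0, seq(16, 60, by = 4)),
                       TE_ms = 74,
                       estimator = c("loglinear", "nls"),
                       thresholds = failure_thresholds(),
                       dsc = list(TR_s = 1.5, TE_gre_ms = 18.6,
                                  TE_se_ms = 69, n_volumes = 122L,
                                  n_discard = 4L),
                       b_values = c(0, 10, 1000),
                       high_pct = 80, low_pct = 20, min_voxels = 9L,
                       cluster_shape = "block222",
                       neighborhood = "cube27",
                       max_targets = 4L,
                       coupling = list(diameter = c(0, 1),
                                       density = c(0, 0.02),
                                       hif = c(0, 250),
                                       noise_sd = c(1, 0.005, 15)),
                       stages = list()) {
  defaults <- list(phantom = TRUE, ase = TRUE, qbold = TRUE,
                   perfusion = TRUE, voi = TRUE, targeting = TRUE,
                   histology = TRUE, stats = TRUE)
  for (s in names(stages)) {
    if (!s %in% names(defaults)) stop_input("unknown stage: ", s)
    defaults[[s]] <- isTRUE(stages[[s]])
  }
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size = voxel_size, region_params = region_params,
              noise = noise, seed = as.integer(seed), taus_ms = taus_ms,
              TE_ms = TE_ms, estimator = match.arg(estimator),
              thresholds = thresholds, dsc = dsc, b_values = b_values,
              high_pct = high_pct, low_pct = low_pct,
              min_voxels = as.integer(min_voxels),
              cluster_shape = cluster_shape,
              neighborhood = neighborhood,
              max_targets = max_targets, coupling = coupling,
              stages = defaults)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!0 %in% cfg$taus_ms) stop_input("config: taus_ms must include 0")
  if (cfg$TE_ms <= max(cfg$taus_ms))
    stop_input("config: TE_ms must exceed max(taus_ms)")
  if (!cfg$cluster_shape %in% c("block222", "plane33"))
    stop_input("config: cluster_shape must be block222 or plane33")
  if (!cfg$neighborhood %in% c("cube27", "center10"))
    stop_input("config: neighborhood must be cube27 or center10")
  if (!is.null(cfg$max_targets) && cfg$max_targets < 1)
    stop_input("config: max_targets must be >= 1")
  invisible(cfg)
}

config_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(config_json(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Parse a configuration written by [run_pipeline()] (round-trip identity)
#' @param path config.json path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, list(
    grid_shape = raw$grid_shape, voxel_size = raw$voxel_size,
    region_params = lapply(raw$region_params, as.list),
    noise = as.list(raw$noise), seed = raw$seed, taus_ms = raw$taus_ms,
    TE_ms = raw$TE_ms, estimator = raw$estimator,
    thresholds = as.list(raw$thresholds), dsc = as.list(raw$dsc),
    b_values = raw$b_values, high_pct = raw$high_pct,
    low_pct = raw$low_pct, min_voxels = raw$min_voxels,
    cluster_shape = raw$cluster_shape, neighborhood = raw$neighborhood,
    max_targets = raw$max_targets, coupling = {
      cp <- lapply(raw$coupling, as.numeric)
      cp
    },
    stages = as.list(raw$stages)))
  cfg
}

#' Run the full phantom-to-statistics pipeline
#'
#' Executes the enabled stages in order — phantom construction, FLAIR-ASE /
#' DSC / DWI simulation, sqBOLD fitting, perfusion mapping, VOI summaries
#' and curves, cluster targeting, histology simulation and quantification,
#' and the statistical report — writing each stage's artifacts under
#' `out_dir` and a manifest with the config, package version and per-file
#' checksums. A rerun with an identical config reuses artifacts already on
#' disk (stage-level resume); any config change invalidates the cache.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created).
#' @param quiet suppress stage messages.
#' @return (invisibly) list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  hash <- config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  cache_ok <- FALSE
  if (file.exists(manifest_path)) {
    old <- try(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
               silent = TRUE)
    cache_ok <- !inherits(old, "try-error") &&
      identical(old$config_hash, unname(hash))
  }
  cached <- function(...) {
    paths <- c(...)
    cache_ok && all(file.exists(file.path(out_dir, paths)))
  }
  vx <- config$voxel_size
  res <- list(out_dir = out_dir)

  # phantom (deterministic; always rebuilt in memory, artifacts written once)
  spec <- phantom_spec(config$grid_shape, config$voxel_size,
                       config$region_params, config$noise, config$seed)
  truth <- build_phantom(spec)
  res$truth <- truth
  pd <- file.path(out_dir, "phantom")
  if (config$stages$phantom && !cached("phantom/labels.nii")) {
    say("stage phantom: writing ground truth")
    dir.create(pd, showWarnings = FALSE)
    write_nifti_map(truth$label_volume, file.path(pd, "labels.nii"), vx)
    for (pn in names(truth$parameter_maps))
      write_nifti_map(truth$parameter_maps[[pn]],
                      file.path(pd, paste0(pn, ".nii")), vx)
    writeLines(config_json(config), file.path(pd, "spec.json"))
  }

  # raw-data simulation
  ase_path <- file.path(out_dir, "ase", "ase.nii")
  if (config$stages$ase) {
    if (cached("ase/ase.nii")) {
      say("stage ase: cached")
      res$ase <- read_ase_series(ase_path)
    } else {
      say("stage ase: simulating FLAIR-ASE")
      res$ase <- simulate_flair_ase(truth, config$taus_ms, config$TE_ms)
      dir.create(dirname(ase_path), showWarnings = FALSE)
      write_ase_series(res$ase, ase_path, vx)
    }
  }

  if (config$stages$qbold) {
    if (is.null(res$ase)) res$ase <- simulate_flair_ase(truth, config$taus_ms, config$TE_ms)
    say("stage qbold: fitting (", config$estimator, ")")
    thr <- do.call(failure_thresholds, config$thresholds)
    res$qbold <- if (config$estimator == "nls") {
      fit_nonlinear(res$ase, thresholds = thr)
    } else {
      fit_loglinear(res$ase, thresholds = thr)
    }
    say("  flagged voxels: ", sum(res$qbold$error_mask), " / ",
        length(res$qbold$error_mask))
    write_qbold_maps(res$qbold, file.path(out_dir, "qbold"), vx)
  }

  if (config$stages$perfusion) {
    say("stage perfusion: DSC + DWI analysis")
    dsc <- do.call(simulate_dsc, c(list(truth = truth), config$dsc))
    dwi <- simulate_dwi(truth, config$b_values)
    adc <- adc_from_dwi(dwi$data, dwi$b_values)
    labels <- truth$label_volume
    ref_mask <- labels > 0 & labels != PHANTOM_REGIONS[["enhancing"]] &
      labels != PHANTOM_REGIONS[["CSF"]]
    res$perfusion <- perfusion_maps(
      dsc, contra_wm_mask = phantom_region_mask(truth, "contra_WM"),
      brain_mask = labels > 0, reference_mask = ref_mask, adc = adc)
    res$adc <- adc
    dd <- file.path(out_dir, "perfusion")
    dir.create(dd, showWarnings = FALSE)
    for (f in c("cbv", "vessel_size", "K2"))
      write_nifti_map(res$perfusion[[f]], file.path(dd, paste0(f, ".nii")), vx)
    write_nifti_map(adc, file.path(dd, "adc.nii"), vx)
  }

  voi_set <- phantom_voi_masks(truth)
  err <- if (!is.null(res$qbold)) res$qbold$error_mask else NULL

  if (config$stages$voi && !is.null(res$ase) && !is.null(res$qbold)) {
    say("stage voi: curves and summaries")
    curves <- voi_curves(res$ase, voi_set, err)
    maps <- list(R2prime = res$qbold$R2prime, DBV = res$qbold$DBV,
                 OEF = res$qbold$OEF)
    if (!is.null(res$perfusion)) {
      maps$CBV <- res$perfusion$cbv
      maps$vessel_size <- res$perfusion$vessel_size
    }
    summ <- voi_summary(maps, voi_set, err)
    vd <- file.path(out_dir, "voi")
    dir.create(vd, showWarnings = FALSE)
    utils::write.csv(summ, file.path(vd, "summary.csv"), row.names = FALSE)
    curve_df <- do.call(rbind, lapply(curves, function(cu)
      data.frame(voi = cu$voi_name, tau_ms = cu$taus_ms,
                 mean_ln_signal = cu$mean_ln_signal,
                 sd_ln_signal = cu$sd_ln_signal,
                 baseline_offset = cu$baseline_offset)))
    utils::write.csv(curve_df, file.path(vd, "curves.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(vd, "curves.png"), width = 650, height = 500)
    plot_voi_curves(curves)
    grDevices::dev.off()
    res$voi <- list(curves = curves, summary = summ)
  }

  if (config$stages$targeting && !is.null(res$qbold) &&
      !is.null(res$perfusion)) {
    say("stage targeting: percentile clusters")
    search <- phantom_region_mask(truth, "nonenhancing") |
      phantom_region_mask(truth, "enhancing") |
      phantom_region_mask(truth, "necrosis")
    maps <- list(OEF = res$qbold$OEF, CBV = res$perfusion$cbv,
                 vessel_size = res$perfusion$vessel_size)
    sets <- list()
    for (mn in names(maps)) {
      cl <- list()
      for (pol in c("high", "low")) {
        crit <- cluster_criteria(mn, pol, config$high_pct, config$low_pct,
                                 config$min_voxels, config$cluster_shape)
        cl <- c(cl, find_clusters(maps[[mn]], crit, search, err))
      }
      sets[[mn]] <- cl
    }
    targets <- prioritize_targets(sets, dim(truth$label_volume),
                                  config$max_targets)
    ttab <- targets_table(targets, maps, truth$label_volume, err,
                          config$neighborhood,
                          affine = voxdim_affine(vx))
    td <- file.path(out_dir, "targets")
    dir.create(td, showWarnings = FALSE)
    utils::write.csv(ttab, file.path(td, "targets.csv"), row.names = FALSE)
    foot <- array(0L, dim(truth$label_volume))
    for (tg in targets) foot[tg$voxels] <- tg$priority_rank
    write_nifti_map(foot, file.path(td, "clusters.nii"), vx)
    res$targets <- targets
    res$targets_table <- ttab
    say("  targets: ", length(targets))
  }

  if (config$stages$histology && !is.null(res$targets_table) &&
      nrow(res$targets_table) > 0) {
    say("stage histology: simulated biopsies")
    cp <- config$coupling
    histo <- simulate_histology(truth, res$targets_table, coupling = cp)
    hd <- file.path(out_dir, "histology")
    dir.create(hd, showWarnings = FALSE)
    utils::write.csv(histo$table, file.path(hd, "histology.csv"),
                     row.names = FALSE)
    res$histology <- histo$table
  }

  if (config$stages$stats && !is.null(res$histology)) {
    say("stage stats: MRI vs histology")
    paired <- paired_measurements(res$targets_table, res$histology)
    utils::write.csv(paired, file.path(out_dir, "paired.csv"),
                     row.names = FALSE)
    res$stats <- stats_report(paired, out_dir = file.path(out_dir, "stats"))
    res$paired <- paired
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  md5 <- tools::md5sum(files)
  names(md5) <- sub(paste0("^", out_dir, "/?"), "", names(md5))
  manifest <- list(config_hash = unname(hash),
                   package_version = as.character(utils::packageVersion("hypoxmap")),
                   config = unclass(config),
                   files = as.list(md5))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
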