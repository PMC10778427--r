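# DSC perfusion: relaxation conversion, bolus detection, BSW correction,
# CBV normalization, ADC, vessel size.

make_perfusion <- function(sigma = 0, seed = 1L, grid = 24L) {
  truth <- tiny_truth(sigma = sigma, seed = seed, grid = grid)
  dsc <- simulate_dsc(truth)
  dwi <- simulate_dwi(truth)
  adc <- adc_from_dwi(dwi$data, dwi$b_values)
  labels <- truth$label_volume
  ref <- labels > 0 &
    labels != hypoxmap:::PHANTOM_REGIONS[["enhancing"]] &
    labels != hypoxmap:::PHANTOM_REGIONS[["CSF"]]
  pm <- perfusion_maps(dsc, phantom_region_mask(truth, "contra_WM"),
                       brain_mask = labels > 0, reference_mask = ref,
                       adc = adc)
  list(truth = truth, dsc = dsc, adc = adc, pm = pm, ref = ref)
}

test_that("delta_r2 inverts the exponential signal model", {
  # baseline signal -> 0; one-e-fold drop -> 1/TE
  Y <- matrix(100, 2, 40)
  Y[2, 30] <- 100 * exp(-1)
  d <- delta_r2(Y, baseline_range = 1:10, TE_ms = 18.6)
  expect_equal(d[1, ], rep(0, 40))
  expect_equal(d[2, 30], 1 / 0.0186, tolerance = 1e-10)
  expect_equal(d[2, 30], 53.76, tolerance = 1e-3)
  # non-positive samples are repaired by temporal interpolation
  Y2 <- matrix(100, 1, 40)
  Y2[1, 20] <- 0
  d2 <- delta_r2(Y2, 1:10, 18.6)
  expect_equal(attr(d2, "n_interpolated"), 1L)
  expect_equal(d2[1, 20], 0)
})

test_that("bolus window brackets the gamma-variate mass and rejects flats", {
  t <- (0:117) * 1.5
  curve <- 25 * gamma_variate(t, onset_s = 20, alpha = 3, beta_s = 1.5)
  w <- detect_bolus(curve)
  expect_true(w$t_in < w$t_peak && w$t_peak <= w$t_out)
  expect_true(max(w$baseline_range) < w$t_in)
  mass <- sum(hypoxmap:::trapz_weights(t, w$t_in:w$t_out) * curve)
  expect_gt(mass / sum(hypoxmap:::trapz_weights(t) * curve), 0.95)
  expect_error(detect_bolus(rep(3, 60)), "no bolus")
  expect_error(detect_bolus(curve[1:20]), ">= 30")
  # amplitude doubling leaves the entrance within one sample
  set.seed(1)
  noisy <- curve + rnorm(length(curve), 0, 0.3)
  noisy2 <- 2 * curve + rnorm(length(curve), 0, 0.3)
  expect_lte(abs(detect_bolus(noisy)$t_in - detect_bolus(noisy2)$t_in), 1)
})

test_that("BSW identities: zero leakage and reference-equal voxels", {
  t <- (0:99) * 1.5
  g <- gamma_variate(t, 20, 3, 1.5)
  amps <- c(10, 20, 15, 12, 18)
  Y <- outer(amps, g)
  ref_mask <- rep(TRUE, 5)
  out <- bsw_leakage_correct(Y, t, reference_mask = ref_mask)
  expect_lt(max(abs(out$K2)), 1e-6)
  expect_equal(out$corrected, Y, tolerance = 1e-8)
  # a voxel identical to the reference mean curve has K1 = 1, K2 = 0
  Y2 <- rbind(Y, colMeans(Y))
  out2 <- bsw_leakage_correct(Y2, t, reference_mask = c(ref_mask, FALSE))
  expect_equal(out2$K1[6], 1, tolerance = 1e-10)
  expect_equal(out2$K2[6], 0, tolerance = 1e-10)
  expect_error(bsw_leakage_correct(matrix(0, 3, 100), t,
                                   reference_mask = rep(TRUE, 3)),
               "degenerate")
})

test_that("noiseless phantom round trip recovers CBV, vessel size and K2", {
  mk <- make_perfusion(sigma = 0)
  truth <- mk$truth
  labels <- truth$label_volume
  tissue <- labels > 0 & labels != hypoxmap:::PHANTOM_REGIONS[["CSF"]]
  cbv_true <- truth$parameter_maps$CBV_true
  expect_lt(max(abs(mk$pm$cbv[tissue] - cbv_true[tissue])), 1e-3)
  vs_true <- truth$parameter_maps$vessel_size_true
  vsel <- tissue & is.finite(mk$pm$vessel_size)
  expect_equal(sum(vsel), sum(tissue))
  expect_lt(max(abs(mk$pm$vessel_size[vsel] - vs_true[vsel]) /
                  vs_true[vsel]), 0.01)
  # contra-WM self-normalization and exact K2 recovery
  wm <- phantom_region_mask(truth, "contra_WM")
  expect_equal(mean(mk$pm$cbv[wm]), 1, tolerance = 1e-9)
  enh <- phantom_region_mask(truth, "enhancing")
  expect_equal(unname(mean(mk$pm$K2[enh])),
               truth$spec$region_params$enhancing$leakage_K2,
               tolerance = 1e-6)
  expect_lt(max(abs(mk$pm$K2[mk$ref])), 1e-6)
})

test_that("BSW correction beats no correction on leaky voxels", {
  mk <- make_perfusion(sigma = 0)
  truth <- mk$truth
  g <- hypoxmap:::discard_volumes(mk$dsc$gre, mk$dsc$n_discard,
                                  mk$dsc$TR_s)
  dr2s <- delta_r2(g$Y, mk$pm$window$baseline_range, mk$dsc$TE_gre_ms)
  unc <- compute_cbv(dr2s, g$times, mk$pm$window,
                     phantom_region_mask(truth, "contra_WM"))$cbv
  enh <- which(phantom_region_mask(truth, "enhancing"))
  cbv_true <- truth$parameter_maps$CBV_true
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_gt(rmse(unc[enh], cbv_true[enh]), 0.1)     # injected bias is real
  expect_lt(rmse(as.vector(mk$pm$cbv)[enh], cbv_true[enh]),
            rmse(unc[enh], cbv_true[enh]))
  expect_lt(rmse(as.vector(mk$pm$cbv)[enh], cbv_true[enh]), 0.02 * 1.78)
})

test_that("normalized CBV is invariant to global intensity scaling", {
  mk <- make_perfusion(sigma = 0, grid = 24L)
  dsc2 <- dsc_series(mk$dsc$gre * 3.7, mk$dsc$se * 3.7, mk$dsc$TR_s,
                     mk$dsc$TE_gre_ms, mk$dsc$TE_se_ms, mk$dsc$n_discard)
  labels <- mk$truth$label_volume
  pm2 <- perfusion_maps(dsc2, phantom_region_mask(mk$truth, "contra_WM"),
                        brain_mask = labels > 0, reference_mask = mk$ref,
                        adc = mk$adc)
  ok <- is.finite(mk$pm$cbv)
  expect_equal(pm2$cbv[ok], mk$pm$cbv[ok], tolerance = 1e-9)
})

test_that("recovery degrades gracefully at 2% noise", {
  mk <- make_perfusion(sigma = 0.02, seed = 9L, grid = 24L)
  truth <- mk$truth
  labels <- truth$label_volume
  tissue <- labels > 0 & labels != hypoxmap:::PHANTOM_REGIONS[["CSF"]]
  cbv_true <- truth$parameter_maps$CBV_true
  rel_cbv <- abs(mk$pm$cbv[tissue] - cbv_true[tissue]) / cbv_true[tissue]
  expect_lt(median(rel_cbv, na.rm = TRUE), 0.05)
  expect_lt(median(abs(mk$pm$cbv[tissue] - cbv_true[tissue]), na.rm = TRUE),
            0.05)
  # vessel size is peak-amplitude limited: its documented noise-robustness
  # bound at this SNR is 7.5% (see the methods vignette)
  vs_true <- truth$parameter_maps$vessel_size_true
  rel_vs <- abs(mk$pm$vessel_size[tissue] - vs_true[tissue]) /
    vs_true[tissue]
  expect_lt(median(rel_vs, na.rm = TRUE), 0.075)
})

test_that("ADC closed forms and input contracts", {
  # two-point closed form: S ratio e^-1 over b = 1000
  Y <- matrix(c(100, 100 * exp(-1)), 1, 2)
  expect_equal(adc_from_dwi(Y, c(0, 1000)), 1e-3, tolerance = 1e-12)
  expect_error(adc_from_dwi(Y, c(10, 1000)), "include 0")
  expect_error(adc_from_dwi(Y, c(0, 0)), "distinct")
  Yneg <- matrix(c(100, 0), 1, 2)
  expect_true(is.na(adc_from_dwi(Yneg, c(0, 1000))))
})

test_that("vessel size follows the Kiselev relation and its scalings", {
  # direct arithmetic: CBV 1, ADC 1e-3, peaks 30 / 10 -> 26.0 um
  expect_equal(vessel_size_map(1, 1e-3, 30, 10),
               0.867 * sqrt(1e-3) * 30 / 10^1.5 * 1000, tolerance = 1e-12)
  expect_equal(vessel_size_map(1, 1e-3, 30, 10), 26.0, tolerance = 0.05)
  # quadrupling CBV doubles vessel size
  expect_equal(vessel_size_map(4, 1e-3, 30, 10),
               2 * vessel_size_map(1, 1e-3, 30, 10), tolerance = 1e-12)
  expect_true(is.na(vessel_size_map(1, 1e-3, 30, 0)))
  expect_true(is.na(vessel_size_map(0.01, 1e-3, 30, 10)))
})
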