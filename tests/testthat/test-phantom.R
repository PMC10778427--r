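# Phantom construction and forward simulators.

test_that("phantom labels and parameter maps agree with the spec exactly", {
  truth <- tiny_truth()
  labs <- truth$label_volume
  for (rn in c("contra_GM", "contra_WM", "CSF", "edema", "nonenhancing",
               "enhancing", "necrosis")) {
    sel <- phantom_region_mask(truth, rn)
    expect_gt(sum(sel), 0)
    p <- truth$spec$region_params[[rn]]
    expect_identical(unique(truth$parameter_maps$R2prime[sel]), p$R2prime)
    expect_identical(unique(truth$parameter_maps$DBV[sel]), p$DBV)
    expect_identical(unique(truth$parameter_maps$CBV_true[sel]), p$CBV_true)
  }
  # contra-GM ground truth carries the published group mean
  expect_equal(unique(truth$parameter_maps$R2prime[
    phantom_region_mask(truth, "contra_GM")]), 5.13)
  # tumor nesting: necrosis and enhancing lie inside the edema envelope
  env <- phantom_region_mask(truth, "edema") |
    phantom_region_mask(truth, "enhancing") |
    phantom_region_mask(truth, "necrosis")
  comp <- hypoxmap:::label_components_3d(env)
  expect_equal(max(comp), 1L)
})

test_that("phantom spec validation rejects inconsistent parameters", {
  bad <- default_region_params()
  bad$contra_GM$DBV <- 1.2
  expect_error(tiny_spec(regions = bad), "DBV")
  noWM <- default_region_params()
  noWM$contra_WM <- NULL
  expect_error(tiny_spec(regions = noWM), "contra_WM")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "16")
})

test_that("simulators are bit-identical under a repeated seed", {
  truth <- tiny_truth(sigma = 0.02, seed = 11L)
  expect_identical(build_phantom(tiny_spec(sigma = 0.02, seed = 11L)),
                   truth)
  a1 <- simulate_flair_ase(truth)
  a2 <- simulate_flair_ase(truth)
  expect_identical(a1$data, a2$data)
  d1 <- simulate_dsc(truth)
  d2 <- simulate_dsc(truth)
  expect_identical(d1$gre, d2$gre)
  expect_identical(d1$se, d2$se)
  w1 <- simulate_dwi(truth)
  expect_identical(w1$data, simulate_dwi(truth)$data)
  # different seed changes the noise
  expect_false(identical(
    a1$data, simulate_flair_ase(truth, seed = 12L)$data))
})

test_that("noiseless FLAIR-ASE signal follows the piecewise decay", {
  truth <- tiny_truth()
  ase <- simulate_flair_ase(truth)
  # tau = 0 limit: S = S0 exp(-R2 TE)
  gm <- which(phantom_region_mask(truth, "contra_GM"))[1]
  p <- truth$spec$region_params$contra_GM
  s_tau0 <- matrix(ase$data, length(truth$label_volume),
                   length(ase$taus_ms))[gm, 1]
  expect_equal(s_tau0, p$S0 * exp(-p$R2 * 0.074), tolerance = 1e-12)
  # linear branch: R2'=4, DBV=0.05 at tau=40 ms gives DBV - R2' tau = -0.11
  reg <- default_region_params()
  reg$contra_WM$R2prime <- 4
  reg$contra_WM$DBV <- 0.05
  tr2 <- build_phantom(tiny_spec(regions = reg))
  a2 <- simulate_flair_ase(tr2)
  wm <- which(phantom_region_mask(tr2, "contra_WM"))[1]
  lnS <- log(matrix(a2$data, length(tr2$label_volume),
                    length(a2$taus_ms))[wm, ])
  j40 <- match(40, a2$taus_ms)
  p2 <- reg$contra_WM
  expect_equal(lnS[j40],
               log(p2$S0) - p2$R2 * 0.074 + 0.05 - 4 * 0.040,
               tolerance = 1e-12)
  expect_equal(lnS[j40], oracle_ln_signal(40, p2$S0, p2$R2, 74, 4, 0.05),
               tolerance = 1e-12)
  # strictly decreasing over the linear regime wherever R2' > 0
  lin <- a2$taus_ms >= 16
  for (rn in c("contra_GM", "enhancing", "necrosis")) {
    v <- which(phantom_region_mask(tr2, rn))[1]
    lnv <- log(matrix(a2$data, length(tr2$label_volume),
                      length(a2$taus_ms))[v, lin])
    expect_true(all(diff(lnv) < 0))
  }
})

test_that("FLAIR-ASE input contracts are enforced", {
  truth <- tiny_truth()
  expect_error(simulate_flair_ase(truth, taus_ms = c(16, 20)), "include 0")
  expect_error(simulate_flair_ase(truth, taus_ms = c(0, -4, 16)), "> 0")
  expect_error(simulate_flair_ase(truth, taus_ms = c(0, 16, 60),
                                  TE_ms = 50), "exceed")
})

test_that("DWI simulation is mono-exponential and ADC recovery is exact", {
  truth <- tiny_truth()
  dwi <- simulate_dwi(truth, b_values = c(0, 10, 1000))
  dm <- dim(truth$label_volume)
  Y <- matrix(dwi$data, prod(dm), 3)
  gm <- which(phantom_region_mask(truth, "contra_GM"))[1]
  adc_gm <- truth$spec$region_params$contra_GM$ADC
  expect_equal(Y[gm, 3] / Y[gm, 1], exp(-1000 * adc_gm), tolerance = 1e-12)
  expect_equal(Y[gm, 1], truth$spec$region_params$contra_GM$S0)
  adc <- adc_from_dwi(dwi$data, dwi$b_values)
  brain <- truth$label_volume > 0
  expect_lt(max(abs(adc[brain] - truth$parameter_maps$ADC[brain]) /
                  truth$parameter_maps$ADC[brain]), 1e-9)
  # CSF exceeds every tissue compartment by construction
  expect_gt(min(adc[phantom_region_mask(truth, "CSF")]),
            max(adc[brain & !phantom_region_mask(truth, "CSF")]))
  expect_error(simulate_dwi(truth, b_values = c(0, -5)), ">= 0")
})

test_that("rician and gaussian noise models differ and respect sigma = 0", {
  truth_g <- tiny_truth(sigma = 0.03, seed = 5L)
  truth_r <- build_phantom(tiny_spec(sigma = 0.03, seed = 5L,
                                     model = "rician"))
  ag <- simulate_flair_ase(truth_g)
  ar <- simulate_flair_ase(truth_r)
  expect_false(identical(ag$data, ar$data))
  expect_true(all(ar$data >= 0))
  a0 <- simulate_flair_ase(tiny_truth(sigma = 0))
  expect_identical(a0$data, simulate_flair_ase(tiny_truth(sigma = 0))$data)
})

test_that("histology simulation couples monotonically to the ground truth", {
  truth <- tiny_truth()
  # targets scattered over tumor compartments with distinct ground truths
  pick <- function(rn, n) {
    idx <- which(phantom_region_mask(truth, rn))[seq_len(n)]
    arrayInd(idx, dim(truth$label_volume))
  }
  vox <- rbind(pick("nonenhancing", 4), pick("enhancing", 4),
               pick("necrosis", 3))
  targets <- data.frame(x = vox[, 1], y = vox[, 2], z = vox[, 3])
  noise0 <- list(diameter = c(0, 1), density = c(0, 0.02),
                 hif = c(0, 250), noise_sd = c(0, 0, 0))
  h <- simulate_histology(truth, targets, coupling = noise0)
  expect_equal(nrow(h$table), 11L)
  # brute-force oracle for the local (3x3x3, boundary-clipped) truth means
  local_mean <- function(map, v) {
    dm <- dim(map)
    mean(map[max(1, v[1] - 1):min(dm[1], v[1] + 1),
             max(1, v[2] - 1):min(dm[2], v[2] + 1),
             max(1, v[3] - 1):min(dm[3], v[3] + 1)])
  }
  wm_ref <- truth$spec$region_params$contra_WM$CBV_true
  vs <- apply(vox, 1, function(v)
    local_mean(truth$parameter_maps$vessel_size_true, v))
  expect_equal(h$table$vessel_diameter, pmax(vs, 0.5), tolerance = 1e-12)
  expect_equal(suppressWarnings(
    cor(h$table$vessel_diameter, vs, method = "spearman")), 1)
  cbv <- apply(vox, 1, function(v)
    local_mean(truth$parameter_maps$CBV_true, v)) / wm_ref
  expect_equal(suppressWarnings(
    cor(h$table$vessel_density, cbv, method = "spearman")), 1)
  # single target -> one fully populated row
  h1 <- simulate_histology(truth, targets[1, , drop = FALSE],
                           coupling = noise0)
  expect_equal(nrow(h1$table), 1L)
  expect_true(all(is.finite(unlist(
    h1$table[, c("vessel_density", "vessel_diameter", "hif_score")]))))
  expect_error(simulate_histology(truth, targets[0, ]), "non-empty")
})

test_that("null histology coupling induces no correlation on average", {
  truth <- tiny_truth()
  tumor <- which(truth$label_volume %in%
                   hypoxmap:::PHANTOM_REGIONS[c("nonenhancing",
                                                "enhancing", "necrosis")])
  idx <- tumor[round(seq(1, length(tumor), length.out = 12))]
  vox <- arrayInd(idx, dim(truth$label_volume))
  targets <- data.frame(x = vox[, 1], y = vox[, 2], z = vox[, 3])
  null_cp <- list(diameter = c(10, 0), density = c(0.02, 0),
                  hif = c(100, 0), noise_sd = c(2, 0.005, 30))
  vs <- truth$parameter_maps$vessel_size_true[vox]
  rs <- vapply(seq_len(200), function(s) {
    h <- simulate_histology(truth, targets, coupling = null_cp, seed = s)
    suppressWarnings(cor(h$table$vessel_diameter, vs, method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})
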