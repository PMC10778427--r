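# Percentile cluster detection, cross-metric prioritization, neighborhood
# value extraction.

plant_block <- function(map, at, size = 3L, value = 10) {
  idx <- lapply(seq_len(3), function(k) at[k] + seq_len(size) - 1L)
  map[idx[[1]], idx[[2]], idx[[3]]] <- value
  map
}

test_that("a planted hot block is found as exactly one cluster", {
  dm <- c(16, 16, 16)
  map <- array(0, dm)
  map <- plant_block(map, c(5, 5, 5), 3L, 50)
  mask <- array(TRUE, dm)
  crit <- cluster_criteria("OEF", "high")
  cl <- find_clusters(map, crit, mask)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$size, 27L)
  expect_true(all(map[cl[[1]]$voxels] == 50))
})

test_that("a 9-voxel line fails the compact-block rule", {
  dm <- c(16, 16, 16)
  map <- array(0, dm)
  map[4:12, 8, 8] <- 100
  mask <- array(TRUE, dm)
  cl <- find_clusters(map, cluster_criteria("CBV", "high"), mask)
  expect_equal(length(cl), 0L)
  # same voxel count arranged as a plane passes under the plane33 rule
  map2 <- array(0, dm)
  map2[4:6, 6:8, 8] <- 100
  cl2 <- find_clusters(map2, cluster_criteria("CBV", "high",
                                              shape = "plane33"), mask)
  expect_equal(length(cl2), 1L)
  cl3 <- find_clusters(map2, cluster_criteria("CBV", "high"), mask)
  expect_equal(length(cl3), 0L)  # no 2x2x2 block in a single slice
})

test_that("cluster voxels satisfy the percentile predicate (brute force)", {
  set.seed(7)
  for (rep in 1:5) {
    dm <- c(12, 12, 12)
    map <- array(rnorm(prod(dm)), dm)
    # add spatial structure so compact clusters exist
    map <- plant_block(map, c(2 + rep, 3, 4), 3L, 5 + rep)
    map <- plant_block(map, c(7, 8, 6), 2L, -8)
    mask <- array(runif(prod(dm)) < 0.8, dm)
    err <- array(runif(prod(dm)) < 0.1, dm) * 1L
    for (pol in c("high", "low")) {
      crit <- cluster_criteria("OEF", pol, min_voxels = 4L)
      cl <- find_clusters(map, crit, mask, err)
      vals <- map[mask & !(err > 0)]
      thr <- quantile(vals, if (pol == "high") 0.8 else 0.2, type = 7,
                      names = FALSE)
      for (c1 in cl) {
        vv <- map[c1$voxels]
        if (pol == "high") expect_true(all(vv > thr))
        else expect_true(all(vv < thr))
        expect_false(any(err[c1$voxels] > 0))
        expect_false(any(!mask[c1$voxels]))
      }
    }
  }
})

test_that("overlapping clusters across metrics merge into rank 1", {
  dm <- c(16, 16, 16)
  base <- array(0, dm)
  oef <- plant_block(base, c(4, 4, 4), 3L, 10)
  cbv <- plant_block(base, c(4, 4, 4), 3L, 10)   # full overlap with OEF
  vs <- plant_block(base, c(11, 11, 11), 3L, 10) # disjoint
  mask <- array(TRUE, dm)
  sets <- list(
    OEF = find_clusters(oef, cluster_criteria("OEF", "high"), mask),
    CBV = find_clusters(cbv, cluster_criteria("CBV", "high"), mask),
    vessel_size = find_clusters(vs, cluster_criteria("vessel_size", "high"),
                                mask))
  tg <- prioritize_targets(sets, dm)
  expect_equal(length(tg), 2L)
  expect_equal(tg[[1]]$priority_rank, 1L)
  expect_equal(nrow(tg[[1]]$defining_criteria), 2L)
  expect_setequal(tg[[1]]$defining_criteria$metric, c("OEF", "CBV"))
  expect_equal(tg[[2]]$defining_criteria$metric, "vessel_size")
  # the rank-1 center is the centroid voxel of the planted block
  expect_equal(unname(tg[[1]]$center_voxel), c(5, 5, 5))
})

test_that("metric precedence breaks ties between disjoint clusters", {
  dm <- c(16, 16, 16)
  base <- array(0, dm)
  oef <- plant_block(base, c(4, 4, 4), 3L, 10)
  cbv <- plant_block(base, c(10, 10, 10), 3L, 10)
  mask <- array(TRUE, dm)
  sets <- list(
    OEF = find_clusters(oef, cluster_criteria("OEF", "high"), mask),
    CBV = find_clusters(cbv, cluster_criteria("CBV", "high"), mask))
  tg <- prioritize_targets(sets, dm)
  expect_equal(tg[[1]]$defining_criteria$metric, "OEF")
  expect_equal(tg[[2]]$defining_criteria$metric, "CBV")
  # permuting the input cluster lists does not change the ranking
  sets_perm <- list(CBV = rev(sets$CBV), OEF = sets$OEF)
  tg2 <- prioritize_targets(sets_perm, dm)
  expect_equal(lapply(tg2, `[[`, "center_voxel"),
               lapply(tg, `[[`, "center_voxel"))
})

test_that("max_targets truncates the ranked list to surgical practice", {
  dm <- c(24, 24, 24)
  base <- array(0, dm)
  mask <- array(TRUE, dm)
  m <- base
  for (i in 0:4) m <- plant_block(m, c(1 + 4 * i, 3, 3), 3L, 10 + i)
  sets <- list(OEF = find_clusters(m, cluster_criteria("OEF", "high"),
                                   mask))
  expect_equal(length(sets$OEF), 5L)
  tg <- prioritize_targets(sets, dm, max_targets = 4L)
  expect_equal(length(tg), 4L)
  expect_equal(vapply(tg, `[[`, integer(1), "priority_rank"), 1:4)
  # truncation honors rank order: the most extreme cluster survives
  expect_equal(tg[[1]]$defining_criteria$metric, "OEF")
  expect_equal(unname(m[matrix(tg[[1]]$center_voxel, 1)]), 14)
})

test_that("edema never hosts a target when excluded from the search mask", {
  truth <- tiny_truth(sigma = 0.01, seed = 13L)
  set.seed(13)
  oef <- array(rnorm(length(truth$label_volume), sd = 0.01),
               dim(truth$label_volume))
  search <- phantom_region_mask(truth, "nonenhancing") |
    phantom_region_mask(truth, "enhancing") |
    phantom_region_mask(truth, "necrosis")
  # hot 2x2x2 blob planted fully inside the search mask
  interior <- which(vapply(which(search), function(i) {
    v <- arrayInd(i, dim(search))
    all(v + 1 <= dim(search)) && all(search[v[1] + 0:1, v[2] + 0:1,
                                            v[3] + 0:1])
  }, logical(1)))
  ctr <- arrayInd(which(search)[interior[1]], dim(search))
  oef[ctr[1] + 0:1, ctr[2] + 0:1, ctr[3] + 0:1] <- 5
  cl <- find_clusters(oef, cluster_criteria("OEF", "high",
                                            min_voxels = 8L), search)
  tg <- prioritize_targets(list(OEF = cl), dim(truth$label_volume))
  expect_gte(length(tg), 1L)
  edema <- phantom_region_mask(truth, "edema")
  for (t1 in tg) {
    expect_false(edema[matrix(t1$center_voxel, 1)])
    expect_false(any(edema[t1$voxels]))
  }
})

test_that("neighborhood means match the brute-force average", {
  set.seed(5)
  dm <- c(10, 10, 10)
  map <- array(rnorm(prod(dm)), dm)
  tg <- list(center_voxel = c(5, 6, 7))
  out <- extract_target_values(list(m = map), tg)
  expect_equal(unname(out["m"]), mean(map[4:6, 5:7, 6:8]))
  # constant map returns the constant
  outc <- extract_target_values(list(m = array(3.3, dm)), tg)
  expect_equal(unname(outc["m"]), 3.3)
  # grid corner clips to the in-bounds 8 voxels
  tgc <- list(center_voxel = c(1, 1, 1))
  outk <- extract_target_values(list(m = map), tgc)
  expect_equal(unname(outk["m"]), mean(map[1:2, 1:2, 1:2]))
  # flagged voxels are excluded; fully flagged neighborhoods annotate NA
  err <- array(0L, dm); err[4:6, 5:7, 6:8] <- 1L
  out2 <- extract_target_values(list(m = map), tg, error_mask = err)
  expect_true(is.na(out2["m"]))
  expect_true(attr(out2, "all_flagged"))
  err2 <- array(0L, dm); err2[5, 6, 7] <- 1L
  out3 <- extract_target_values(list(m = map), tg, error_mask = err2)
  nb <- map[4:6, 5:7, 6:8]
  expect_equal(unname(out3["m"]), mean(nb[-14]))
  # the ten-voxel reading: center plus its nearest neighbors
  out10 <- extract_target_values(list(m = map), tg,
                                 neighborhood = "center10")
  expect_false(isTRUE(all.equal(unname(out10["m"]), unname(out["m"]))))
  expect_error(extract_target_values(list(m = map),
                                     list(center_voxel = c(99, 1, 1))),
               "bounds")
})
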