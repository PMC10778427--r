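# Biopsy target selection: percentile-defined clusters on OEF / CBV /
# vessel-size maps, cross-metric prioritization, and neighborhood-averaged
# MRI values at target voxels.

#' Criteria defining percentile clusters
#'
#' A cluster is a 26-connected component of voxels above the `high_pct`
#' percentile (polarity "high") or below the `low_pct` percentile
#' (polarity "low"), computed over the unflagged voxels of the search mask,
#' containing at least `min_voxels` voxels and one full compact block. The
#' compactness rule ("arranged cubically") has two readings, selectable via
#' `shape`: a 2x2x2 block ("block222", default) or a 3x3 in-plane square
#' ("plane33").
#'
#' @param metric one of "OEF", "CBV", "vessel_size".
#' @param polarity "high" or "low".
#' @param high_pct,low_pct percentile cutoffs (default 80 / 20).
#' @param min_voxels minimum component size (default 9).
#' @param shape compact-block rule, see above.
#' @export
cluster_criteria <- function(metric = c("OEF", "CBV", "vessel_size"),
                             polarity = c("high", "low"),
                             high_pct = 80, low_pct = 20,
                             min_voxels = 9L,
                             shape = c("block222", "plane33")) {
  list(metric = match.arg(metric), polarity = match.arg(polarity),
       high_pct = high_pct, low_pct = low_pct,
       min_voxels = as.integer(min_voxels), shape = match.arg(shape))
}

#' Find percentile-defined clusters on a map
#'
#' The percentile is computed over the finite, unflagged voxels of the
#' search mask (by protocol the tumor compartments excluding edema, where
#' biopsies are prohibited); thresholding is strict (> for high, < for
#' low). Components are 26-connected and kept if they have at least
#' `min_voxels` voxels and contain the required compact block. Clusters are
#' ordered by mean extremity (most extreme mean first), deterministically.
#'
#' @param map 3D metric array.
#' @param criteria a [cluster_criteria()].
#' @param search_mask logical/0-1 3D array (non-empty).
#' @param error_mask optional binary exclusion array.
#' @return list of clusters; each has `voxels` (n x 3 index matrix),
#'   `metric`, `polarity`, `mean_value`, `threshold`, `size`. Empty list
#'   when nothing qualifies.
#' @export
find_clusters <- function(map, criteria, search_mask, error_mask = NULL) {
  sel_mask <- search_mask > 0
  if (!any(sel_mask)) stop_input("search mask is empty")
  if (!is.null(error_mask)) sel_mask <- sel_mask & !(error_mask > 0)
  valid <- sel_mask & is.finite(map)
  vals <- map[valid]
  if (!length(vals)) return(list())
  if (criteria$polarity == "high") {
    thr <- pctl(vals, criteria$high_pct / 100)
    hot <- valid & (map > thr)
  } else {
    thr <- pctl(vals, criteria$low_pct / 100)
    hot <- valid & (map < thr)
  }
  labels <- label_components_3d(hot)
  k <- max(labels)
  out <- list()
  for (i in seq_len(k)) {
    comp <- labels == i
    if (sum(comp) < criteria$min_voxels) next
    okshape <- if (criteria$shape == "block222") has_block_222(comp)
               else has_block_33_inplane(comp)
    if (!okshape) next
    vox <- arrayInd(which(comp), dim(map))
    colnames(vox) <- c("x", "y", "z")
    out[[length(out) + 1L]] <- list(
      voxels = vox, metric = criteria$metric, polarity = criteria$polarity,
      mean_value = mean(map[comp]), threshold = thr, size = sum(comp))
  }
  if (length(out) > 1L) {
    extremity <- vapply(out, function(cl) {
      if (cl$polarity == "high") cl$mean_value else -cl$mean_value
    }, numeric(1))
    out <- out[order(-extremity,
                     vapply(out, function(cl)
                       min(cl$voxels[, 1] +
                             (cl$voxels[, 2] - 1) * dim(map)[1] +
                             (cl$voxels[, 3] - 1) * prod(dim(map)[1:2])),
                       numeric(1)))]
  }
  out
}

METRIC_ORDER <- c(OEF = 1L, CBV = 2L, vessel_size = 3L)

# linear voxel indices of a cluster on grid dm
cluster_lin <- function(cl, dm) {
  cl$voxels[, 1] + (cl$voxels[, 2] - 1L) * dm[1] +
    (cl$voxels[, 3] - 1L) * prod(dm[1:2])
}

#' Merge and rank clusters across metrics into biopsy targets
#'
#' Metrics are considered in the protocol order OEF, then CBV, then vessel
#' size. Clusters from different metrics that share voxels are merged into
#' one candidate whose defining criteria accumulate; candidates spanning
#' more metrics rank first, then larger cross-metric voxel overlap, then
#' earlier metric precedence, then mean extremity. The target center is the
#' component centroid snapped to the nearest in-cluster voxel. The ranking
#' is independent of input list order.
#'
#' @param cluster_sets named list of cluster lists from [find_clusters()],
#'   names among "OEF", "CBV", "vessel_size".
#' @param dim_grid grid dimensions (length 3).
#' @param max_targets optional truncation of the ranked list (surgical
#'   practice: 2-4 targets per subject).
#' @return list of `biopsy_target`s: `center_voxel`, `cluster_id`,
#'   `defining_criteria` (data frame metric/polarity), `priority_rank`,
#'   `voxels`, `n_overlap`.
#' @export
prioritize_targets <- function(cluster_sets, dim_grid, max_targets = NULL) {
  keep <- intersect(names(METRIC_ORDER), names(cluster_sets))
  clusters <- list()
  for (mn in keep) {
    set <- cluster_sets[[mn]]
    # deterministic intra-metric order regardless of caller's list order
    if (length(set) > 1L) {
      ext <- vapply(set, function(cl)
        if (cl$polarity == "high") cl$mean_value else -cl$mean_value,
        numeric(1))
      minlin <- vapply(set, function(cl) min(cluster_lin(cl, dim_grid)),
                       numeric(1))
      set <- set[order(-ext, minlin)]
    }
    clusters <- c(clusters, set)
  }
  n <- length(clusters)
  if (n == 0L) return(list())
  lin <- lapply(clusters, cluster_lin, dm = dim_grid)

  # union-find over cross-metric overlaps
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (clusters[[i]]$metric == clusters[[j]]$metric) next
    if (length(intersect(lin[[i]], lin[[j]]))) {
      rj <- find(j)
      ri <- find(i)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)

  cands <- lapply(unname(groups), function(idx) {
    mem <- clusters[idx]
    vox_lin <- sort(unique(unlist(lin[idx])))
    metrics <- vapply(mem, `[[`, character(1), "metric")
    overlap <- 0L
    if (length(idx) > 1L) {
      tab <- table(unlist(lapply(lin[idx], unique)))
      overlap <- sum(tab >= 2L)
    }
    crit <- unique(data.frame(
      metric = metrics,
      polarity = vapply(mem, `[[`, character(1), "polarity")))
    ext <- max(vapply(mem, function(cl)
      if (cl$polarity == "high") cl$mean_value else -cl$mean_value,
      numeric(1)))
    vox <- arrayInd(vox_lin, dim_grid)
    colnames(vox) <- c("x", "y", "z")
    ctr <- colMeans(vox)
    d2 <- rowSums((vox - matrix(ctr, nrow(vox), 3, byrow = TRUE))^2)
    center <- vox[order(d2, vox_lin)[1], ]
    list(center_voxel = center, defining_criteria = crit,
         voxels = vox, n_overlap = overlap,
         n_metrics = length(unique(metrics)),
         best_metric = min(METRIC_ORDER[unique(metrics)]),
         extremity = ext,
         min_lin = vox_lin[1])
  })
  ord <- order(
    -vapply(cands, `[[`, integer(1), "n_metrics"),
    -vapply(cands, `[[`, integer(1), "n_overlap"),
    vapply(cands, `[[`, integer(1), "best_metric"),
    -vapply(cands, `[[`, numeric(1), "extremity"),
    vapply(cands, `[[`, numeric(1), "min_lin"))
  cands <- cands[ord]
  if (!is.null(max_targets)) cands <- cands[seq_len(min(max_targets, length(cands)))]
  for (i in seq_along(cands)) {
    cands[[i]]$priority_rank <- i
    cands[[i]]$cluster_id <- sprintf("T%02d", i)
    class(cands[[i]]) <- "biopsy_target"
  }
  cands
}

#' Neighborhood-averaged MRI values at a biopsy target
#'
#' The mean over the target voxel's 3D neighborhood, clipped at the grid
#' boundary and excluding flagged voxels. The default neighborhood is the
#' full 3x3x3 cube (27 voxels including the center); `"center10"` restricts
#' it to the center plus its 9 nearest neighbors by Euclidean distance (the
#' 6 face voxels and 3 of the edge voxels), the literal ten-voxel reading.
#'
#' @param maps named list of 3D arrays (e.g. OEF, CBV, vessel_size).
#' @param target a `biopsy_target` (or list with `center_voxel`).
#' @param error_mask optional binary exclusion array.
#' @param neighborhood "cube27" (default) or "center10".
#' @return named numeric vector of neighborhood means; NA with attribute
#'   `all_flagged = TRUE` for metrics whose whole neighborhood is excluded.
#' @export
extract_target_values <- function(maps, target, error_mask = NULL,
                                  neighborhood = c("cube27", "center10")) {
  neighborhood <- match.arg(neighborhood)
  dm <- dim(maps[[1]])
  ctr <- as.integer(target$center_voxel)
  if (any(ctr < 1L) || any(ctr > dm))
    stop_input("target center outside map bounds")
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  if (neighborhood == "center10") {
    d <- sqrt(rowSums(offs^2))
    offs <- offs[order(d, offs[, 1], offs[, 2], offs[, 3]), ][1:10, ]
  }
  pts <- sweep(offs, 2L, ctr, `+`)
  inb <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
    pts[, 2] >= 1 & pts[, 2] <= dm[2] &
    pts[, 3] >= 1 & pts[, 3] <= dm[3]
  pts <- pts[inb, , drop = FALSE]
  lin <- pts[, 1] + (pts[, 2] - 1L) * dm[1] + (pts[, 3] - 1L) * prod(dm[1:2])
  if (!is.null(error_mask)) lin <- lin[!(as.vector(error_mask)[lin] > 0)]
  out <- vapply(maps, function(m) {
    v <- as.vector(m)[lin]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  attr(out, "all_flagged") <- length(lin) == 0L
  out
}

#' Tabulate ranked targets with their neighborhood-averaged MRI values
#'
#' @param targets list from [prioritize_targets()].
#' @param maps named list of metric arrays for [extract_target_values()].
#' @param label_volume optional integer region-label array used to annotate
#'   each target's VOI.
#' @param error_mask optional binary exclusion array.
#' @param neighborhood passed to [extract_target_values()].
#' @param affine optional 4x4 voxel-to-world matrix adding world
#'   coordinates.
#' @return data frame, one row per target.
#' @export
targets_table <- function(targets, maps, label_volume = NULL,
                          error_mask = NULL, neighborhood = "cube27",
                          affine = NULL) {
  if (!length(targets)) {
    return(data.frame(cluster_id = character(), rank = integer(),
                      x = integer(), y = integer(), z = integer()))
  }
  rows <- lapply(targets, function(tg) {
    vals <- extract_target_values(maps, tg, error_mask, neighborhood)
    row <- data.frame(cluster_id = tg$cluster_id, rank = tg$priority_rank,
                      x = tg$center_voxel[1], y = tg$center_voxel[2],
                      z = tg$center_voxel[3],
                      criteria = paste(tg$defining_criteria$metric,
                                       tg$defining_criteria$polarity,
                                       sep = ":", collapse = ";"),
                      n_voxels = nrow(tg$voxels))
    for (mn in names(vals)) row[[mn]] <- vals[[mn]]
    if (!is.null(label_volume)) {
      lab <- label_volume[tg$center_voxel[1], tg$center_voxel[2],
                          tg$center_voxel[3]]
      row$voi_label <- names(PHANTOM_REGIONS)[match(lab, PHANTOM_REGIONS)]
    }
    if (!is.null(affine)) {
      wc <- affine %*% c(tg$center_voxel - 1L, 1)
      row$wx <- wc[1]; row$wy <- wc[2]; row$wz <- wc[3]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
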