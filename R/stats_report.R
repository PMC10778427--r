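# Statistical comparison of MRI-derived and histological measurements:
# Kruskal-Wallis across VOIs, Mann-Whitney post hoc pairs, Spearman
# MRI-vs-histology correlations, and the results bundle with plots.
#
# No multiple-testing correction is applied anywhere in this module: the
# pairwise p-values are reported raw, exactly as they are annotated on the
# bar plots.

#' Kruskal-Wallis H test across groups
#'
#' Rank-based H with tie correction and a chi-square p-value on k-1
#' degrees of freedom. Fully tied data (all values equal) are the H = 0,
#' p = 1 degenerate case.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length; every group must
#'   have >= 2 observations and there must be >= 2 groups.
#' @return list with `H`, `p`, `df`, `n`.
#' @export
kw_test <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  tab <- table(groups)
  if (length(tab) < 2L)
    stop_input("need >= 2 groups")
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop_input("group(s) with < 2 observations: ",
               paste(small, collapse = ", "))
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = length(tab) - 1L, n = length(values)))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' Mann-Whitney U tests for all group pairs
#'
#' Two-sided; exact enumeration when both groups have <= 8 observations
#' and no ties, otherwise the tie-corrected normal approximation (with
#' continuity correction).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return data frame with group1, group2, U, p, n1, n2.
#' @export
mw_test_pairs <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  lv <- levels(groups)
  rows <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j <= i) next
    x <- values[groups == lv[i]]
    y <- values[groups == lv[j]]
    if (!length(x) || !length(y)) next
    ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- length(x) <= 8L && length(y) <= 8L && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = use_exact, correct = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = lv[i], group2 = lv[j],
      U = unname(wt$statistic), p = wt$p.value,
      n1 = length(x), n2 = length(y))
  }
  do.call(rbind, rows)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; p-value from the t approximation. Zero variance
#' in either vector makes r undefined (reported as NA, not an error).
#'
#' @param x,y numeric vectors; pairs with missing values are dropped (and
#'   counted in `n_dropped`).
#' @param alpha significance threshold for the `significant` flag.
#' @return list with `r`, `p`, `n`, `n_dropped`, `significant`.
#' @export
spearman_test <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_input("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                n_dropped = n_dropped, significant = NA))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       n_dropped = n_dropped, significant = ct$p.value < alpha)
}

MRI_HISTO_PAIRS <- list(
  c(mri = "OEF", histo = "hif_score"),
  c(mri = "CBV", histo = "vessel_density"),
  c(mri = "vessel_size", histo = "vessel_diameter"))

#' Joined MRI/histology comparison table
#'
#' @param targets data frame from [targets_table()] (one row per biopsy
#'   with neighborhood-averaged OEF, CBV, vessel_size and a voi_label).
#' @param histology data frame from [histology_table()].
#' @return data frame of paired measurements, class `paired_measurements`.
#' @export
paired_measurements <- function(targets, histology) {
  if (nrow(targets) != nrow(histology))
    stop_input("targets and histology tables must pair row-for-row")
  out <- data.frame(
    voi_label = histology$voi_label,
    OEF = targets$OEF, CBV = targets$CBV,
    vessel_size = targets$vessel_size,
    hif_score = histology$hif_score,
    vessel_density = histology$vessel_density,
    vessel_diameter = histology$vessel_diameter)
  class(out) <- c("paired_measurements", "data.frame")
  out
}

#' Full statistical report on a paired MRI/histology table
#'
#' Per metric: Kruskal-Wallis across VOI labels (skipped with a logged
#' reason when fewer than two adequate groups remain) and all pairwise
#' Mann-Whitney tests; plus the three Spearman MRI-vs-histology
#' correlations (OEF vs HIF-1alpha H-score, CBV vs vessel density, vessel
#' size vs vessel diameter). Rows with undefined values are dropped
#' listwise per tested quantity and counted. Raw p-values throughout; no
#' multiplicity correction.
#'
#' @param paired a [paired_measurements()] data frame.
#' @param alpha significance threshold for flags.
#' @param out_dir optional directory: writes `stats.json`, bar plots per
#'   metric and scatter plots per correlation pair.
#' @return list with `group_tests`, `correlations`, `skipped`, `n_rows`.
#' @export
stats_report <- function(paired, alpha = 0.05, out_dir = NULL) {
  metrics <- c("OEF", "CBV", "vessel_size",
               "hif_score", "vessel_density", "vessel_diameter")
  group_tests <- list()
  skipped <- list()
  for (mn in intersect(metrics, names(paired))) {
    ok <- is.finite(paired[[mn]])
    v <- paired[[mn]][ok]
    g <- as.character(paired$voi_label[ok])
    tab <- table(g)
    adequate <- names(tab)[tab >= 2L]
    if (length(adequate) < 2L) {
      skipped[[mn]] <- paste0("fewer than two groups with >= 2 values (",
                              paste(names(tab), tab, collapse = ", "), ")")
      next
    }
    keep <- g %in% adequate
    kw <- if (length(adequate) >= 2L) kw_test(v[keep], g[keep]) else NULL
    mw <- mw_test_pairs(v[keep], g[keep])
    group_tests[[mn]] <- list(kruskal_wallis = kw, mann_whitney = mw,
                              n_dropped = sum(!ok))
  }
  correlations <- list()
  for (pr in MRI_HISTO_PAIRS) {
    if (!all(pr %in% names(paired))) next
    key <- paste(pr[["mri"]], "vs", pr[["histo"]])
    n_ok <- sum(is.finite(paired[[pr[["mri"]]]]) &
                  is.finite(paired[[pr[["histo"]]]]))
    if (n_ok < 3L) {
      skipped[[key]] <- sprintf("only %d complete pairs (need >= 3)", n_ok)
      correlations[[key]] <- list(r = NA_real_, p = NA_real_, n = n_ok,
                                  n_dropped = nrow(paired) - n_ok,
                                  significant = NA)
      next
    }
    correlations[[key]] <- spearman_test(paired[[pr[["mri"]]]],
                                         paired[[pr[["histo"]]]],
                                         alpha = alpha)
  }
  out <- list(group_tests = group_tests, correlations = correlations,
              skipped = skipped, n_rows = nrow(paired))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (mn in names(group_tests)) {
      grDevices::png(file.path(out_dir, paste0("bars_", mn, ".png")),
                     width = 600, height = 450)
      plot_metric_bars(paired, mn, group_tests[[mn]]$mann_whitney)
      grDevices::dev.off()
    }
    for (pr in MRI_HISTO_PAIRS) {
      if (!all(pr %in% names(paired))) next
      key <- paste(pr[["mri"]], "vs", pr[["histo"]])
      grDevices::png(file.path(out_dir,
                               paste0("scatter_", pr[["mri"]], "_",
                                      pr[["histo"]], ".png")),
                     width = 500, height = 450)
      plot_correlation(paired[[pr[["mri"]]]], paired[[pr[["histo"]]]],
                       pr[["mri"]], pr[["histo"]],
                       correlations[[key]])
      grDevices::dev.off()
    }
  }
  out
}

# grouped bar of per-VOI means with pairwise p annotations
plot_metric_bars <- function(paired, metric, mw) {
  ok <- is.finite(paired[[metric]])
  v <- paired[[metric]][ok]
  g <- factor(paired$voi_label[ok])
  means <- tapply(v, g, mean)
  sds <- tapply(v, g, stats::sd)
  bp <- graphics::barplot(means, ylim = c(0, max(means + sds, na.rm = TRUE) * 1.4),
                          ylab = metric, col = "grey80")
  graphics::arrows(bp, means, bp, means + sds, angle = 90, length = 0.05)
  if (!is.null(mw) && nrow(mw)) {
    ytop <- max(means + sds, na.rm = TRUE)
    for (i in seq_len(nrow(mw))) {
      i1 <- match(mw$group1[i], levels(g))
      i2 <- match(mw$group2[i], levels(g))
      y <- ytop * (1.05 + 0.1 * i)
      graphics::segments(bp[i1], y, bp[i2], y)
      lab <- sprintf("p=%.3g%s", mw$p[i], if (mw$p[i] < 0.05) " *" else "")
      graphics::text((bp[i1] + bp[i2]) / 2, y, lab, pos = 3, cex = 0.7)
    }
  }
  invisible(NULL)
}

plot_correlation <- function(x, y, xlab, ylab, test) {
  ok <- is.finite(x) & is.finite(y)
  graphics::plot(x[ok], y[ok], pch = 16, xlab = xlab, ylab = ylab,
                 main = sprintf("r = %.2f, p = %.3g%s", test$r, test$p,
                                if (isTRUE(test$significant)) " *" else ""))
  invisible(NULL)
}
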