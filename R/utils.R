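# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

#' Ellipsoid membership on a voxel grid
#'
#' @param dim integer vector of length 3, grid size.
#' @param center,radii in voxel units (may be fractional).
#' @return logical array of `dim`.
#' @noRd
ellipsoid_mask <- function(dim, center, radii) {
  x <- (seq_len(dim[1]) - center[1]) / radii[1]
  y <- (seq_len(dim[2]) - center[2]) / radii[2]
  z <- (seq_len(dim[3]) - center[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(d2 <= 1, dim = dim)
}

#' Trapezoid weights for sample times, optionally over an index window
#' @noRd
trapz_weights <- function(times, window = seq_along(times)) {
  t <- times[window]
  n <- length(t)
  if (n < 2L) return(stats::setNames(numeric(length(times)), NULL))
  w <- numeric(length(times))
  dt <- diff(t)
  w[window[1L]] <- dt[1L] / 2
  w[window[n]] <- dt[n - 1L] / 2
  if (n > 2L) w[window[2:(n - 1L)]] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}

#' Cumulative trapezoidal integral of y(t), same length as y (starts at 0)
#' @noRd
cumtrapz <- function(times, y) {
  n <- length(y)
  c(0, cumsum(diff(times) * (y[-n] + y[-1]) / 2))
}

#' Row-wise max of a matrix (NA-aware, -Inf for all-NA rows)
#' @noRd
row_max <- function(m) {
  out <- rep(-Inf, nrow(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v) & v > out
    out[ok] <- v[ok]
  }
  out
}

#' @noRd
row_min <- function(m) -row_max(-m)

#' Add magnitude noise to a nonnegative signal array
#'
#' Gaussian: S + N(0, sd). Rician: |(S + N(0, sd)) + i N(0, sd)| — the
#' magnitude of a complex Gaussian perturbation.
#' @noRd
add_noise <- function(signal, sd, model = c("gaussian", "rician")) {
  model <- match.arg(model)
  if (sd <= 0) return(signal)
  n <- length(signal)
  if (model == "gaussian") {
    signal + stats::rnorm(n, 0, sd)
  } else {
    sqrt((signal + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
  }
}

# Offsets of the 26-neighborhood in 3D
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

#' Label 26-connected components of a 3D logical mask
#'
#' Breadth-first flood fill; intended for sparse masks (thresholded maps),
#' where the selected voxel count is far below the grid size.
#'
#' @return integer array, 0 = background, 1..k = component labels (ordered
#'   by first-encountered linear index, hence deterministic).
#' @noRd
label_components_3d <- function(mask) {
  dm <- dim(mask)
  labels <- array(0L, dm)
  offs <- neighbor_offsets_26()
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  coords <- arrayInd(idx, dm)
  in_mask <- mask
  lab <- 0L
  for (s in seq_along(idx)) {
    if (labels[idx[s]] != 0L) next
    lab <- lab + 1L
    queue <- matrix(coords[s, ], ncol = 3)
    labels[idx[s]] <- lab
    while (nrow(queue) > 0L) {
      v <- queue[nrow(queue), ]
      queue <- queue[-nrow(queue), , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        p <- v + offs[k, ]
        if (any(p < 1L) || any(p > dm)) next
        li <- p[1] + dm[1] * (p[2] - 1L) + dm[1] * dm[2] * (p[3] - 1L)
        if (in_mask[li] && labels[li] == 0L) {
          labels[li] <- lab
          queue <- rbind(queue, p)
        }
      }
    }
  }
  labels
}

#' Does a component (logical array) contain a full 2x2x2 voxel block?
#' @noRd
has_block_222 <- function(comp) {
  dm <- dim(comp)
  if (any(dm < 2L)) return(FALSE)
  a <- comp[-dm[1], -dm[2], -dm[3], drop = FALSE] &
    comp[-1, -dm[2], -dm[3], drop = FALSE] &
    comp[-dm[1], -1, -dm[3], drop = FALSE] &
    comp[-1, -1, -dm[3], drop = FALSE] &
    comp[-dm[1], -dm[2], -1, drop = FALSE] &
    comp[-1, -dm[2], -1, drop = FALSE] &
    comp[-dm[1], -1, -1, drop = FALSE] &
    comp[-1, -1, -1, drop = FALSE]
  any(a)
}

#' Does a component contain a 3x3 in-plane (axial, fixed z) block?
#' @noRd
has_block_33_inplane <- function(comp) {
  dm <- dim(comp)
  if (dm[1] < 3L || dm[2] < 3L) return(FALSE)
  for (z in seq_len(dm[3])) {
    sl <- comp[, , z]
    s <- sl[-c(dm[1] - 1L, dm[1]), -c(dm[2] - 1L, dm[2]), drop = FALSE]
    for (dx in 0:2) for (dy in 0:2) {
      if (dx == 0 && dy == 0) next
      s <- s & sl[seq_len(dm[1] - 2L) + dx, seq_len(dm[2] - 2L) + dy, drop = FALSE]
    }
    if (any(s)) return(TRUE)
  }
  FALSE
}

#' Quantile with linear interpolation (type 7), the package-wide convention
#' @noRd
pctl <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE, na.rm = TRUE)

#' Evaluate the run seed for a stage without perturbing user RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
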