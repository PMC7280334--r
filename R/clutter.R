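## SVD clutter filtering of image stacks and POD denoising of vector-field
## time series. The Casorati matrix (pixels x frames) is factorised by a
## singular value decomposition; tissue, blood and noise occupy different
## singular-vector subspaces because of their distinct spatiotemporal
## coherence. Vector-field series are denoised by truncating a proper
## orthogonal decomposition of the concatenated (u, v) state vectors.

#' Singular value decomposition of an image stack
#'
#' Factorises the Casorati matrix (pixels x frames) of the stack. The
#' reconstruction from all components reproduces the stack to floating
#' tolerance.
#'
#' @param stack an [image_stack()] with at least two frames.
#' @return list of class `echo_svd` with `u` (pixels x K spatial vectors),
#'   `d` (singular values, non-increasing), `v` (frames x K temporal
#'   vectors), `shape` (ny, nx, T), `stack_meta`.
#' @export
svd_decompose <- function(stack) {
  d <- dim(stack$data)
  if (d[3] < 2L) stop("svd_decompose needs at least 2 frames")
  cas <- matrix(stack$data, d[1] * d[2], d[3])
  s <- svd(cas)
  structure(list(u = s$u, d = s$d, v = s$v, shape = d,
                 stack_meta = unclass(stack)[c("pixel_spacing", "frame_interval", "t0", "angle")]),
            class = "echo_svd")
}

#' Select the blood (flow) band of singular components
#'
#' Tissue singular vectors are mutually similar in space; blood and noise
#' vectors are not. The low cut is placed at the first component where the
#' Pearson correlation between the magnitudes of adjacent spatial singular
#' vectors drops below `threshold`; if the curve never crosses the
#' threshold (blood vectors share the lumen footprint and stay mutually
#' similar), the cut falls at the valley between the tissue block and the
#' blood plateau. The high cut
#' keeps components up to `noise_energy` cumulative energy of the
#' post-low-cut spectrum.
#'
#' @param decomp an `echo_svd`.
#' @param threshold adjacent-|U| correlation below which components are no
#'   longer tissue; `<= 0` keeps everything (low cut = 1).
#' @param noise_energy cumulative energy fraction of the post-low-cut
#'   spectrum retained before the noise floor.
#' @return A `rank_band`: list `(low, high)`, 1-based inclusive component
#'   indices of the blood band.
#' @export
select_blood_band <- function(decomp, threshold = 0.2, noise_energy = 0.90) {
  K <- length(decomp$d)
  if (K < 2L) stop("degenerate decomposition: fewer than 2 components")
  if (threshold <= 0) {
    low <- 1L
  } else {
    cors <- vapply(seq_len(K - 1), function(j)
      suppressWarnings(stats::cor(abs(decomp$u[, j]), abs(decomp$u[, j + 1]))),
      numeric(1))
    cors[!is.finite(cors)] <- 0
    # the decision uses the raw curve: a moving-mean smoothing delays the
    # crossing by a component when the tissue/blood transition is abrupt
    drop_idx <- which(cors < threshold)
    if (length(drop_idx)) {
      low <- drop_idx[1] + 1L
    } else {
      # no absolute crossing: blood components share the lumen footprint and
      # stay mutually similar, so the tissue/blood split shows as a valley
      # between the tissue block and the blood plateau
      half <- seq_len(max(1L, ceiling(K / 2)))
      valley <- which.min(cors[half])   # the valley is sharp; use unsmoothed
      low <- if (cors[valley] < 0.75 * stats::median(cors)) valley + 1L else K
    }
  }
  en <- decomp$d[low:K]^2
  cum <- cumsum(en) / sum(en)
  high <- low + which(cum >= noise_energy)[1] - 1L
  rank_band(low, high, K)
}

#' Rank band of singular components
#' @param low,high 1-based inclusive bounds into the singular-value order.
#' @param n_components total number of components (for validation).
#' @export
rank_band <- function(low, high, n_components = NULL) {
  low <- as.integer(low); high <- as.integer(high)
  if (low < 1L || high < low) stop("invalid rank band [", low, ", ", high, "]")
  if (!is.null(n_components) && high > n_components)
    stop("rank band exceeds number of components")
  structure(list(low = low, high = high), class = "rank_band")
}

reconstruct_band <- function(decomp, idx) {
  d <- decomp$shape
  if (!length(idx)) return(array(0, d))
  cas <- decomp$u[, idx, drop = FALSE] %*%
    (decomp$d[idx] * t(decomp$v[, idx, drop = FALSE]))
  array(cas, d)
}

#' Split a stack into tissue and blood components
#'
#' Reconstructs the blood stack from the singular components inside `band`
#' and the tissue stack from the components below the low cut; the two plus
#' the discarded noise residual sum to the original stack.
#'
#' @param stack an [image_stack()].
#' @param band a `rank_band`, or `NULL` to select automatically via
#'   [select_blood_band()].
#' @param decomp optionally a precomputed `echo_svd` of `stack`.
#' @param ... passed to [select_blood_band()].
#' @return list with `tissue` and `blood` [image_stack()]s, plus the `band`
#'   and `decomp` used.
#' @export
svd_filter <- function(stack, band = NULL, decomp = NULL, ...) {
  if (is.null(decomp)) decomp <- svd_decompose(stack)
  if (is.null(band)) band <- select_blood_band(decomp, ...)
  K <- length(decomp$d)
  if (band$high > K) stop("rank band out of range")
  blood <- reconstruct_band(decomp, band$low:band$high)
  tissue <- reconstruct_band(decomp, seq_len(band$low - 1L))
  mk <- function(a) image_stack(a, stack$pixel_spacing, stack$frame_interval,
                                t0 = stack$t0, angle = stack$angle)
  list(tissue = mk(tissue), blood = mk(blood), band = band, decomp = decomp)
}

## fill missing (NA) vectors by the median of valid 3x3 neighbours,
## falling back to the frame median, then zero
fill_missing <- function(m) {
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (!nrow(bad)) return(m)
  ny <- nrow(m); nx <- ncol(m)
  fm <- stats::median(m[is.finite(m)])
  if (!is.finite(fm)) fm <- 0
  out <- m
  for (k in seq_len(nrow(bad))) {
    i <- bad[k, 1]; j <- bad[k, 2]
    nb <- m[max(1, i - 1):min(ny, i + 1), max(1, j - 1):min(nx, j + 1)]
    nb <- nb[is.finite(nb)]
    out[i, j] <- if (length(nb)) stats::median(nb) else fm
  }
  out
}

#' Denoise a velocity-field time series by proper orthogonal decomposition
#'
#' Stacks the per-frame (u, v) fields into state vectors, factorises the
#' series by SVD, and reconstructs from the leading modes carrying
#' `energy_fraction` of the total energy (or exactly `n_modes` modes).
#' Missing vectors are filled by the median of valid neighbours before the
#' decomposition and re-masked afterwards.
#'
#' @param field an [velocity_field()] with >= 2 frames.
#' @param energy_fraction fraction in (0, 1] of squared-singular-value
#'   energy to retain.
#' @param n_modes optional explicit mode count (overrides
#'   `energy_fraction`).
#' @return The filtered `echo_vfield`; attribute `n_modes` records the
#'   number of modes kept.
#' @export
pod_filter <- function(field, energy_fraction = 0.95, n_modes = NULL) {
  if (is.null(n_modes) && (energy_fraction <= 0 || energy_fraction > 1))
    stop("energy_fraction must be in (0, 1]")
  T_len <- dim(field$u)[3]
  if (T_len < 2L) stop("pod_filter needs at least 2 frames")
  P <- prod(dim(field$u)[1:2])
  X <- matrix(0, 2 * P, T_len)
  for (k in seq_len(T_len)) {
    uk <- field$u[, , k]; vk <- field$v[, , k]
    uk[!field$valid[, , k]] <- NA; vk[!field$valid[, , k]] <- NA
    X[seq_len(P), k] <- as.vector(fill_missing(uk))
    X[P + seq_len(P), k] <- as.vector(fill_missing(vk))
  }
  s <- svd(X)
  if (is.null(n_modes)) {
    cum <- cumsum(s$d^2) / sum(s$d^2)
    n_modes <- which(cum >= energy_fraction)[1]
  }
  n_modes <- min(n_modes, length(s$d))
  idx <- seq_len(n_modes)
  Xf <- s$u[, idx, drop = FALSE] %*% (s$d[idx] * t(s$v[, idx, drop = FALSE]))
  out <- field
  for (k in seq_len(T_len)) {
    uk <- matrix(Xf[seq_len(P), k], dim(field$u)[1], dim(field$u)[2])
    vk <- matrix(Xf[P + seq_len(P), k], dim(field$u)[1], dim(field$u)[2])
    # grid points with no stored value (outside the analysis mask) stay
    # masked; in-mask rejected nodes keep their smoothed reconstruction but
    # remain flagged invalid
    blank <- !is.finite(field$u[, , k])
    uk[blank] <- NA; vk[blank] <- NA
    out$u[, , k] <- uk; out$v[, , k] <- vk
  }
  attr(out, "n_modes") <- n_modes
  out
}
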