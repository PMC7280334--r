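## Multipass, window-deforming, ensemble-averaged normalised
## cross-correlation velocimetry (echoPIV). Interrogation windows start at
## 32 x 32 px and are halved each pass, the previous pass providing the
## displacement predictor; correlation planes of all low-resolution image
## pairs of a compounded acquisition are averaged before peak detection
## (incoherent ensemble correlation); sub-pixel displacement by 3-point
## Gaussian peak fitting; spurious vectors removed by the normalised
## median test.

#' PIV configuration
#'
#' @param window initial interrogation-window side (px).
#' @param passes number of passes; the window side halves each pass
#'   (32 -> 16 -> 8 for the defaults).
#' @param overlap window overlap fraction in [0, 0.75].
#' @param deform logical; warp the second frame by the predictor field
#'   before each pass.
#' @param outlier_threshold normalised-median-test residual threshold.
#' @param subpixel `"gaussian"` (3-point log fit) or `"parabolic"`.
#' @export
piv_config <- function(window = 32L, passes = 3L, overlap = 0.5,
                       deform = TRUE, outlier_threshold = 2.0,
                       subpixel = c("gaussian", "parabolic")) {
  subpixel <- match.arg(subpixel)
  window <- as.integer(window); passes <- as.integer(passes)
  if (passes < 1L) stop("passes must be >= 1")
  if (overlap < 0 || overlap > 0.75) stop("overlap must be in [0, 0.75]")
  if (window / 2^(passes - 1) < 4) stop("window after all passes must be >= 4 px")
  structure(list(window = window, passes = passes, overlap = overlap,
                 deform = deform, outlier_threshold = outlier_threshold,
                 subpixel = subpixel),
            class = "piv_config")
}

## swap quadrants so the zero lag sits at (w %/% 2 + 1, w %/% 2 + 1)
fftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- c((ny %/% 2 + 1):ny, 1:(ny %/% 2))
  ix <- c((nx %/% 2 + 1):nx, 1:(nx %/% 2))
  m[iy, ix]
}

## interrogation grid: 1-based top-left corners and 0-based window centres
piv_grid <- function(shape, window, step) {
  tl_y <- seq(1, shape[1] - window + 1, by = step)
  tl_x <- seq(1, shape[2] - window + 1, by = step)
  g <- expand.grid(tl_y = tl_y, tl_x = tl_x)
  g$cy <- g$tl_y - 1 + (window - 1) / 2
  g$cx <- g$tl_x - 1 + (window - 1) / 2
  g
}

#' Normalised cross-correlation planes at grid nodes
#'
#' Correlates interrogation windows of two frames. Each window is
#' zero-meaned and unit-variance normalised, and the circular correlation
#' is computed by FFT; the plane is shifted so the zero lag sits at its
#' centre `(window %/% 2 + 1)`. A zero-variance (uniform) window flags the
#' plane invalid rather than erroring.
#'
#' @param frameA,frameB numeric matrices of equal shape.
#' @param nodes data.frame with 1-based window top-left corners `tl_y`,
#'   `tl_x` (as from the internal grid builder); one plane per row.
#' @param window window side (px).
#' @return list of class `corr_planes`: `planes` array
#'   `window x window x n_nodes`, `valid` logical, `nodes`, `window`.
#' @export
correlate_windows <- function(frameA, frameB, nodes, window) {
  stopifnot(identical(dim(frameA), dim(frameB)))
  n <- nrow(nodes)
  planes <- array(0, c(window, window, n))
  valid <- logical(n)
  N <- window * window
  # zero-padded (linear, not circular) correlation with overlap
  # normalisation: a circular correlation's triangular wraparound weighting
  # biases broad-speckle peaks toward zero lag
  wp <- 2L * window
  lag_sel <- c((wp - window %/% 2 + 1):wp, 1:(window - window %/% 2))
  lags <- c(-(window %/% 2):(window %/% 2 - 1))
  # cap the overlap correction: extreme lags have little support and the
  # raw 1/overlap factor would amplify noise there unboundedly
  overlap <- pmax(outer(window - abs(lags), window - abs(lags)) / N, 0.25)
  pa <- matrix(0, wp, wp); pb <- matrix(0, wp, wp)
  for (k in seq_len(n)) {
    ys <- nodes$tl_y[k]:(nodes$tl_y[k] + window - 1)
    xs <- nodes$tl_x[k]:(nodes$tl_x[k] + window - 1)
    wa <- frameA[ys, xs]; wb <- frameB[ys, xs]
    wa <- wa - mean(wa); wb <- wb - mean(wb)
    sa <- sqrt(mean(wa^2)); sb <- sqrt(mean(wb^2))
    if (sa <= 0 || sb <= 0) next
    pa[] <- 0; pb[] <- 0
    pa[seq_len(window), seq_len(window)] <- wa
    pb[seq_len(window), seq_len(window)] <- wb
    cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE)) / (wp * wp)
    planes[, , k] <- cc[lag_sel, lag_sel] / (overlap * N * sa * sb)
    valid[k] <- TRUE
  }
  structure(list(planes = planes, valid = valid, nodes = nodes, window = window),
            class = "corr_planes")
}

#' Ensemble-averaged correlation planes
#'
#' Correlates each image pair on the same grid and returns the arithmetic
#' mean of the per-pair correlation planes per node, the incoherent
#' ensemble used for peak detection downstream.
#'
#' @param pairs non-empty list of `list(A = , B = )` frame pairs sharing
#'   one shape.
#' @inheritParams correlate_windows
#' @return A `corr_planes` object of the averaged planes.
#' @export
ensemble_correlate <- function(pairs, nodes, window) {
  if (!length(pairs)) stop("empty pair list")
  acc <- NULL; cnt <- NULL
  for (p in pairs) {
    cp <- correlate_windows(p$A, p$B, nodes, window)
    if (is.null(acc)) { acc <- cp$planes * 0; cnt <- numeric(length(cp$valid)) }
    ok <- which(cp$valid)
    for (k in ok) {
      acc[, , k] <- acc[, , k] + cp$planes[, , k]
      cnt[k] <- cnt[k] + 1
    }
  }
  valid <- cnt > 0
  for (k in which(valid)) acc[, , k] <- acc[, , k] / cnt[k]
  structure(list(planes = acc, valid = valid, nodes = nodes, window = window),
            class = "corr_planes")
}

#' Sub-pixel correlation peak location
#'
#' Finds the integer peak of a correlation plane and refines it with an
#' independent 3-point Gaussian fit per axis. A peak on the plane border
#' returns the integer lag with `border = TRUE`; non-positive neighbour
#' values trigger a parabolic fallback (`fallback = TRUE`).
#'
#' @param plane correlation plane matrix with zero lag at
#'   `(nrow %/% 2 + 1, ncol %/% 2 + 1)`.
#' @param method `"gaussian"` or `"parabolic"`.
#' @param search_frac optionally restrict the peak search to lags within
#'   `search_frac * window` of zero (the quarter-window rule when 0.25).
#' @return list `lag = c(dx, dy)` (continuous px), `value` (peak height),
#'   `border`, `fallback`.
#' @export
subpixel_peak <- function(plane, method = c("gaussian", "parabolic"),
                          search_frac = NULL) {
  method <- match.arg(method)
  ny <- nrow(plane); nx <- ncol(plane)
  if (!is.null(search_frac)) {
    cy <- ny %/% 2 + 1; cx <- nx %/% 2 + 1
    ry <- abs(seq_len(ny) - cy) > ny * search_frac
    rx <- abs(seq_len(nx) - cx) > nx * search_frac
    lo <- min(plane)
    plane[ry, ] <- lo; plane[, rx] <- lo
  }
  pk <- which.max(plane)
  iy <- (pk - 1) %% ny + 1; ix <- (pk - 1) %/% ny + 1
  cy0 <- ny %/% 2 + 1; cx0 <- nx %/% 2 + 1
  if (iy <= 1 || iy >= ny || ix <= 1 || ix >= nx)
    return(list(lag = c(ix - cx0, iy - cy0), value = plane[iy, ix],
                border = TRUE, fallback = FALSE))
  fit1 <- function(cm, c0, cp) {
    if (method == "gaussian" && cm > 0 && c0 > 0 && cp > 0) {
      den <- log(cm) + log(cp) - 2 * log(c0)
      if (den < 0) return(list(d = 0.5 * (log(cm) - log(cp)) / den, fb = FALSE))
    }
    den <- cm - 2 * c0 + cp
    d <- if (den < 0) 0.5 * (cm - cp) / den else 0
    list(d = d, fb = TRUE)
  }
  fx <- fit1(plane[iy, ix - 1], plane[iy, ix], plane[iy, ix + 1])
  fy <- fit1(plane[iy - 1, ix], plane[iy, ix], plane[iy + 1, ix])
  list(lag = c(ix - cx0 + fx$d, iy - cy0 + fy$d), value = plane[iy, ix],
       border = FALSE, fallback = (fx$fb || fy$fb) && method == "gaussian")
}

## normalised median test on matrices; returns list(u, v, valid, interpolated)
nmt_validate <- function(u, v, valid, threshold = 2.0, eps = 0.1) {
  ny <- nrow(u); nx <- ncol(u)
  res <- matrix(0, ny, nx)
  med_u <- matrix(NA_real_, ny, nx); med_v <- med_u
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ii <- max(1, i - 1):min(ny, i + 1); jj <- max(1, j - 1):min(nx, j + 1)
    nb <- cbind(as.vector(u[ii, jj]), as.vector(v[ii, jj]))
    ctr <- (match(i, ii) - 1) + (match(j, jj) - 1) * length(ii) + 1
    nb <- nb[-ctr, , drop = FALSE]
    nb <- nb[is.finite(nb[, 1]) & is.finite(nb[, 2]), , drop = FALSE]
    if (!nrow(nb)) next
    mu <- stats::median(nb[, 1]); mv <- stats::median(nb[, 2])
    med_u[i, j] <- mu; med_v[i, j] <- mv
    if (!valid[i, j] || !is.finite(u[i, j])) next
    ru <- abs(u[i, j] - mu) / (stats::median(abs(nb[, 1] - mu)) + eps)
    rv <- abs(v[i, j] - mv) / (stats::median(abs(nb[, 2] - mv)) + eps)
    res[i, j] <- sqrt(ru^2 + rv^2)
  }
  reject <- res > threshold * sqrt(2)
  interpolated <- reject | !valid | !is.finite(u)
  u[interpolated] <- med_u[interpolated]
  v[interpolated] <- med_v[interpolated]
  u <- fill_missing(u); v <- fill_missing(v)
  list(u = u, v = v, valid = valid & !reject, interpolated = interpolated)
}

#' Spurious-vector elimination by the normalised median test
#'
#' Applies the universal outlier (normalised median) test on 3 x 3
#' neighbourhoods to every slice of a velocity field; rejected vectors are
#' replaced by the median of their valid neighbours and flagged as
#' interpolated.
#'
#' @param field an [velocity_field()].
#' @param threshold residual threshold (default 2.0).
#' @return The validated `echo_vfield` with updated `valid` and
#'   `interpolated` masks.
#' @export
validate_vectors <- function(field, threshold = 2.0) {
  out <- field
  for (k in seq_len(dim(field$u)[3])) {
    r <- nmt_validate(field$u[, , k], field$v[, , k], field$valid[, , k], threshold)
    out$u[, , k] <- r$u; out$v[, , k] <- r$v
    out$valid[, , k] <- r$valid
    out$interpolated[, , k] <- r$interpolated
  }
  if (!any(out$valid)) warning("all vectors rejected by validation")
  out
}

## bilinear sample of per-node matrix `val` (nodes at uniform grid xs, ys,
## 0-based px) at arbitrary pixel coordinates
interp_nodes <- function(val, xs, ys, xq, yq) {
  dx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  dy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  out <- bilinear(val, (xq - xs[1]) / dx, (yq - ys[1]) / dy)
  matrix(out, nrow = if (is.matrix(xq)) nrow(xq) else 1)
}

warp_image <- function(img, du, dv) {
  ny <- nrow(img); nx <- ncol(img)
  X <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  Y <- matrix(0:(ny - 1), ny, nx)
  matrix(bilinear(img, X + du, Y + dv), ny, nx)
}

#' Multipass window-deforming PIV on an ensemble of image pairs
#'
#' Runs `passes` correlation passes with window sides halving each pass
#' (default 32 -> 16 -> 8). Each pass correlates every pair (ensemble
#' averaging the planes), refines the peak to sub-pixel precision,
#' validates with the normalised median test, and uses the accumulated
#' displacement as predictor for the next pass, deforming the second frame
#' of each pair by the bilinearly interpolated displacement field.
#'
#' @param pairs list of `list(A = , B = )` image-pair matrices (one pair,
#'   or one per steering angle for ensemble correlation).
#' @param config a [piv_config()].
#' @param mask optional logical lumen mask (`ny x nx`); only windows whose
#'   centre lies inside are computed, and output vectors outside are
#'   invalid.
#' @param pixel_spacing,pair_interval physical scaling; when both are given
#'   the result is converted to m/s, otherwise left in px/frame.
#' @return An [velocity_field()] on the final-pass grid.
#' @export
multipass <- function(pairs, config = piv_config(), mask = NULL,
                      pixel_spacing = NULL, pair_interval = NULL) {
  if (!length(pairs)) stop("empty pair list")
  shape <- dim(pairs[[1]]$A)
  for (p in pairs) stopifnot(identical(dim(p$A), shape), identical(dim(p$B), shape))
  if (config$window > min(shape)) stop("window larger than frame")
  prev <- NULL
  for (pass in seq_len(config$passes)) {
    w <- config$window %/% (2^(pass - 1))
    step <- max(2L, as.integer(round(w * (1 - config$overlap))))
    g <- piv_grid(shape, w, step)
    xs <- sort(unique(g$cx)); ys <- sort(unique(g$cy))
    nxg <- length(xs); nyg <- length(ys)
    in_mask <- if (is.null(mask)) rep(TRUE, nrow(g)) else
      mask[cbind(round(g$cy) + 1, round(g$cx) + 1)]
    # predictor at this pass's nodes
    if (is.null(prev)) {
      pu <- matrix(0, nyg, nxg); pv <- matrix(0, nyg, nxg)
    } else {
      pu <- interp_nodes(prev$u, prev$xs, prev$ys,
                         matrix(g$cx, nyg, nxg), matrix(g$cy, nyg, nxg))
      pv <- interp_nodes(prev$v, prev$xs, prev$ys,
                         matrix(g$cx, nyg, nxg), matrix(g$cy, nyg, nxg))
    }
    use_pairs <- pairs
    if (config$deform && !is.null(prev)) {
      X <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
      Y <- matrix(0:(shape[1] - 1), shape[1], shape[2])
      du <- matrix(bilinear_from_nodes(prev$u, prev$xs, prev$ys, X, Y), shape[1], shape[2])
      dv <- matrix(bilinear_from_nodes(prev$v, prev$xs, prev$ys, X, Y), shape[1], shape[2])
      use_pairs <- lapply(pairs, function(p)
        list(A = p$A, B = warp_image(p$B, du, dv)))
    }
    sub <- g[in_mask, , drop = FALSE]
    u <- matrix(NA_real_, nyg, nxg); v <- matrix(NA_real_, nyg, nxg)
    valid <- matrix(FALSE, nyg, nxg)
    if (nrow(sub)) {
      cp <- ensemble_correlate(use_pairs, sub, w)
      ridx <- match(sub$cy, ys); cidx <- match(sub$cx, xs)
      for (k in seq_len(nrow(sub))) {
        if (!cp$valid[k]) next
        pk <- subpixel_peak(cp$planes[, , k], method = config$subpixel,
                            search_frac = 0.25)
        i <- ridx[k]; j <- cidx[k]
        base_u <- if (config$deform && !is.null(prev)) pu[i, j] else 0
        base_v <- if (config$deform && !is.null(prev)) pv[i, j] else 0
        if (!config$deform && !is.null(prev)) { base_u <- 0; base_v <- 0 }
        u[i, j] <- base_u + pk$lag[1]
        v[i, j] <- base_v + pk$lag[2]
        valid[i, j] <- !pk$border
      }
    }
    r <- nmt_validate(u, v, valid, config$outlier_threshold)
    mask_nodes <- matrix(FALSE, nyg, nxg)
    mask_nodes[cbind(match(g$cy, ys), match(g$cx, xs))] <- in_mask
    r$u[!mask_nodes & !is.finite(r$u)] <- 0
    r$v[!mask_nodes & !is.finite(r$v)] <- 0
    prev <- list(u = r$u, v = r$v, xs = xs, ys = ys,
                 valid = r$valid & mask_nodes, interpolated = r$interpolated,
                 mask_nodes = mask_nodes)
  }
  # values outside the analysis mask are not meaningful: blank them, but keep
  # median-replaced values at rejected in-mask nodes (flagged invalid)
  prev$u[!prev$mask_nodes] <- NA_real_
  prev$v[!prev$mask_nodes] <- NA_real_
  fld <- velocity_field(prev$u, prev$v, prev$xs, prev$ys,
                        valid = array(prev$valid, c(dim(prev$u), 1)),
                        times = 0,
                        pixel_spacing = if (is.null(pixel_spacing)) c(1, 1) else pixel_spacing,
                        pair_interval = if (is.null(pair_interval)) 1 else pair_interval,
                        units = "px",
                        interpolated = array(prev$interpolated, c(dim(prev$u), 1)))
  if (!is.null(pixel_spacing) && !is.null(pair_interval)) fld <- field_to_mps(fld)
  fld
}

## like interp_nodes but anisotropic px scaling handled by caller; kept for
## clarity at call sites where axial and lateral displacements differ
bilinear_from_nodes <- function(val, xs, ys, Xq, Yq) {
  dx <- if (length(xs) > 1) xs[2] - xs[1] else 1
  dy <- if (length(ys) > 1) ys[2] - ys[1] else 1
  bilinear(val, (Xq - xs[1]) / dx, (Yq - ys[1]) / dy)
}

#' PIV over a time series of per-angle stacks
#'
#' For each requested frame pair, runs [multipass()] on the ensemble of
#' per-angle image pairs (each angle's frame correlated with its own
#' consecutive frame) and assembles the per-pair fields into one
#' time-resolved velocity field in m/s.
#'
#' @param stacks list of per-angle [image_stack()]s (or a single stack).
#' @param pair_index 2-column matrix of frame indices (A, B) per time
#'   sample; defaults to consecutive frames.
#' @param config a [piv_config()].
#' @param masks optional list of logical lumen masks, one per time sample
#'   (or a single mask reused).
#' @param times optional time stamps (s) per pair (default: frame times of
#'   the first stack at the pair midpoint).
#' @return An [velocity_field()] in m/s.
#' @export
piv_series <- function(stacks, pair_index = NULL, config = piv_config(),
                       masks = NULL, times = NULL) {
  if (inherits(stacks, "echo_stack")) stacks <- list(stacks)
  T_len <- n_frames(stacks[[1]])
  if (is.null(pair_index))
    pair_index <- cbind(seq_len(T_len - 1), seq(2, T_len))
  np <- nrow(pair_index)
  if (np < 1) stop("need at least one frame pair")
  if (is.null(times))
    times <- frame_times(stacks[[1]])[pair_index[, 1]] + stacks[[1]]$frame_interval / 2
  get_mask <- function(j) {
    if (is.null(masks)) NULL
    else if (is.list(masks)) masks[[min(j, length(masks))]]
    else masks
  }
  out <- NULL
  for (j in seq_len(np)) {
    prs <- lapply(stacks, function(s)
      list(A = s$data[, , pair_index[j, 1]], B = s$data[, , pair_index[j, 2]]))
    f <- multipass(prs, config, mask = get_mask(j),
                   pixel_spacing = stacks[[1]]$pixel_spacing,
                   pair_interval = stacks[[1]]$frame_interval)
    if (is.null(out)) {
      d <- dim(f$u)
      out <- velocity_field(array(0, c(d[1], d[2], np)), array(0, c(d[1], d[2], np)),
                            f$x, f$y,
                            valid = array(FALSE, c(d[1], d[2], np)),
                            times = times,
                            pixel_spacing = stacks[[1]]$pixel_spacing,
                            pair_interval = stacks[[1]]$frame_interval,
                            units = "mps")
    }
    out$u[, , j] <- f$u[, , 1]; out$v[, , j] <- f$v[, , 1]
    out$valid[, , j] <- f$valid[, , 1]
    out$interpolated[, , j] <- f$interpolated[, , 1]
  }
  out
}
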