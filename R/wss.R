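## Wall shear rate and stress along tracked boundaries: image-oriented
## strain-rate tensor, rotation into wall-oriented coordinates by the
## boundary tangent angle, near-wall shear from a Savitzky-Golay filtered
## velocity profile with a no-slip anchor, tau_w = mu_b * rotated shear,
## and the derived time-averaged WSS and oscillatory shear index.

#' Image-oriented strain-rate tensor of a velocity field
#'
#' Computes `e_ij = du_i/dx_j + du_j/dx_i` (no 1/2 factor, so simple shear
#' `u = g*y` yields `e_12 = g`) by central differences in the interior and
#' one-sided differences at the edges.
#'
#' @param field an [velocity_field()] in m/s on a regular grid.
#' @return list of class `strain_rate_field` with arrays `e11`, `e12`,
#'   `e22` (1/s) matching the field grid.
#' @export
strain_rate <- function(field) {
  d <- dim(field$u)
  if (d[1] < 2L || d[2] < 2L) stop("strain rate needs at least a 2 x 2 grid")
  dx <- (field$x[2] - field$x[1]) * field$pixel_spacing[2]
  dy <- (field$y[2] - field$y[1]) * field$pixel_spacing[1]
  grad <- function(m, along, h) {
    n <- dim(m)[along]
    idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
    den <- (idx_p - idx_m) * h
    if (along == 1) (m[idx_p, , drop = FALSE] - m[idx_m, , drop = FALSE]) / den
    else t(t(m[, idx_p, drop = FALSE] - m[, idx_m, drop = FALSE]) / den)
  }
  e11 <- array(0, d); e12 <- array(0, d); e22 <- array(0, d)
  for (k in seq_len(d[3])) {
    u <- field$u[, , k]; v <- field$v[, , k]
    dudx <- grad(u, 2, dx); dudy <- grad(u, 1, dy)
    dvdx <- grad(v, 2, dx); dvdy <- grad(v, 1, dy)
    e11[, , k] <- 2 * dudx
    e22[, , k] <- 2 * dvdy
    e12[, , k] <- dudy + dvdx
  }
  structure(list(e11 = e11, e12 = e12, e22 = e22, x = field$x, y = field$y,
                 pixel_spacing = field$pixel_spacing),
            class = "strain_rate_field")
}

#' Rotate a 2-D strain-rate tensor into wall-oriented coordinates
#'
#' Applies the second-rank tensor transformation `e'_mn = a_mi a_nj e_ij`
#' with `a = [[cos t, sin t], [-sin t, cos t]]` and returns the tangential
#' component `e'_12` (and optionally the full rotated tensor). Inputs are
#' vectorised.
#'
#' @param e11,e12,e22 tensor components (1/s).
#' @param theta rotation angle(s), radians.
#' @param full return all rotated components.
#' @export
rotate_tensor <- function(e11, e12, e22, theta, full = FALSE) {
  ct <- cos(theta); st <- sin(theta)
  e12p <- (e22 - e11) * st * ct + e12 * (ct^2 - st^2)
  if (!full) return(e12p)
  list(e11 = e11 * ct^2 + 2 * e12 * st * ct + e22 * st^2,
       e12 = e12p,
       e22 = e11 * st^2 - 2 * e12 * st * ct + e22 * ct^2)
}

#' Near-wall shear rate along a boundary
#'
#' For each wall point, the velocity is sampled along the inward normal
#' over the local radius (bilinear interpolation of the gridded field,
#' step = axial pixel spacing), rotated into the wall-oriented frame by
#' the tangent angle `theta`, and the tangential component is filtered
#' with a third-order Savitzky-Golay filter of relative length
#' `n/D = 0.4` (forced odd; shrunk and flagged when the profile is
#' shorter). The shear rate is the finite difference of the two closest
#' filtered points to the wall with zero velocity imposed at the wall
#' (no-slip), and is median-filtered along the boundary.
#'
#' @param field an [velocity_field()] (single slice index `k`).
#' @param bd boundary data.frame (one frame; see [classify_boundaries()]).
#' @param D local vessel diameter (m), setting the filter length and
#'   profile depth.
#' @param k slice of `field` to use.
#' @param median_width width of the 1-D median filter along the border.
#' @param ns relative Savitzky-Golay filter length `n/D`.
#' @return numeric vector of signed shear rates (1/s), positive when the
#'   tangential velocity increases along the forward-flow direction.
#' @export
near_wall_shear <- function(field, bd, D, k = 1L, median_width = 5L, ns = 0.4) {
  h <- field$pixel_spacing[1]                  # sample step (m)
  depth <- D / 2
  nsamp <- max(5L, ceiling(depth / h))
  n_sg <- round(ns * D / h)
  if (n_sg %% 2L == 0L) n_sg <- n_sg + 1L
  # use the stored field values as-is: rejected in-mask vectors carry their
  # median/POD-smoothed replacement, NA marks points outside the lumen
  u <- field$u[, , k]; v <- field$v[, , k]
  # grid node coordinates in metres
  gx <- field$x * field$pixel_spacing[2]
  gy <- field$y * field$pixel_spacing[1]
  shear <- rep(NA_real_, nrow(bd))
  for (i in seq_len(nrow(bd))) {
    th <- bd$theta[i]
    tx <- cos(th); ty <- sin(th)
    if (tx < 0) { tx <- -tx; ty <- -ty }       # orient tangent with forward flow (+x)
    nrm <- c(-ty, tx)                          # one of the two normals
    if ((bd$side[i] == "upper" && nrm[2] < 0) ||
        (bd$side[i] == "lower" && nrm[2] > 0)) nrm <- -nrm   # point into lumen
    dd <- (0:nsamp) * h
    px <- bd$x_m[i] + dd * nrm[1]
    py <- bd$y_m[i] + dd * nrm[2]
    qx <- (px - gx[1]) / (gx[2] - gx[1])
    qy <- (py - gy[1]) / (gy[2] - gy[1])
    us <- bilinear_na(u, qx, qy)
    vs <- bilinear_na(v, qx, qy)
    ut <- us * tx + vs * ty                    # tangential (wall-oriented) velocity
    ut[1] <- 0                                 # no-slip anchor at the wall
    fin <- which(is.finite(ut))
    if (length(fin) < 4) next
    if (anyNA(ut)) {
      # fill grid-masked samples with a no-slip-consistent cubic through the
      # anchor, fitted to the valid part of the profile
      dv <- dd[fin[-1]]; uv <- ut[fin[-1]]
      co <- stats::lm.fit(cbind(dv, dv^2, dv^3), uv)$coefficients
      miss <- which(!is.finite(ut))
      ut[miss] <- co[1] * dd[miss] + co[2] * dd[miss]^2 + co[3] * dd[miss]^3
    }
    n_eff <- min(n_sg, if (length(ut) %% 2L == 1L) length(ut) else length(ut) - 1L)
    if (n_eff >= 5) ut <- signal::sgolayfilt(ut, p = 3, n = n_eff)
    ut <- ut - ut[1]                           # re-impose the anchor after filtering
    shear[i] <- (ut[2] - ut[1]) / h
  }
  # 1-D median filter along each boundary chain
  for (key in unique(paste(bd$vessel, bd$side))) {
    idx <- which(paste(bd$vessel, bd$side) == key)
    ok <- idx[is.finite(shear[idx])]
    if (length(ok) > median_width)
      shear[ok] <- stats::runmed(shear[ok], k = median_width, endrule = "median")
  }
  shear
}

## bilinear interpolation returning NA when any of the 4 corners is NA or
## the query leaves the grid
bilinear_na <- function(m, xq, yq) {
  ny <- nrow(m); nx <- ncol(m)
  out <- rep(NA_real_, length(xq))
  ok <- xq >= 0 & xq <= nx - 1 & yq >= 0 & yq <= ny - 1
  if (!any(ok)) return(out)
  x <- pmin(xq[ok], nx - 1 - 1e-9); y <- pmin(yq[ok], ny - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  v <- m[cbind(i0, j0)] * (1 - fx) * (1 - fy) + m[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    m[cbind(i0 + 1, j0)] * (1 - fx) * fy + m[cbind(i0 + 1, j0 + 1)] * fx * fy
  out[ok] <- v
  out
}

#' Wall shear stress from shear rates
#'
#' `tau_w = mu_b * shear`, elementwise.
#' @param shear shear rate(s), 1/s (vector or points x frames matrix).
#' @param mu_b dynamic viscosity of blood, Pa s (> 0).
#' @export
wss_from_shear <- function(shear, mu_b) {
  stopifnot(mu_b > 0)
  mu_b * shear
}

#' WSS series along a tracked boundary over time
#'
#' Computes the near-wall shear for every frame of a velocity field /
#' boundary sequence and multiplies by the blood viscosity.
#'
#' @param field time-resolved [velocity_field()] (m/s).
#' @param boundaries list of per-frame boundary data.frames (or one
#'   data.frame reused for all frames).
#' @param D vessel diameter per frame (m), recycled.
#' @param mu_b dynamic viscosity (Pa s).
#' @param ... passed to [near_wall_shear()].
#' @return An `echo_wss` object (see [wss_series_object()]).
#' @export
wss_series <- function(field, boundaries, D, mu_b = 4.043e-3, ...) {
  T_len <- dim(field$u)[3]
  if (is.data.frame(boundaries)) boundaries <- rep(list(boundaries), T_len)
  D <- rep_len(D, T_len)
  npts <- nrow(boundaries[[1]])
  tau <- matrix(NA_real_, npts, T_len)
  for (k in seq_len(T_len)) {
    sh <- near_wall_shear(field, boundaries[[k]], D[k], k = k, ...)
    tau[seq_along(sh), k] <- wss_from_shear(sh, mu_b)
  }
  wss_series_object(tau, field$times, boundaries[[1]], mu_b)
}

#' Time-averaged wall shear stress
#'
#' `TAWSS = (1/T) integral |tau| dt` by the trapezoidal rule over the
#' series (rows = points, columns = time).
#'
#' @param tau numeric vector or points x frames matrix of WSS (Pa).
#' @param times frame times (s).
#' @export
tawss <- function(tau, times) {
  if (is.vector(tau)) tau <- matrix(tau, 1)
  if (ncol(tau) != length(times)) stop("tau / times mismatch")
  if (!length(times) || !ncol(tau)) stop("empty series")
  if (length(times) == 1L) return(abs(tau[, 1]))
  trapz_mean(abs(tau), times)
}

trapz_mean <- function(m, times) {
  w <- diff(times)
  num <- (m[, -ncol(m), drop = FALSE] + m[, -1, drop = FALSE]) %*% w / 2
  as.numeric(num) / (times[length(times)] - times[1])
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |mean tau| / TAWSS)`, integrals by the trapezoidal
#' rule; bounded in [0, 0.5]. Points with zero TAWSS are defined as 0 and
#' flagged via the `degenerate` attribute.
#'
#' @inheritParams tawss
#' @export
osi <- function(tau, times) {
  if (is.vector(tau)) tau <- matrix(tau, 1)
  if (!length(times) || !ncol(tau)) stop("empty series")
  if (length(times) == 1L) {
    out <- rep(0, nrow(tau)); attr(out, "degenerate") <- tau[, 1] == 0
    return(out)
  }
  ta <- trapz_mean(abs(tau), times)
  tm <- abs(trapz_mean(tau, times))
  out <- ifelse(ta > 0, 0.5 * (1 - tm / ta), 0)
  out <- pmin(pmax(out, 0), 0.5)
  attr(out, "degenerate") <- ta <= 0
  out
}

#' Agreement metrics between a measured and a reference waveform
#'
#' Normalised mean error (mean absolute deviation over the cycle divided
#' by the configured normaliser of the reference, in percent), RMSE,
#' normalised RMSE (percent of the reference range) and the Pearson
#' correlation coefficient.
#'
#' @param measured,reference waveforms on a common time base.
#' @param normalization denominator of the normalised mean error:
#'   `"max"` (default), `"mean"` or `"range"` of `|reference|`.
#' @return list `nme_pct`, `rmse`, `nrmse_pct`, `pcc`.
#' @export
waveform_metrics <- function(measured, reference,
                             normalization = c("max", "mean", "range")) {
  normalization <- match.arg(normalization)
  stopifnot(length(measured) == length(reference))
  rng <- max(reference) - min(reference)
  if (rng == 0) stop("constant reference: NRMSE undefined")
  den <- switch(normalization,
                max = max(abs(reference)),
                mean = mean(abs(reference)),
                range = rng)
  err <- measured - reference
  list(nme_pct = mean(abs(err)) / den * 100,
       rmse = sqrt(mean(err^2)),
       nrmse_pct = sqrt(mean(err^2)) / rng * 100,
       pcc = stats::cor(measured, reference))
}
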