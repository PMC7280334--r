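#' Time-resolved image stack
#'
#' The common currency of the pipeline: a T-frame stack of 2-D intensity
#' images with physical pixel spacing and a fixed frame interval. Frames are
#' stored rows = axial (y, positive downward, toward increasing depth),
#' columns = lateral (x). Pixel indices are 0-based with pixel-centre
#' registration; physical coordinates in metres.
#'
#' @param data numeric array `ny x nx x T` (a single matrix is promoted to a
#'   one-frame stack).
#' @param pixel_spacing numeric length-2, metres per pixel, `c(axial, lateral)`.
#' @param frame_interval frame-to-frame time step in seconds.
#' @param t0 acquisition time of the first frame (s).
#' @param angle optional steering-angle label for per-angle low-resolution
#'   stacks.
#' @return An object of class `echo_stack`.
#' @export
image_stack <- function(data, pixel_spacing, frame_interval, t0 = 0, angle = NA_real_) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L, length(pixel_spacing) == 2L,
            all(pixel_spacing > 0), frame_interval > 0)
  structure(list(data = data,
                 pixel_spacing = as.numeric(pixel_spacing),
                 frame_interval = as.numeric(frame_interval),
                 t0 = as.numeric(t0),
                 angle = angle),
            class = "echo_stack")
}

#' @export
print.echo_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_stack> %d x %d px, %d frame(s), %.3g/%.3g m/px (ax/lat), dt = %.3g s\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2], x$frame_interval))
  invisible(x)
}

#' @export
`[.echo_stack` <- function(x, i) {
  image_stack(x$data[, , i, drop = FALSE], x$pixel_spacing, x$frame_interval,
              t0 = x$t0 + (min(i) - 1) * x$frame_interval, angle = x$angle)
}

#' Number of frames in a stack
#' @param stack an `echo_stack`.
#' @export
n_frames <- function(stack) dim(stack$data)[3]

#' Frame acquisition times of a stack
#' @param stack an `echo_stack`.
#' @export
frame_times <- function(stack) stack$t0 + (seq_len(n_frames(stack)) - 1) * stack$frame_interval

#' Gridded 2-D velocity field time series
#'
#' Velocities on a regular sub-grid of the image, one slice per analysed
#' frame pair. `u` is lateral (x), `v` axial (y, positive downward), both in
#' m/s unless `units = "px"`.
#'
#' @param u,v numeric arrays `nyg x nxg x T`.
#' @param x,y grid-node pixel coordinates (0-based, length nxg / nyg).
#' @param valid logical array, same shape as `u`; FALSE marks missing or
#'   rejected vectors.
#' @param times time stamp (s) of each slice.
#' @param pixel_spacing metres per pixel `c(axial, lateral)` of the parent
#'   image.
#' @param pair_interval time separation (s) of the correlated frame pair.
#' @param units `"mps"` or `"px"` (pixels/frame).
#' @param interpolated logical array marking vectors replaced during
#'   validation.
#' @return An object of class `echo_vfield`.
#' @export
velocity_field <- function(u, v, x, y, valid = NULL, times = NULL,
                           pixel_spacing = c(1, 1), pair_interval = 1,
                           units = "mps", interpolated = NULL) {
  if (is.matrix(u)) { u <- array(u, c(dim(u), 1L)); v <- array(v, c(dim(v), 1L)) }
  stopifnot(identical(dim(u), dim(v)), length(x) == dim(u)[2], length(y) == dim(u)[1])
  if (is.null(valid)) valid <- array(is.finite(u) & is.finite(v), dim(u))
  if (is.null(times)) times <- seq_len(dim(u)[3]) - 1
  if (is.null(interpolated)) interpolated <- array(FALSE, dim(u))
  structure(list(u = u, v = v, x = as.numeric(x), y = as.numeric(y),
                 valid = valid, times = as.numeric(times),
                 pixel_spacing = as.numeric(pixel_spacing),
                 pair_interval = as.numeric(pair_interval),
                 units = units, interpolated = interpolated),
            class = "echo_vfield")
}

#' @export
print.echo_vfield <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<echo_vfield> %d x %d grid, %d frame(s), units = %s, %.1f%% valid\n",
              d[1], d[2], d[3], x$units, 100 * mean(x$valid)))
  invisible(x)
}

#' Convert a pixel-displacement field to m/s
#'
#' Pixels/frame become m/s through the pixel spacing and the pair interval:
#' `u_mps = u_px * spacing_lateral / pair_interval` (and axial likewise).
#'
#' @param field an `echo_vfield` with `units == "px"`.
#' @export
field_to_mps <- function(field) {
  if (field$units == "mps") return(field)
  field$u <- field$u * field$pixel_spacing[2] / field$pair_interval
  field$v <- field$v * field$pixel_spacing[1] / field$pair_interval
  field$units <- "mps"
  field
}

#' Tracked vessel-wall boundary
#'
#' Per frame, ordered wall-point polylines in physical coordinates with the
#' local tangent angle `theta` (radians between the wall-oriented and
#' image-oriented coordinate frames) and labels `side` (upper = anterior,
#' i.e. smaller axial coordinate; lower = posterior) and `vessel`
#' (primary = largest lumen, secondary otherwise).
#'
#' @param frames list (one element per frame) of data.frames with columns
#'   `x_m`, `y_m`, `x_px`, `y_px`, `theta`, `side`, `vessel`, `flagged`.
#' @param pixel_spacing metres per pixel `c(axial, lateral)`.
#' @param times frame times (s).
#' @return An object of class `echo_wall`.
#' @export
wall_boundary <- function(frames, pixel_spacing, times = NULL) {
  if (is.data.frame(frames)) frames <- list(frames)
  if (is.null(times)) times <- seq_along(frames) - 1
  structure(list(frames = frames, pixel_spacing = as.numeric(pixel_spacing),
                 times = as.numeric(times)),
            class = "echo_wall")
}

#' @export
print.echo_wall <- function(x, ...) {
  np <- if (length(x$frames)) nrow(x$frames[[1]]) else 0
  cat(sprintf("<echo_wall> %d frame(s), %d point(s) in frame 1\n",
              length(x$frames), np))
  invisible(x)
}

#' Wall shear stress series along a boundary
#'
#' Holds the signed in-plane WSS time series per boundary point together
#' with derived TAWSS and OSI values and the viscosity used.
#'
#' @param tau matrix `n_points x n_frames` of signed WSS (Pa).
#' @param times frame times (s).
#' @param points data.frame describing the boundary points (as in
#'   [wall_boundary()] frames).
#' @param mu dynamic viscosity of blood (Pa s).
#' @return An object of class `echo_wss` with elements `tau`, `times`,
#'   `points`, `mu`, `tawss`, `osi`.
#' @export
wss_series_object <- function(tau, times, points, mu) {
  structure(list(tau = tau, times = as.numeric(times), points = points, mu = mu,
                 tawss = tawss(tau, times), osi = osi(tau, times)),
            class = "echo_wss")
}

#' @export
print.echo_wss <- function(x, ...) {
  cat(sprintf("<echo_wss> %d point(s) x %d frame(s), mu = %.4g Pa s, mean TAWSS = %.3g Pa\n",
              nrow(x$tau), ncol(x$tau), x$mu, mean(x$tawss, na.rm = TRUE)))
  invisible(x)
}

## internal: bilinear interpolation of a matrix at fractional 0-based pixel
## coordinates (rows = y, cols = x); coordinates clamped to the valid domain.
bilinear <- function(img, xq, yq) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(as.vector(xq), 0), nx - 1 - 1e-9)
  y <- pmin(pmax(as.vector(yq), 0), ny - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  v00 <- img[cbind(i0, j0)];     v01 <- img[cbind(i0, j0 + 1)]
  v10 <- img[cbind(i0 + 1, j0)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

## internal: moving average along the third dimension of an array, partial
## windows renormalised at the ends.
movavg_time <- function(a, window) {
  if (window <= 1L) return(a)
  d <- dim(a); t_len <- d[3]
  cs <- array(0, c(d[1], d[2], t_len + 1))
  for (t in seq_len(t_len)) cs[, , t + 1] <- cs[, , t] + a[, , t]
  out <- array(0, d)
  half <- floor(window / 2)
  for (t in seq_len(t_len)) {
    lo <- max(1, t - half); hi <- min(t_len, t - half + window - 1)
    out[, , t] <- (cs[, , hi + 1] - cs[, , lo]) / (hi - lo + 1)
  }
  out
}
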