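## File formats: multi-page 32-bit float TIFF stacks with a JSON sidecar
## carrying the physical metadata, and long-format CSV for velocity
## fields, boundaries and WSS series. All CSVs are in SI units.

#' Write / read an image stack as multi-page TIFF with JSON sidecar
#'
#' One 32-bit float page per frame; pixel spacing, frame interval, origin
#' time and angle go to `<path>.json`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  rng <- range(stack$data)
  span <- if (diff(rng) > 0) diff(rng) else 1
  # TIFF float pages hold [0, 1]; store scaled data and the range in the
  # sidecar for lossless-within-float32 restoration
  frames <- lapply(seq_len(n_frames(stack)), function(k)
    (stack$data[, , k] - rng[1]) / span)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_spacing = stack$pixel_spacing,
               frame_interval = stack$frame_interval,
               t0 = stack$t0, angle = stack$angle,
               n_frames = n_frames(stack), data_range = rng)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  rng <- meta$data_range
  span <- if (!is.null(rng) && diff(range(rng)) > 0) rng[2] - rng[1] else 1
  off <- if (!is.null(rng)) rng[1] else 0
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * span + off
  image_stack(data, meta$pixel_spacing, meta$frame_interval,
              t0 = meta$t0 %||% 0, angle = meta$angle %||% NA_real_)
}

#' Write a velocity field as long-format CSV
#'
#' Columns: frame (1-based), time_s, x_px, y_px, u_mps, v_mps, valid,
#' interpolated.
#' @param field an [velocity_field()].
#' @param path output path.
#' @export
write_velocity_csv <- function(field, path) {
  d <- dim(field$u)
  rows <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]), frame = seq_len(d[3]))
  df <- data.frame(frame = rows$frame,
                   time_s = field$times[rows$frame],
                   x_px = field$x[rows$x], y_px = field$y[rows$y],
                   u_mps = field$u[cbind(rows$y, rows$x, rows$frame)],
                   v_mps = field$v[cbind(rows$y, rows$x, rows$frame)],
                   valid = field$valid[cbind(rows$y, rows$x, rows$frame)],
                   interpolated = field$interpolated[cbind(rows$y, rows$x, rows$frame)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame wall boundaries as CSV
#'
#' Columns: frame, time_s, vessel, side, index, x_m, y_m, theta_rad,
#' flagged.
#' @param boundaries list of boundary data.frames.
#' @param times frame times (s).
#' @param path output path.
#' @export
write_boundary_csv <- function(boundaries, times, path) {
  out <- do.call(rbind, lapply(seq_along(boundaries), function(k) {
    bd <- boundaries[[k]]
    data.frame(frame = k, time_s = times[k], vessel = bd$vessel, side = bd$side,
               index = seq_len(nrow(bd)), x_m = bd$x_m, y_m = bd$y_m,
               theta_rad = bd$theta, flagged = bd$flagged)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a WSS series (plus TAWSS / OSI per point) as CSV
#' @param wss an `echo_wss`.
#' @param path output path.
#' @export
write_wss_csv <- function(wss, path) {
  n <- nrow(wss$tau)
  long <- data.frame(point = rep(seq_len(n), ncol(wss$tau)),
                     time_s = rep(wss$times, each = n),
                     tau_pa = as.vector(wss$tau))
  utils::write.csv(long, path, row.names = FALSE)
  per_point <- data.frame(point = seq_len(n), tawss_pa = wss$tawss, osi = wss$osi)
  utils::write.csv(per_point, sub("\\.csv$", "_tawss_osi.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Export a singular-value spectrum as CSV (diagnostics)
#' @param decomp an `echo_svd`.
#' @param path output path.
#' @export
write_spectrum_csv <- function(decomp, path) {
  utils::write.csv(data.frame(component = seq_along(decomp$d),
                              singular_value = decomp$d),
                   path, row.names = FALSE)
  invisible(path)
}
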