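## End-to-end orchestration: phantom generation, clutter filtering, PIV,
## POD denoising, wall tracking, WSS estimation, and validation against
## the phantom's analytic ground truth.

#' Desk-scale in-silico phantom configuration
#'
#' The straight-tube study conditions at a grid small enough for desktop
#' replication: 128 x 288 px at 1.2e-4 / 3.0e-5 m/px (lateral / axial),
#' 2.6-2.8 mm pulsating diameter, 15 degree beam-to-flow angle, Womersley
#' flow, three angles at PRF 4500 Hz, low-noise renderer.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [phantom_config()].
#' @export
insilico_config <- function(seed = 1L, ...) {
  args <- list(image_shape = c(288L, 128L),
               pixel_spacing = c(3.0e-5, 1.2e-4),
               noise_sd = 0.02,
               seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(phantom_config, args)
}

#' Ground-truth velocity at arbitrary image locations
#'
#' Evaluates the phantom's analytic velocity field (rotated into the image
#' frame) at physical coordinates, returning `NA` outside the lumen.
#'
#' @param config a [phantom_config()].
#' @param t time (s).
#' @param x_m,y_m image-frame coordinates (m).
#' @return list `u`, `v` (m/s), `inside` (logical).
#' @export
truth_velocity_at <- function(config, t, x_m, y_m) {
  geom <- phantom_geometry(config)
  vr <- image_to_vessel(geom, x_m, y_m)
  fl <- analytic_flow(config, t, r = seq(0, config$diameter_waveform(t) / 2,
                                         length.out = 96))
  R <- fl$R
  inside <- abs(vr$r) < R
  ua <- rep(0, length(x_m))
  ua[inside] <- stats::approx(fl$r, fl$u, xout = abs(vr$r[inside]), rule = 2)$y
  vrad <- (vr$r / R) * fl$dRdt
  u <- ua * geom$a[1] + vrad * geom$n[1]
  v <- ua * geom$a[2] + vrad * geom$n[2]
  u[!inside] <- NA; v[!inside] <- NA
  list(u = u, v = v, inside = inside)
}

#' Programmatic first-frame lumen mask from the blood stack
#'
#' Thresholds the temporal mean of the clutter-filtered blood signal
#' (Otsu), keeps the largest connected component, fills holes and closes
#' small gaps: the phantom counterpart of a manually placed mask.
#'
#' @param blood_stack the blood [image_stack()] from [svd_filter()].
#' @param n_avg frames averaged.
#' @return logical mask.
#' @export
initial_lumen_mask <- function(blood_stack, n_avg = 10L) {
  n <- min(n_avg, dim(blood_stack$data)[3])
  mb <- apply(abs(blood_stack$data[, , seq_len(n), drop = FALSE]), c(1, 2), mean)
  mb <- mb / max(mb)
  thr <- EBImage::otsu(EBImage::Image(mb))
  m <- mb > thr
  lab <- matrix(as.integer(EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m)))),
                nrow(m), ncol(m))
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  img <- EBImage::Image(matrix(as.numeric(m), nrow(m), ncol(m)))
  img <- EBImage::closing(img, EBImage::makeBrush(5, "disc"))
  img <- EBImage::fillHull(img)
  matrix(as.logical(img), nrow(m), ncol(m))
}

## perpendicular diameter of the primary vessel from a boundary frame
boundary_diameter <- function(bd) {
  up <- bd[bd$side == "upper" & bd$vessel == "primary", ]
  lo <- bd[bd$side == "lower" & bd$vessel == "primary", ]
  xs <- intersect(round(up$x_px), round(lo$x_px))
  if (!length(xs)) return(NA_real_)
  yu <- stats::approx(up$x_px, up$y_m, xout = xs, rule = 2)$y
  yl <- stats::approx(lo$x_px, lo$y_m, xout = xs, rule = 2)$y
  phi <- stats::median(c(up$theta, lo$theta), na.rm = TRUE)
  mean(yl - yu) * cos(phi)
}

#' Run the full measurement chain on a phantom sequence
#'
#' Clutter-filters each per-angle stack, tracks the vessel wall on the
#' augmented compound stack, estimates the velocity field by ensemble
#' multipass PIV inside the tracked lumen, POD-filters the field series
#' and computes the WSS along the smoothed, peak-fitted boundaries.
#'
#' @param seq a `phantom_sequence` from [generate_sequence()].
#' @param pair_index 2-column matrix of (A, B) frame-slot pairs to
#'   correlate; defaults to consecutive emitted frames that are adjacent
#'   in acquisition time.
#' @param piv a [piv_config()].
#' @param pod_energy POD energy fraction (NULL disables POD).
#' @param sg_window boundary Savitzky-Golay window (points).
#' @return list with `field` (POD-filtered [velocity_field()], m/s),
#'   `field_raw`, `masks`, `boundaries` (per pair), `wss` (`echo_wss`),
#'   `D` (diameter per pair, m), `times` (pair midpoints, s), `band`s
#'   used, and the input `seq` metadata.
#' @export
run_measurement <- function(seq, pair_index = NULL, piv = piv_config(),
                            pod_energy = 0.99, sg_window = 21L,
                            noise_energy = 1.0) {
  cfg <- seq$config
  if (is.null(pair_index)) {
    adj <- which(diff(seq$frames) == 1L)
    pair_index <- cbind(adj, adj + 1L)
  }
  np <- nrow(pair_index)
  if (!np) stop("no adjacent frame pairs available")
  # clutter filter per angle stack; the noise cut is left open by default:
  # with ensemble correlation and POD downstream, an energy-based high cut
  # removes pair-specific speckle detail rather than noise
  filt <- lapply(seq$stacks, function(s) svd_filter(s, noise_energy = noise_energy))
  blood_stacks <- lapply(filt, `[[`, "blood")
  # wall tracking on the augmented compound stack
  comp_filt <- svd_filter(seq$compound)
  aug <- augment_images(seq$compound, band = comp_filt$band, decomp = comp_filt$decomp)
  init <- initial_lumen_mask(comp_filt$blood)
  masks <- track_sequence(aug, init, lambda = 0.3)
  # boundaries: DPF on the time-averaged tissue image, then SG smoothing
  tis <- movavg_time(abs(comp_filt$tissue$data), 10L)
  boundaries <- vector("list", np); D <- numeric(np)
  for (j in seq_len(np)) {
    k <- pair_index[j, 1]
    bd <- directional_peak_fit(tis[, , k], masks[[k]], cfg$pixel_spacing)
    if (any(!bd$flagged)) bd <- bd[!bd$flagged, ]   # drop mask-contour fallbacks
    bd <- smooth_boundary(bd, window = sg_window, order = 2L,
                          pixel_spacing = cfg$pixel_spacing)
    boundaries[[j]] <- bd
    D[j] <- boundary_diameter(bd)
  }
  times_mid <- seq$times[pair_index[, 1]] + cfg$frame_interval / 2
  field_raw <- piv_series(blood_stacks, pair_index = pair_index, config = piv,
                          masks = masks[pair_index[, 1]], times = times_mid)
  field_full <- if (is.null(pod_energy)) field_raw else
    pod_filter(field_raw, energy_fraction = pod_energy)
  # strict validity for reported velocities: only vectors whose final
  # interrogation window fits inside the lumen (windows straddling the wall
  # are weighted toward the bright moving interior and overestimate the
  # near-wall velocity); the WSS profile keeps the full field, where the
  # long Savitzky-Golay filter moderates the near-wall bias and the genuine
  # near-wall flow reversal is retained
  w_final <- piv$window %/% (2^(piv$passes - 1))
  brush <- matrix(1, 2L * (w_final %/% 2L) + 1L, 3L)
  field <- field_full
  for (j in seq_len(np)) {
    m <- masks[[pair_index[j, 1]]]
    er <- matrix(as.logical(EBImage::erode(
      matrix(as.numeric(m), nrow(m), ncol(m)), brush)), nrow(m), ncol(m))
    node_in <- er[cbind(round(rep(field$y, length(field$x))) + 1,
                        round(rep(field$x, each = length(field$y))) + 1)]
    field$valid[, , j] <- field$valid[, , j] &
      matrix(node_in, length(field$y), length(field$x))
  }
  wss <- wss_series_multi(field_full, boundaries, D, mu_b = cfg$blood_viscosity)
  # final segmentation: level-set mask closed onto the peak-fitted walls
  masks_final <- lapply(boundaries, function(bd)
    boundary_mask(bd, dim(seq$compound$data)[1:2], cfg$pixel_spacing))
  list(field = field, field_full = field_full, field_raw = field_raw,
       masks = masks, masks_final = masks_final,
       boundaries = boundaries, wss = wss, D = D, times = times_mid,
       pair_index = pair_index, bands = lapply(filt, `[[`, "band"),
       aug = aug, config = cfg)
}

## wss_series over per-frame boundaries with varying point counts: pads to
## the largest chain
wss_series_multi <- function(field, boundaries, D, mu_b) {
  T_len <- dim(field$u)[3]
  npts <- max(vapply(boundaries, nrow, integer(1)))
  tau <- matrix(NA_real_, npts, T_len)
  for (k in seq_len(T_len)) {
    sh <- near_wall_shear(field, boundaries[[k]], D[k], k = k)
    tau[seq_along(sh), k] <- wss_from_shear(sh, mu_b)
  }
  wss_series_object(tau, field$times, boundaries[[1]], mu_b)
}

#' Validate a measurement run against the phantom ground truth
#'
#' Recomputes the analytic truth at the PIV grid nodes and pair times and
#' reports: the normalised mean error of the spatially averaged velocity
#' waveform, the same for the boundary-averaged WSS waveform, the
#' point-by-point velocity-magnitude error (percent of the global truth
#' maximum), the point-by-point flow-direction error (degrees, vectors
#' above the magnitude floor), and segmentation DSC / MADW against the
#' true lumen.
#'
#' @param meas result of [run_measurement()].
#' @param config the [phantom_config()] that generated the data.
#' @param floor_frac magnitude floor for direction errors, as a fraction
#'   of the peak true speed.
#' @param normalization normaliser for the waveform errors (see
#'   [waveform_metrics()]).
#' @return list of class `validation_report`.
#' @export
validate_against_truth <- function(meas, config, floor_frac = 0.05,
                                   normalization = "max") {
  sp <- config$pixel_spacing
  gx <- meas$field$x * sp[2]; gy <- meas$field$y * sp[1]
  X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  Y <- matrix(gy, length(gy), length(gx))
  np <- length(meas$times)
  v_meas <- numeric(np); v_true <- numeric(np)
  mag_err <- c(); dir_err <- c()
  speed_true_all <- c()
  tu_all <- vector("list", np)
  for (j in seq_len(np)) {
    tr <- truth_velocity_at(config, meas$times[j], as.vector(X), as.vector(Y))
    tu_all[[j]] <- tr
    speed_true_all <- c(speed_true_all, sqrt(tr$u^2 + tr$v^2))
  }
  vmax <- max(speed_true_all, na.rm = TRUE)
  for (j in seq_len(np)) {
    tr <- tu_all[[j]]
    su <- as.vector(meas$field$u[, , j]); sv <- as.vector(meas$field$v[, , j])
    ok <- as.vector(meas$field$valid[, , j]) & tr$inside &
      is.finite(su) & is.finite(sv)
    sp_m <- sqrt(su[ok]^2 + sv[ok]^2)
    sp_t <- sqrt(tr$u[ok]^2 + tr$v[ok]^2)
    v_meas[j] <- mean(sp_m); v_true[j] <- mean(sp_t)
    mag_err <- c(mag_err, abs(sp_m - sp_t) / vmax * 100)
    fl <- sp_t > floor_frac * vmax & sp_m > 0
    dotp <- (su[ok][fl] * tr$u[ok][fl] + sv[ok][fl] * tr$v[ok][fl]) /
      (sp_m[fl] * sp_t[fl])
    dir_err <- c(dir_err, acos(pmin(pmax(dotp, -1), 1)) * 180 / pi)
  }
  metrics_safe <- function(m, r) {
    if (max(r) - min(r) == 0)   # steady reference: range-normalised RMSE undefined
      list(nme_pct = mean(abs(m - r)) / max(abs(r)) * 100,
           rmse = sqrt(mean((m - r)^2)), nrmse_pct = NA_real_, pcc = NA_real_)
    else waveform_metrics(m, r, normalization)
  }
  vel_wave <- metrics_safe(v_meas, v_true)
  # WSS waveform: boundary-averaged measurement vs analytic truth
  wss_meas <- colMeans(meas$wss$tau, na.rm = TRUE)
  wss_true <- analytic_wss(config, meas$times)
  wss_wave <- metrics_safe(wss_meas, wss_true)
  # segmentation scores at the pair frames
  truth <- phantom_ground_truth(config, meas$times)
  dsc <- numeric(np); mad_m <- numeric(np)
  msk <- meas$masks_final %||% meas$masks[meas$pair_index[, 1]]
  for (j in seq_len(np)) {
    dsc[j] <- dice(msk[[j]], truth$lumen[, , j])
    mad_m[j] <- madw(meas$boundaries[[j]], truth$wall$frames[[j]])
  }
  structure(list(velocity_waveform_error_pct = vel_wave$nme_pct,
                 wss_waveform_error_pct = wss_wave$nme_pct,
                 velocity_magnitude_error_pct = mean(mag_err),
                 velocity_magnitude_error_sd_pct = stats::sd(mag_err),
                 direction_error_deg = mean(dir_err),
                 direction_error_sd_deg = stats::sd(dir_err),
                 dsc = mean(dsc), madw_m = mean(mad_m),
                 n_frames = np,
                 n_points_magnitude = length(mag_err),
                 n_points_direction = length(dir_err),
                 dsc_per_frame = dsc, madw_per_frame_m = mad_m,
                 v_meas = v_meas, v_true = v_true,
                 wss_meas = wss_meas, wss_true = wss_true,
                 vel_metrics = vel_wave, wss_metrics = wss_wave,
                 times = meas$times),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("In-silico validation report\n")
  cat(sprintf("  velocity waveform error : %.3f %%\n", x$velocity_waveform_error_pct))
  cat(sprintf("  WSS waveform error      : %.3f %%\n", x$wss_waveform_error_pct))
  cat(sprintf("  velocity magnitude error: %.2f +/- %.2f %%\n",
              x$velocity_magnitude_error_pct, x$velocity_magnitude_error_sd_pct))
  cat(sprintf("  direction error         : %.2f +/- %.2f deg\n",
              x$direction_error_deg, x$direction_error_sd_deg))
  cat(sprintf("  DSC = %.3f, MADW = %.1f um\n", x$dsc, x$madw_m * 1e6))
  invisible(x)
}

#' One-call in-silico validation experiment
#'
#' Generates the desk-scale straight-tube phantom, runs the full
#' measurement chain and scores it against the analytic ground truth.
#' `n_pairs` frame pairs are analysed, spread evenly over one cardiac
#' cycle.
#'
#' @param seed integer seed (drives phantom placement, amplitudes and
#'   noise).
#' @param n_pairs analysed frame pairs per cycle.
#' @param ... overrides for [insilico_config()].
#' @return list `report` ([validate_against_truth()]), `meas`, `seq`.
#' @export
insilico_validation <- function(seed = 1L, n_pairs = 40L, ...) {
  cfg <- insilico_config(seed = seed, ...)
  n_total <- ceiling(cfg$cycle_period / cfg$frame_interval)
  starts <- unique(round(seq(1, n_total - 1, length.out = n_pairs)))
  frames <- sort(unique(c(starts, starts + 1L)))
  seq_ <- generate_sequence(cfg, frames = frames)
  slot <- match(starts, seq_$frames)
  meas <- run_measurement(seq_, pair_index = cbind(slot, slot + 1L))
  report <- validate_against_truth(meas, cfg)
  list(report = report, meas = meas, seq = seq_)
}

#' Run the pipeline from a configuration list and write artifacts
#'
#' Thin orchestration for scripted use: generates (or loads) the phantom,
#' runs [run_measurement()] and [validate_against_truth()], and writes the
#' image stacks, velocity field, boundaries, WSS series and a JSON
#' manifest (config hash, seed, versions) under `out_dir`.
#'
#' @param config nested list (or path to a YAML file) with optional blocks
#'   `phantom`, `piv`, `run` (`n_pairs`), `seed`.
#' @param out_dir output directory, created if missing.
#' @return The validation report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("echowss_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  n_pairs <- config$run$n_pairs %||% 40L
  phantom_args <- config$phantom %||% list()
  res <- do.call(insilico_validation,
                 c(list(seed = seed, n_pairs = n_pairs), phantom_args))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack_tiff(res$seq$compound, file.path(out_dir, "compound.tif"))
  write_velocity_csv(res$meas$field, file.path(out_dir, "velocity.csv"))
  write_boundary_csv(res$meas$boundaries, res$meas$times,
                     file.path(out_dir, "boundaries.csv"))
  write_wss_csv(res$meas$wss, file.path(out_dir, "wss.csv"))
  manifest <- list(seed = seed, n_pairs = n_pairs,
                   package_version = as.character(utils::packageVersion("echowss")),
                   r_version = R.version.string,
                   config = config,
                   report = unclass(res$report[c("velocity_waveform_error_pct",
                                                 "wss_waveform_error_pct",
                                                 "velocity_magnitude_error_pct",
                                                 "direction_error_deg",
                                                 "dsc", "madw_m")]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res$report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
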