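## Synthetic moving-wall pulsatile-flow speckle phantom.
##
## A straight vessel with circular cross-section crosses the image at the
## beam-to-flow angle. Microbubble-like scatterers in the lumen are advected
## by an analytic Womersley/Poiseuille flow; a three-layer wall and the
## surrounding tissue move radially with the prescribed diameter waveform.
## Frames are rendered by stamping a separable Gaussian point-spread
## function at each scatterer position (envelope of the coherent sum), so
## the ground-truth velocity and wall shear stress are known exactly.

default_velocity_waveform <- function(period) {
  force(period)
  function(t) {
    s <- (t / period) %% 1
    0.05 + 0.42 * exp(-((s - 0.18) / 0.075)^2) - 0.035 * exp(-((s - 0.42) / 0.06)^2)
  }
}

default_diameter_waveform <- function(period) {
  force(period)
  function(t) {
    s <- (t / period) %% 1
    2.6e-3 + 0.2e-3 * exp(-((s - 0.25) / 0.11)^2)
  }
}

#' Phantom configuration
#'
#' Assembles the study conditions of the in-silico phantom: a 2.6-2.8 mm
#' pulsating vessel with a uniform 200 um three-layer wall, imaged at a 15
#' degree beam-to-flow angle with three steered transmissions per frame at a
#' PRF of 4500 Hz (compounded frame rate 1500 fps). Scatterer amplitude
#' statistics default to mean +/- SD pairs of (tissue 2.5/0.01, intima 0/1,
#' media 2.5/0.01, adventitia 0/0.01, microbubble 1.4/0.01); the mean is a
#' symmetric random sign times the stated magnitude with Gaussian jitter of
#' the stated SD.
#'
#' @param diameter_waveform function of time returning the lumen diameter
#'   (m); default pulsates between 2.6e-3 and 2.8e-3 over the cycle.
#' @param mean_velocity_waveform function of time returning the spatial-mean
#'   axial velocity (m/s); default is a systolic pulse peaking at ~0.47 m/s
#'   with a slow diastolic tail.
#' @param cycle_period cardiac cycle length (s).
#' @param beam_to_flow_angle degrees between the vessel axis and the lateral
#'   image axis.
#' @param wall_thickness total wall thickness (m), split into three equal
#'   layers (intima, media, adventitia).
#' @param layer_amplitudes named list of `c(mean, sd)` per compartment
#'   (`lumen`, `intima`, `media`, `adventitia`, `tissue`).
#' @param scatterer_density lumen scatterers per resolution cell (the cell
#'   being the product of the PSF FWHMs).
#' @param wall_density,tissue_density scatterers per resolution cell for the
#'   wall layers and background tissue.
#' @param image_shape `c(axial px, lateral px)`.
#' @param pixel_spacing `c(axial, lateral)` m/px.
#' @param prf pulse repetition frequency (Hz).
#' @param n_angles steered transmissions compounded per frame.
#' @param frame_interval s; must equal `n_angles / prf`.
#' @param blood_density kg/m^3.
#' @param blood_viscosity Pa s.
#' @param flow_model `"womersley"` or `"poiseuille"`.
#' @param n_harmonics harmonics used for the Womersley decomposition.
#' @param psf_fwhm point-spread-function full width at half maximum,
#'   `c(axial, lateral)` in m.
#' @param noise_sd additive Gaussian background noise (image units).
#' @param seed integer seed; fanned out into independent sub-streams for
#'   placement, amplitudes and noise.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(diameter_waveform = NULL,
                           mean_velocity_waveform = NULL,
                           cycle_period = 0.33,
                           beam_to_flow_angle = 15,
                           wall_thickness = 200e-6,
                           layer_amplitudes = NULL,
                           scatterer_density = 10,
                           wall_density = 30,
                           tissue_density = 3,
                           image_shape = c(512L, 128L),
                           pixel_spacing = c(3.0e-5, 3.0e-4),
                           prf = 4500,
                           n_angles = 3,
                           frame_interval = NULL,
                           blood_density = 1044.0,
                           blood_viscosity = 4.043e-3,
                           flow_model = c("womersley", "poiseuille"),
                           n_harmonics = 8,
                           psf_fwhm = c(0.25e-3, 0.45e-3),
                           noise_sd = 0.05,
                           seed = 1L) {
  flow_model <- match.arg(flow_model)
  stopifnot(cycle_period > 0, wall_thickness > 0, prf > 0, n_angles >= 1)
  if (is.null(diameter_waveform)) diameter_waveform <- default_diameter_waveform(cycle_period)
  if (is.null(mean_velocity_waveform)) mean_velocity_waveform <- default_velocity_waveform(cycle_period)
  if (is.null(frame_interval)) frame_interval <- n_angles / prf
  if (abs(frame_interval - n_angles / prf) > 1e-12)
    stop("frame_interval must equal n_angles / prf")
  ts <- seq(0, cycle_period, length.out = 257)
  if (any(!is.finite(diameter_waveform(ts))) || any(diameter_waveform(ts) <= 0))
    stop("diameter_waveform must be positive over the cycle")
  if (is.null(layer_amplitudes))
    layer_amplitudes <- list(lumen = c(1.4, 0.01), intima = c(0, 1),
                             media = c(2.5, 0.01), adventitia = c(0, 0.01),
                             tissue = c(2.5, 0.01))
  if (length(layer_amplitudes) != 5L)
    stop("layer_amplitudes must name lumen, intima, media, adventitia, tissue")
  cfg <- list(diameter_waveform = diameter_waveform,
              mean_velocity_waveform = mean_velocity_waveform,
              cycle_period = cycle_period,
              beam_to_flow_angle = beam_to_flow_angle,
              wall_thickness = wall_thickness,
              layer_amplitudes = layer_amplitudes,
              scatterer_density = scatterer_density,
              wall_density = wall_density,
              tissue_density = tissue_density,
              image_shape = as.integer(image_shape),
              pixel_spacing = as.numeric(pixel_spacing),
              prf = prf, n_angles = as.integer(n_angles),
              frame_interval = frame_interval,
              blood_density = blood_density,
              blood_viscosity = blood_viscosity,
              flow_model = flow_model,
              psf_fwhm = as.numeric(psf_fwhm),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (flow_model == "womersley") {
    if (cycle_period <= 0) stop("womersley mode requires a positive cycle_period")
    cfg$.harmonics <- waveform_harmonics(mean_velocity_waveform, cycle_period,
                                         n_harmonics = max(8, n_harmonics))
  }
  class(cfg) <- "phantom_config"
  cfg
}

## deterministic sub-stream seeds derived from the master seed
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 1297) %% 2147483647)
}

## vessel-frame geometry helpers ------------------------------------------

phantom_geometry <- function(config) {
  phi <- config$beam_to_flow_angle * pi / 180
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  sp <- config$pixel_spacing
  centre <- c(x = (nx - 1) / 2 * sp[2], y = (ny - 1) / 2 * sp[1])
  a <- c(cos(phi), sin(phi))    # axis direction (x, y), y positive downward
  n <- c(-sin(phi), cos(phi))   # normal direction; r > 0 is the lower side
  corners <- rbind(c(0, 0), c((nx - 1) * sp[2], 0),
                   c(0, (ny - 1) * sp[1]), c((nx - 1) * sp[2], (ny - 1) * sp[1]))
  rel <- sweep(corners, 2, centre)
  s_corner <- rel %*% a
  r_corner <- rel %*% n
  margin <- 4 * max(config$psf_fwhm)
  list(phi = phi, centre = centre, a = a, n = n,
       s_range = range(s_corner) + c(-1, 1) * margin,
       r_range = range(r_corner) + c(-1, 1) * margin,
       extent = c(x = (nx - 1) * sp[2], y = (ny - 1) * sp[1]))
}

## (s, r) vessel-frame -> (x, y) image-frame metres
vessel_to_image <- function(geom, s, r) {
  list(x = geom$centre[1] + s * geom$a[1] + r * geom$n[1],
       y = geom$centre[2] + s * geom$a[2] + r * geom$n[2])
}

## (x, y) image-frame metres -> (s, r)
image_to_vessel <- function(geom, x, y) {
  dx <- x - geom$centre[1]; dy <- y - geom$centre[2]
  list(s = dx * geom$a[1] + dy * geom$a[2],
       r = dx * geom$n[1] + dy * geom$n[2])
}

draw_amplitudes <- function(n, ms, coherent = FALSE) {
  sgn <- if (coherent) 1 else sample(c(-1, 1), n, replace = TRUE)
  sgn * ms[1] + stats::rnorm(n, 0, ms[2])
}

#' Seed the phantom scatterer population
#'
#' Places scatterers uniformly in the vessel-frame rectangle covering the
#' image: microbubble scatterers inside the instantaneous lumen, three wall
#' layers of equal thickness on both sides, and background tissue outside
#' the wall. Amplitudes are drawn per compartment from the configured
#' mean +/- SD model.
#'
#' @param config a [phantom_config()].
#' @param t time (s) defining the instantaneous lumen radius.
#' @return A `scatterer_set`: data.frame with columns `s`, `r` (vessel-frame
#'   coordinates, m), `amp`, `compartment`.
#' @export
seed_scatterers <- function(config, t = 0) {
  geom <- phantom_geometry(config)
  R <- config$diameter_waveform(t) / 2
  lt <- config$wall_thickness / 3
  cell <- prod(config$psf_fwhm)
  seg_len <- diff(geom$s_range)
  dens <- function(per_cell) per_cell / cell
  set.seed(substream_seed(config$seed, 1))

  coh <- config$coherent_compartments %||% "media"
  mk <- function(n, r_lo, r_hi, comp, two_sided = TRUE) {
    if (n <= 0) return(NULL)
    side <- if (two_sided) sample(c(-1, 1), n, replace = TRUE) else 1
    data.frame(s = stats::runif(n, geom$s_range[1], geom$s_range[2]),
               r = side * stats::runif(n, r_lo, r_hi),
               amp = draw_amplitudes(n, config$layer_amplitudes[[comp]],
                                     coherent = comp %in% coh),
               compartment = comp, stringsAsFactors = FALSE)
  }
  n_lumen <- round(dens(config$scatterer_density) * seg_len * 2 * R)
  lum <- data.frame(s = stats::runif(n_lumen, geom$s_range[1], geom$s_range[2]),
                    r = stats::runif(n_lumen, -R, R),
                    amp = draw_amplitudes(n_lumen, config$layer_amplitudes$lumen),
                    compartment = "lumen", stringsAsFactors = FALSE)
  n_layer <- round(dens(config$wall_density) * seg_len * lt)  # per side
  walls <- rbind(mk(2 * n_layer, R, R + lt, "intima"),
                 mk(2 * n_layer, R + lt, R + 2 * lt, "media"),
                 mk(2 * n_layer, R + 2 * lt, R + 3 * lt, "adventitia"))
  r_out <- max(abs(geom$r_range))
  n_tis <- round(dens(config$tissue_density) * seg_len * 2 * (r_out - R - 3 * lt))
  tis <- mk(n_tis, R + 3 * lt, r_out, "tissue")
  sc <- rbind(lum, walls, tis)
  class(sc) <- c("scatterer_set", class(sc))
  sc
}

#' Advect the scatterer population over one time step
#'
#' Lumen scatterers move axially by their local analytic velocity times
#' `dt` and radially with the wall so that `r / R(t)` is preserved (the
#' integral of the radial velocity component `(r/R) dR/dt`). Wall scatterers
#' translate radially with the inner-wall displacement (rigid three-layer
#' cross-section); tissue displacement decays exponentially away from the
#' adventitia. A lumen scatterer found outside the new lumen radius raises
#' an error: wall crossings indicate a bug, and are never clamped.
#'
#' @param sc a `scatterer_set`.
#' @param config a [phantom_config()].
#' @param t current time (s).
#' @param dt time step (s); defaults to one pulse interval `1/prf`.
#' @param velocity optional override `function(s, r, t)` returning
#'   `list(u_axial, v_radial)` in m/s, used in place of the analytic flow.
#' @return The advected `scatterer_set`.
#' @export
advect_scatterers <- function(sc, config, t, dt = 1 / config$prf, velocity = NULL) {
  R0 <- config$diameter_waveform(t) / 2
  R1 <- config$diameter_waveform(t + dt) / 2
  lum <- sc$compartment == "lumen"
  if (any(lum)) {
    if (is.null(velocity)) {
      prof <- analytic_flow(config, t, r = seq(0, R0, length.out = 48))
      u <- stats::approx(prof$r, prof$u, xout = pmin(abs(sc$r[lum]), R0),
                         rule = 2)$y
      sc$s[lum] <- sc$s[lum] + u * dt
      sc$r[lum] <- sc$r[lum] * (R1 / R0)
    } else {
      vel <- velocity(sc$s[lum], sc$r[lum], t)
      sc$s[lum] <- sc$s[lum] + vel$u_axial * dt
      sc$r[lum] <- sc$r[lum] + vel$v_radial * dt
    }
    if (any(abs(sc$r[lum]) > R1 * (1 + 1e-6)))
      stop("lumen scatterer crossed the wall during advection")
  }
  dR <- R1 - R0
  wall <- sc$compartment %in% c("intima", "media", "adventitia")
  sc$r[wall] <- sc$r[wall] + sign(sc$r[wall]) * dR
  tis <- sc$compartment == "tissue"
  if (any(tis)) {
    R_out <- R0 + config$wall_thickness
    decay <- exp(-pmax(abs(sc$r[tis]) - R_out, 0) / 1.5e-3)
    sc$r[tis] <- sc$r[tis] + sign(sc$r[tis]) * dR * decay
  }
  sc
}

#' Replenish washed-out lumen scatterers
#'
#' The image is partitioned into a 20 x 20 grid of sub-regions (each 5% of
#' the image length by 5% of its width). In every sub-region whose
#' lumen-scatterer count has fallen below the density target, uniformly
#' placed scatterers are added inside the lumen portion of that sub-region;
#' counts are never reduced. Lumen scatterers that have left the image
#' (plus a PSF margin) are dropped first.
#'
#' @inheritParams advect_scatterers
#' @return The replenished `scatterer_set`.
#' @export
replenish_scatterers <- function(sc, config, t) {
  geom <- phantom_geometry(config)
  R <- config$diameter_waveform(t) / 2
  margin <- 4 * max(config$psf_fwhm)
  pos <- vessel_to_image(geom, sc$s, sc$r)
  lum <- sc$compartment == "lumen"
  off <- lum & (pos$x < -margin | pos$x > geom$extent["x"] + margin |
                pos$y < -margin | pos$y > geom$extent["y"] + margin)
  if (any(off)) {
    sc <- sc[!off, ]
    pos <- list(x = pos$x[!off], y = pos$y[!off])
    lum <- sc$compartment == "lumen"
  }
  ngrid <- 20L
  wx <- geom$extent["x"] / ngrid; wy <- geom$extent["y"] / ngrid
  ix <- pmin(pmax(floor(pos$x / wx), 0), ngrid - 1)
  iy <- pmin(pmax(floor(pos$y / wy), 0), ngrid - 1)
  cellidx <- ix * ngrid + iy
  counts <- tabulate(cellidx[lum] + 1, nbins = ngrid * ngrid)

  # lumen area per sub-region from a fixed 6x6 midpoint subgrid
  dens <- config$scatterer_density / prod(config$psf_fwhm)
  sub <- (seq_len(6) - 0.5) / 6
  gx <- rep(sub, each = 6); gy <- rep(sub, times = 6)
  add <- vector("list", 0)
  for (cx in 0:(ngrid - 1)) for (cy in 0:(ngrid - 1)) {
    px <- (cx + gx) * wx; py <- (cy + gy) * wy
    vr <- image_to_vessel(geom, px, py)
    frac <- mean(abs(vr$r) < R)
    if (frac == 0) next
    target <- round(dens * wx * wy * frac)
    have <- counts[cx * ngrid + cy + 1]
    deficit <- target - have
    if (deficit <= 0) next
    got <- 0; tries <- 0
    while (got < deficit && tries < 30) {
      m <- max(4 * deficit, 16)
      qx <- stats::runif(m, cx * wx, (cx + 1) * wx)
      qy <- stats::runif(m, cy * wy, (cy + 1) * wy)
      vq <- image_to_vessel(geom, qx, qy)
      keep <- which(abs(vq$r) < R)
      keep <- keep[seq_len(min(length(keep), deficit - got))]
      if (length(keep)) {
        add[[length(add) + 1]] <- data.frame(
          s = vq$s[keep], r = vq$r[keep],
          amp = draw_amplitudes(length(keep), config$layer_amplitudes$lumen),
          compartment = "lumen", stringsAsFactors = FALSE)
        got <- got + length(keep)
      }
      tries <- tries + 1
    }
  }
  if (length(add)) sc <- rbind(sc, do.call(rbind, add))
  class(sc) <- unique(c("scatterer_set", class(sc)))
  sc
}

#' Render one B-mode-like frame from the scatterer population
#'
#' The image is the sum of amplitude-weighted separable Gaussian PSFs
#' stamped at the scatterer positions rotated into the image frame, plus
#' additive Gaussian background noise. The returned field is the signed
#' linear superposition (so rendering is additive in disjoint scatterer
#' sets); the envelope `abs()` applied by [generate_sequence()] produces
#' the speckle image. Scatterers falling outside the image are clipped
#' silently.
#'
#' @inheritParams advect_scatterers
#' @param noise_sd standard deviation of the additive noise; defaults to
#'   the configured value.
#' @return `ny x nx` numeric matrix.
#' @export
render_frame <- function(sc, config, noise_sd = config$noise_sd) {
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  img <- matrix(0, ny, nx)
  geom <- phantom_geometry(config)
  if (nrow(sc)) {
    pos <- vessel_to_image(geom, sc$s, sc$r)
    sp <- config$pixel_spacing
    cx <- pos$x / sp[2]; cy <- pos$y / sp[1]       # 0-based fractional px
    sigy <- config$psf_fwhm[1] / 2.355 / sp[1]
    sigx <- config$psf_fwhm[2] / 2.355 / sp[2]
    hwy <- ceiling(3 * sigy); hwx <- ceiling(3 * sigx)
    keep <- cx > -hwx & cx < nx - 1 + hwx & cy > -hwy & cy < ny - 1 + hwy
    if (any(keep)) {
      cx <- cx[keep]; cy <- cy[keep]; amp <- sc$amp[keep]
      bx <- round(cx); by <- round(cy)
      nsc <- length(cx)
      # the PSF is separable: accumulate axial and lateral Gaussian factors
      # as sparse matrices and render as their product
      nyo <- 2 * hwy + 1; nxo <- 2 * hwx + 1
      ii <- rep(by, nyo) + rep(-hwy:hwy, each = nsc) + 1
      wy <- exp(-((ii - 1 - rep(cy, nyo))^2) / (2 * sigy^2)) * rep(amp, nyo)
      oky <- ii >= 1 & ii <= ny
      A <- Matrix::sparseMatrix(i = ii[oky], j = rep(seq_len(nsc), nyo)[oky],
                                x = wy[oky], dims = c(ny, nsc))
      jj <- rep(bx, nxo) + rep(-hwx:hwx, each = nsc) + 1
      wx <- exp(-((jj - 1 - rep(cx, nxo))^2) / (2 * sigx^2))
      okx <- jj >= 1 & jj <= nx
      B <- Matrix::sparseMatrix(i = rep(seq_len(nsc), nxo)[okx], j = jj[okx],
                                x = wx[okx], dims = c(nsc, nx))
      img <- as.matrix(A %*% B)
    }
  }
  if (noise_sd > 0) img <- img + stats::rnorm(ny * nx, 0, noise_sd)
  img
}

#' Ground truth of the phantom on the image grid
#'
#' Samples the analytic flow on the pixel grid at the requested times and
#' reports the true wall locations and wall shear stress.
#'
#' @param config a [phantom_config()].
#' @param times times (s) at which to evaluate.
#' @return list of class `phantom_truth` with elements `u`, `v`
#'   (`ny x nx x T` m/s, `NA` outside the lumen), `speed`, `lumen`
#'   (logical array), `wall` (a [wall_boundary()] of the true inner wall),
#'   `wss` (Pa, per time), `v_mean` (spatial mean lumen speed per time),
#'   `times`, `R` (lumen radius per time).
#' @export
phantom_ground_truth <- function(config, times) {
  geom <- phantom_geometry(config)
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  sp <- config$pixel_spacing
  xs <- (seq_len(nx) - 1) * sp[2]; ys <- (seq_len(ny) - 1) * sp[1]
  X <- matrix(xs, ny, nx, byrow = TRUE); Y <- matrix(ys, ny, nx)
  vr <- image_to_vessel(geom, as.vector(X), as.vector(Y))
  S <- matrix(vr$s, ny, nx); Rr <- matrix(vr$r, ny, nx)
  T_len <- length(times)
  u <- array(NA_real_, c(ny, nx, T_len)); v <- u
  lumen <- array(FALSE, c(ny, nx, T_len))
  wss <- numeric(T_len); v_mean <- numeric(T_len); Rt <- numeric(T_len)
  wall_frames <- vector("list", T_len)
  for (k in seq_len(T_len)) {
    fl <- analytic_flow(config, times[k], r = seq(0, config$diameter_waveform(times[k]) / 2,
                                                  length.out = 96))
    R <- fl$R; Rt[k] <- R
    inside <- abs(Rr) < R
    ua <- matrix(0, ny, nx)
    ua[inside] <- stats::approx(fl$r, fl$u, xout = abs(Rr[inside]), rule = 2)$y
    vrad <- (Rr / R) * fl$dRdt
    uk <- ua * geom$a[1] + vrad * geom$n[1]
    vk <- ua * geom$a[2] + vrad * geom$n[2]
    uk[!inside] <- NA; vk[!inside] <- NA
    u[, , k] <- uk; v[, , k] <- vk; lumen[, , k] <- inside
    wss[k] <- fl$wall_shear_rate * config$blood_viscosity
    v_mean[k] <- mean(sqrt(uk[inside]^2 + vk[inside]^2))
    # true inner wall: r = -R (upper) and +R (lower), sampled per column
    mk_wall <- function(rsign, side) {
      sline <- (xs - geom$centre[1] - rsign * R * geom$n[1]) / geom$a[1]
      yline <- geom$centre[2] + sline * geom$a[2] + rsign * R * geom$n[2]
      ok <- yline >= 0 & yline <= (ny - 1) * sp[1]
      data.frame(x_m = xs[ok], y_m = yline[ok],
                 x_px = xs[ok] / sp[2], y_px = yline[ok] / sp[1],
                 theta = geom$phi, side = side, vessel = "primary",
                 flagged = FALSE, stringsAsFactors = FALSE)
    }
    wall_frames[[k]] <- rbind(mk_wall(-1, "upper"), mk_wall(1, "lower"))
  }
  structure(list(u = u, v = v, speed = sqrt(u^2 + v^2), lumen = lumen,
                 wall = wall_boundary(wall_frames, sp, times),
                 wss = wss, v_mean = v_mean, times = times, R = Rt,
                 geom = geom),
            class = "phantom_truth")
}

#' Generate a phantom image sequence with ground truth
#'
#' Runs the scatterer simulation over the requested frames: scatterers are
#' advected at the PRF (one sub-step per steered transmission), each of the
#' `n_angles` transmissions is rendered as its own low-resolution frame with
#' independent noise, and washed-out lumen scatterers are replenished once
#' per compounded frame. Identical seeds give bit-identical output.
#'
#' @param config a [phantom_config()].
#' @param frames integer indices (1-based) of the compounded frames to emit;
#'   default all frames of one cycle, `ceiling(cycle_period/frame_interval)`.
#' @param envelope logical; emit the envelope `abs(field)` (default) or the
#'   signed linear field.
#' @return list of class `phantom_sequence` with `stacks` (list of
#'   per-angle [image_stack()]s), `compound` (their mean), `truth`
#'   ([phantom_ground_truth()] at the emitted frame times), `times`,
#'   `frames`, `config`.
#' @export
generate_sequence <- function(config, frames = NULL, envelope = TRUE) {
  n_total <- ceiling(config$cycle_period / config$frame_interval)
  if (is.null(frames)) frames <- seq_len(n_total)
  frames <- sort(unique(as.integer(frames)))
  sc <- seed_scatterers(config, t = 0)
  set.seed(substream_seed(config$seed, 2))
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  na <- config$n_angles
  emit <- integer(0)
  stacks_data <- lapply(seq_len(na), function(a)
    array(0, c(ny, nx, length(frames))))
  out_k <- 0L
  dt_sub <- 1 / config$prf
  for (f in seq_len(max(frames))) {
    t_f <- (f - 1) * config$frame_interval
    is_emit <- f %in% frames
    if (is_emit) out_k <- out_k + 1L
    for (a in seq_len(na)) {
      t_sub <- t_f + (a - 1) * dt_sub
      if (is_emit) {
        fr <- render_frame(sc, config)
        stacks_data[[a]][, , out_k] <- if (envelope) abs(fr) else fr
      }
      sc <- advect_scatterers(sc, config, t_sub, dt_sub)
    }
    sc <- replenish_scatterers(sc, config, f * config$frame_interval)
  }
  times <- (frames - 1) * config$frame_interval
  stacks <- lapply(seq_len(na), function(a)
    image_stack(stacks_data[[a]], config$pixel_spacing, config$frame_interval,
                t0 = (a - 1) * dt_sub, angle = a))
  comp <- Reduce(`+`, stacks_data) / na
  structure(list(stacks = stacks,
                 compound = image_stack(comp, config$pixel_spacing,
                                        config$frame_interval),
                 truth = phantom_ground_truth(config, times),
                 times = times, frames = frames, config = config),
            class = "phantom_sequence")
}
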