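## Vessel-wall tracking: SVD-based image augmentation, narrow-band
## (sparse-field) level-set segmentation of the lumen, directional peak
## fitting of the specular wall reflection, boundary classification and
## Savitzky-Golay smoothing, plus the segmentation scores (Dice
## coefficient, mean absolute distance between walls) and a 1-D
## cross-correlation diameter waveform.

#' Augment an image stack for wall segmentation
#'
#' Decomposes the acquisition into tissue-only and blood-only stacks with
#' the SVD clutter filter, applies a moving-window temporal average to
#' each, normalises each by its maximum and subtracts blood from tissue:
#' the wall becomes strongly positive and the flowing lumen strongly
#' negative, with output in [-1, 1].
#'
#' @param stack an [image_stack()].
#' @param band optional `rank_band` for the blood subspace (auto-selected
#'   otherwise).
#' @param window moving-average window length in frames (default 10).
#' @param ... passed to [select_blood_band()].
#' @return The augmented [image_stack()].
#' @export
augment_images <- function(stack, band = NULL, window = 10L, ...) {
  if (all(stack$data == 0)) stop("all-zero stack cannot be augmented")
  if (dim(stack$data)[3] < 2L) stop("augmentation needs at least 2 frames")
  fs <- svd_filter(stack, band = band, ...)
  tis <- movavg_time(abs(fs$tissue$data), window)
  blo <- movavg_time(abs(fs$blood$data), window)
  mt <- max(tis); mb <- max(blo)
  tis <- tis / mt
  # a numerically empty blood subspace (static acquisition) must not be
  # blown up by its own maximum: keep it on the tissue scale instead
  blo <- if (mb > 0.05 * mt) blo / mb else blo / mt
  image_stack(tis - blo, stack$pixel_spacing, stack$frame_interval, t0 = stack$t0)
}

## signed distance: negative inside the mask
signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- EBImage::distmap(1 - m) - EBImage::distmap(m)
  matrix(out, nrow(mask), ncol(mask))
}

## curvature of the level-set function at all pixels (central differences)
phi_curvature <- function(phi) {
  ny <- nrow(phi); nx <- ncol(phi)
  pad <- function(m) m[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  p <- pad(phi)
  ci <- 2:(ny + 1); cj <- 2:(nx + 1)
  px <- (p[ci, cj + 1] - p[ci, cj - 1]) / 2
  py <- (p[ci + 1, cj] - p[ci - 1, cj]) / 2
  pxx <- p[ci, cj + 1] - 2 * p[ci, cj] + p[ci, cj - 1]
  pyy <- p[ci + 1, cj] - 2 * p[ci, cj] + p[ci - 1, cj]
  pxy <- (p[ci + 1, cj + 1] - p[ci + 1, cj - 1] - p[ci - 1, cj + 1] + p[ci - 1, cj - 1]) / 4
  den <- (px^2 + py^2)^1.5 + 1e-8
  k <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / den
  pmin(pmax(k, -1), 1)
}

#' Narrow-band (sparse-field) level-set segmentation
#'
#' Evolves an active contour from `init_mask` under a two-region
#' mean-separation speed with curvature regularisation, updating the
#' signed-distance function only inside a narrow band around the zero
#' level set and reinitialising it periodically from the current mask.
#' Convergence is declared when fewer than `tol` of the band pixels change
#' sign in an iteration; non-convergence returns the last iterate with a
#' warning flag.
#'
#' @param image numeric matrix (e.g. one frame of an augmented stack); the
#'   region to segment (lumen) should be darker than its surroundings.
#' @param init_mask nonempty logical matrix initialising the contour.
#' @param lambda curvature weight.
#' @param band band half-width in px.
#' @param max_iter iteration budget.
#' @param tol convergence fraction of sign changes per band pixel.
#' @param dt time step.
#' @param reinit_every iterations between distance reinitialisations.
#' @return logical mask; attribute `converged` reports convergence.
#' @export
sparse_field_levelset <- function(image, init_mask, lambda = 0.3, band = 3,
                                  max_iter = 200L, tol = 0.02, dt = 0.6,
                                  reinit_every = 10L) {
  if (!any(init_mask)) stop("empty initial mask")
  stopifnot(identical(dim(image), dim(init_mask)))
  phi <- signed_distance(init_mask)
  converged <- FALSE
  prev_mask <- init_mask
  for (it in seq_len(max_iter)) {
    inside <- phi < 0
    if (!any(inside) || all(inside)) break
    c_in <- mean(image[inside]); c_out <- mean(image[!inside])
    bnd <- abs(phi) <= band
    G <- (image - c_out)^2 - (image - c_in)^2
    G <- G / (max(abs(G[bnd])) + 1e-12)
    kap <- phi_curvature(phi)
    upd <- dt * (lambda * kap[bnd] - G[bnd])
    phi[bnd] <- phi[bnd] + upd
    # the distance function moves in sub-pixel steps and the front
    # oscillates within a pixel once settled: convergence is judged on the
    # net mask change across whole reinitialisation cycles
    if (it %% reinit_every == 0L) {
      cur <- phi < 0
      phi <- signed_distance(cur)
      if (sum(cur != prev_mask) / max(sum(bnd), 1) < tol) {
        converged <- TRUE
        break
      }
      prev_mask <- cur
    }
  }
  out <- phi < 0
  if (!converged && max_iter > 10L)
    warning("level set did not converge within ", max_iter, " iterations")
  attr(out, "converged") <- converged
  out
}

#' Track the lumen through a sequence
#'
#' Runs the level set on every frame, each frame initialised from the
#' previous frame's converged mask; the first frame gets the full
#' iteration budget, subsequent frames a smaller one.
#'
#' @param stack an [image_stack()] (typically augmented).
#' @param init_mask logical mask for the first frame.
#' @param iter_first,iter_rest iteration budgets.
#' @param ... passed to [sparse_field_levelset()].
#' @return list of logical masks, one per frame.
#' @export
track_sequence <- function(stack, init_mask, iter_first = 200L, iter_rest = 40L, ...) {
  T_len <- dim(stack$data)[3]
  masks <- vector("list", T_len)
  cur <- init_mask
  for (k in seq_len(T_len)) {
    cur <- suppressWarnings(sparse_field_levelset(
      stack$data[, , k], cur,
      max_iter = if (k == 1L) iter_first else iter_rest, ...))
    masks[[k]] <- cur
  }
  masks
}

#' Classify lumen boundaries into labelled wall chains
#'
#' Labels connected lumen components (largest = primary vessel, others
#' secondary) and extracts, per component and per lateral column, the
#' topmost (upper / anterior) and bottommost (lower / posterior) lumen
#' pixels as ordered boundary chains. Labels are invariant under image
#' intensity rescaling since only the mask is used.
#'
#' @param mask logical lumen mask.
#' @param pixel_spacing `c(axial, lateral)` m/px.
#' @param min_area components smaller than this (px) are dropped.
#' @return data.frame with columns `x_px`, `y_px` (0-based), `x_m`, `y_m`,
#'   `theta` (local tangent angle, rad), `side`, `vessel`, `flagged`.
#' @export
classify_boundaries <- function(mask, pixel_spacing = c(1, 1), min_area = 20L) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) stop("no lumen component of sufficient size")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  out <- NULL
  for (vi in seq_along(keep)) {
    comp <- lab == keep[vi]
    vessel <- if (vi == 1L) "primary" else "secondary"
    cols <- which(colSums(comp) > 0)
    ymin <- apply(comp[, cols, drop = FALSE], 2, function(cc) which(cc)[1]) - 1
    ymax <- apply(comp[, cols, drop = FALSE], 2, function(cc) max(which(cc))) - 1
    mk <- function(ypx, side) data.frame(
      x_px = cols - 1, y_px = ypx,
      x_m = (cols - 1) * pixel_spacing[2], y_m = ypx * pixel_spacing[1],
      theta = NA_real_, side = side, vessel = vessel, flagged = FALSE,
      stringsAsFactors = FALSE)
    out <- rbind(out, mk(ymin, "upper"), mk(ymax, "lower"))
  }
  chain_theta(out)
}

## local tangent angle per chain from centred differences in physical units
chain_theta <- function(bd) {
  for (key in unique(paste(bd$vessel, bd$side))) {
    idx <- which(paste(bd$vessel, bd$side) == key)
    if (length(idx) < 2) { bd$theta[idx] <- 0; next }
    x <- bd$x_m[idx]; y <- bd$y_m[idx]
    n <- length(idx)
    dx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
    dy <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1])
    bd$theta[idx] <- atan2(dy, dx)
  }
  bd
}

#' Refine wall positions by directional peak fitting
#'
#' For every boundary point of the classified mask contour, samples the
#' image intensity along the outward wall normal, finds the first local
#' maximum of the specular wall reflection exceeding a prominence
#' threshold, and places the wall at the point where the profile first
#' crosses half that peak height on the lumen side (sub-pixel, by linear
#' interpolation). Points with no qualifying peak keep the mask contour
#' location and are flagged.
#'
#' @param image numeric matrix the walls are visible in.
#' @param mask logical lumen mask (from the level set).
#' @param pixel_spacing `c(axial, lateral)` m/px.
#' @param search_len outward search length in axial-pixel steps.
#' @param back_len inward extension (steps) allowing the half-maximum point
#'   to land inside the initial mask.
#' @param prominence minimum peak height as a fraction of the profile
#'   maximum (scale-invariant, so classification is unchanged under image
#'   rescaling).
#' @return data.frame of refined boundary points (see
#'   [classify_boundaries()]).
#' @export
directional_peak_fit <- function(image, mask, pixel_spacing = c(1, 1),
                                 search_len = 15L, back_len = 14L,
                                 prominence = 0.5) {
  bd <- classify_boundaries(mask, pixel_spacing)
  h <- pixel_spacing[1]                      # sample step: axial pixel size
  n_fall <- 0L
  for (i in seq_len(nrow(bd))) {
    th <- bd$theta[i]
    nrm <- c(-sin(th), cos(th))              # unit normal in physical coords
    if ((bd$side[i] == "upper" && nrm[2] > 0) ||
        (bd$side[i] == "lower" && nrm[2] < 0)) nrm <- -nrm
    ks <- (-back_len):search_len
    px <- (bd$x_m[i] + ks * h * nrm[1]) / pixel_spacing[2]
    py <- (bd$y_m[i] + ks * h * nrm[2]) / pixel_spacing[1]
    ok <- px >= 0 & px <= ncol(image) - 1 & py >= 0 & py <= nrow(image) - 1
    if (sum(ok) < 3) { bd$flagged[i] <- TRUE; n_fall <- n_fall + 1L; next }
    prof <- bilinear(image, px[ok], py[ok])
    ks_ok <- ks[ok]
    K <- length(prof)
    thr <- prominence * max(prof)
    start <- 2L   # search outward from the lumen-side end of the profile
    pk <- NA_integer_
    for (k in start:(K - 1))
      if (prof[k] > prof[k - 1] && prof[k] >= prof[k + 1] && prof[k] >= thr) { pk <- k; break }
    if (is.na(pk) && prof[K] >= thr && prof[K] > prof[K - 1]) pk <- K
    if (is.na(pk)) { bd$flagged[i] <- TRUE; n_fall <- n_fall + 1L; next }
    # half-maximum relative to the foot of the peak's lumen-side flank
    foot <- pk
    while (foot > 1 && prof[foot - 1] < prof[foot]) foot <- foot - 1
    base <- prof[foot]
    half <- base + (prof[pk] - base) / 2
    cross <- NA_real_
    for (k in seq(pk - 1, 1)) {
      if (prof[k] <= half) {
        cross <- ks_ok[k] + (half - prof[k]) / (prof[k + 1] - prof[k]) *
          (ks_ok[k + 1] - ks_ok[k])
        break
      }
      if (k == 1) cross <- ks_ok[1]
    }
    if (pk == 1 || !is.finite(cross)) cross <- 0
    bd$x_m[i] <- bd$x_m[i] + cross * h * nrm[1]
    bd$y_m[i] <- bd$y_m[i] + cross * h * nrm[2]
    bd$x_px[i] <- bd$x_m[i] / pixel_spacing[2]
    bd$y_px[i] <- bd$y_m[i] / pixel_spacing[1]
  }
  if (n_fall == nrow(bd)) warning("directional peak fit: no peak found anywhere")
  chain_theta(bd)
}

#' Savitzky-Golay smoothing of a wall boundary
#'
#' Resamples each labelled chain to uniform arc-length spacing, filters the
#' point coordinates with a Savitzky-Golay filter (which reproduces
#' polynomials up to `order` exactly and handles endpoints by polynomial
#' extension), and recomputes the tangent angle from the smoothed chain.
#' Chains shorter than the window are returned unfiltered and flagged.
#'
#' @param bd boundary data.frame (see [classify_boundaries()]).
#' @param window odd filter window (points).
#' @param order polynomial order, `< window`.
#' @param pixel_spacing `c(axial, lateral)` m/px, used to refresh the px
#'   coordinates.
#' @return The smoothed boundary data.frame.
#' @export
smooth_boundary <- function(bd, window = 11L, order = 2L, pixel_spacing = c(1, 1)) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be < window")
  out <- NULL
  for (key in unique(paste(bd$vessel, bd$side))) {
    ch <- bd[paste(bd$vessel, bd$side) == key, , drop = FALSE]
    n <- nrow(ch)
    if (n < window) {
      ch$flagged <- TRUE
      out <- rbind(out, ch)
      next
    }
    seg <- sqrt(diff(ch$x_m)^2 + diff(ch$y_m)^2)
    s <- c(0, cumsum(seg))
    step <- stats::median(seg)
    ss <- seq(0, s[n], by = step)
    xs <- stats::approx(s, ch$x_m, xout = ss)$y
    ys <- stats::approx(s, ch$y_m, xout = ss)$y
    if (length(ss) >= window) {
      xs <- signal::sgolayfilt(xs, p = order, n = window)
      ys <- signal::sgolayfilt(ys, p = order, n = window)
    }
    m <- length(ss)
    dx <- c(xs[2] - xs[1], (xs[3:m] - xs[1:(m - 2)]) / 2, xs[m] - xs[m - 1])
    dy <- c(ys[2] - ys[1], (ys[3:m] - ys[1:(m - 2)]) / 2, ys[m] - ys[m - 1])
    sm <- data.frame(x_px = xs / pixel_spacing[2], y_px = ys / pixel_spacing[1],
                     x_m = xs, y_m = ys, theta = atan2(dy, dx),
                     side = ch$side[1], vessel = ch$vessel[1], flagged = FALSE,
                     stringsAsFactors = FALSE)
    out <- rbind(out, sm)
  }
  rownames(out) <- NULL
  out
}

#' Rasterise labelled wall boundaries into a lumen mask
#'
#' Fills, per lateral column and vessel component, the pixels between the
#' upper and lower boundary chains: the final segmentation produced by the
#' level set plus directional peak fitting.
#'
#' @param bd boundary data.frame (see [classify_boundaries()]).
#' @param shape `c(ny, nx)` of the target mask.
#' @param pixel_spacing `c(axial, lateral)` m/px.
#' @return logical mask.
#' @export
boundary_mask <- function(bd, shape, pixel_spacing = c(1, 1)) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (ves in unique(bd$vessel)) {
    up <- bd[bd$vessel == ves & bd$side == "upper", ]
    lo <- bd[bd$vessel == ves & bd$side == "lower", ]
    if (!nrow(up) || !nrow(lo)) next
    cols <- intersect(round(up$x_px), round(lo$x_px))
    cols <- cols[cols >= 0 & cols <= shape[2] - 1]
    if (!length(cols)) next
    yu <- stats::approx(up$x_px, up$y_px, xout = cols, rule = 2)$y
    yl <- stats::approx(lo$x_px, lo$y_px, xout = cols, rule = 2)$y
    for (k in seq_along(cols)) {
      r0 <- max(1L, ceiling(yu[k] + 0.5) + 1L)
      r1 <- min(shape[1], floor(yl[k] + 0.5) + 1L)
      if (r1 >= r0) out[r0:r1, cols[k] + 1L] <- TRUE
    }
  }
  out
}

#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1.
#' @param a,b logical masks of identical shape.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Mean absolute distance between wall contours
#'
#' Mean over the ground-truth points of the absolute distance to the
#' closest point of the measured contour (one-sided, the default), or the
#' symmetrised mean of both directions.
#'
#' @param m,gt contours: 2-column matrices or data.frames with `x_m`,
#'   `y_m`, in metres.
#' @param symmetric also average the M -> GT direction.
#' @return distance in metres.
#' @export
madw <- function(m, gt, symmetric = FALSE) {
  as_mat <- function(z) {
    if (is.data.frame(z)) cbind(z$x_m, z$y_m) else as.matrix(z)
  }
  M <- as_mat(m); G <- as_mat(gt)
  if (!nrow(M) || !nrow(G)) stop("empty contour")
  one_sided <- function(from, to) {
    d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
    mean(sqrt(apply(d2, 1, min)))
  }
  if (symmetric) (one_sided(G, M) + one_sided(M, G)) / 2 else one_sided(G, M)
}

## 1-D cross-correlation shift: integer lag by normalised correlation,
## sub-sample refinement by a gradient (optical-flow) step, which is
## unbiased for small shifts of smooth profiles
profile_shift <- function(a, b, max_lag = 6L) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    ia <- max(1, 1 - l):min(n, n - l)
    sum(a[ia] * b[ia + l])
  }, numeric(1))
  k <- which.max(cc)
  d <- lags[k]
  ia <- max(1, 1 - d):min(n, n - d)
  a0 <- a[ia]; b0 <- b[ia + d]
  if (length(a0) > 4) {
    m <- length(a0)
    da <- c(a0[2] - a0[1], (a0[3:m] - a0[1:(m - 2)]) / 2, a0[m] - a0[m - 1])
    den <- sum(da^2)
    if (den > 0) {
      frac <- sum((b0 - a0) * da) / den
      if (abs(frac) < 1) d <- d + frac
    }
  }
  d
}

#' Vessel diameter waveform by 1-D cross-correlation wall tracking
#'
#' At `n_positions` lateral positions, axial intensity profiles around the
#' upper and lower wall are aligned between successive frames by 1-D
#' cross-correlation; the diameter change per frame is the lower-wall
#' shift minus the upper-wall shift (projected perpendicular to the wall),
#' and the waveform is the initial diameter plus the cumulative change
#' averaged over positions.
#'
#' @param stack an [image_stack()].
#' @param boundary0 boundary data.frame of the first frame (e.g. from
#'   [directional_peak_fit()] or the phantom truth) providing the initial
#'   wall positions and diameter.
#' @param n_positions number of tracking positions along the wall.
#' @param search_half axial half-window (px) of the tracked profiles.
#' @param reference align each frame's profiles to the `"previous"` frame
#'   (cumulative shifts) or to the `"first"` frame (drift-free; preferable
#'   when the stack samples the cycle sparsely).
#' @return numeric vector `D(t)` in metres, one value per frame.
#' @export
diameter_waveform <- function(stack, boundary0, n_positions = 10L,
                              search_half = 16L,
                              reference = c("previous", "first")) {
  reference <- match.arg(reference)
  img <- stack$data
  sp <- stack$pixel_spacing
  up <- boundary0[boundary0$side == "upper" & boundary0$vessel == "primary", ]
  lo <- boundary0[boundary0$side == "lower" & boundary0$vessel == "primary", ]
  if (!nrow(up) || !nrow(lo)) stop("boundary0 must contain primary upper and lower chains")
  xr <- range(intersect(round(up$x_px), round(lo$x_px)))
  xs <- round(seq(xr[1] + 0.1 * diff(xr), xr[2] - 0.1 * diff(xr),
                  length.out = n_positions))
  phi <- stats::median(c(up$theta, lo$theta), na.rm = TRUE)
  y_up <- stats::approx(up$x_px, up$y_px, xout = xs, rule = 2)$y
  y_lo <- stats::approx(lo$x_px, lo$y_px, xout = xs, rule = 2)$y
  D0 <- mean(y_lo - y_up) * sp[1] * cos(phi)
  T_len <- dim(img)[3]
  if (T_len < 2L) return(rep(D0, T_len))
  ny <- dim(img)[1]
  dD <- matrix(0, n_positions, T_len)        # cumulative axial separation change
  for (p in seq_len(n_positions)) {
    jx <- xs[p] + 1
    if (jx < 1 || jx > dim(img)[2]) { warning("tracking position outside image"); next }
    win_u <- max(1, round(y_up[p]) - search_half):min(ny, round(y_up[p]) + search_half)
    win_l <- max(1, round(y_lo[p]) - search_half):min(ny, round(y_lo[p]) + search_half)
    cum_u <- 0; cum_l <- 0
    for (t in 2:T_len) {
      if (reference == "previous") {
        su <- profile_shift(img[win_u, jx, t - 1], img[win_u, jx, t])
        sl <- profile_shift(img[win_l, jx, t - 1], img[win_l, jx, t])
        cum_u <- cum_u + su; cum_l <- cum_l + sl
      } else {
        cum_u <- profile_shift(img[win_u, jx, 1], img[win_u, jx, t])
        cum_l <- profile_shift(img[win_l, jx, 1], img[win_l, jx, t])
      }
      dD[p, t] <- cum_l - cum_u
    }
  }
  D0 + colMeans(dD) * sp[1] * cos(phi)
}
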