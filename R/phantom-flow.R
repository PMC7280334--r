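## Analytic pulsatile tube flow: the phantom's ground truth.
##
## Poiseuille mode: quasi-steady parabola u(r) = 2 v_mean(t) (1 - (r/R)^2),
## wall shear rate 4 v_mean(t) / R(t).
## Womersley mode: harmonic decomposition of the mean-velocity waveform,
## Bessel-function profile per harmonic in a tube of (quasi-static) radius
## R(t). A radial component linear in r moves the fluid with the wall.

## Complex-argument Bessel functions of the first kind, power series.
## Accurate to ~1e-10 relative for |z| <= 12, which covers Womersley numbers
## alpha * sqrt(n_harmonics) encountered in arteries at rabbit heart rates.
besselJ0c <- function(z) {
  term <- rep(1 + 0i, length(z)); s <- term
  zz <- -(z * z) / 4
  for (m in 1:60) {
    term <- term * zz / (m * m)
    s <- s + term
    if (all(Mod(term) < 1e-16 * (Mod(s) + 1e-300))) break
  }
  s
}

besselJ1c <- function(z) {
  term <- rep(1 + 0i, length(z)); s <- term
  zz <- -(z * z) / 4
  for (m in 1:60) {
    term <- term * zz / (m * (m + 1))
    s <- s + term
    if (all(Mod(term) < 1e-16 * (Mod(s) + 1e-300))) break
  }
  (z / 2) * s
}

## Fourier coefficients (complex, one-sided) of a periodic waveform given as
## a function of time; k = 0..n_harmonics. Reconstruction:
## f(t) = Re( sum_k c_k exp(i k omega t) ), with c_0 real.
waveform_harmonics <- function(f, period, n_harmonics = 8, n_samples = 512) {
  ts <- (seq_len(n_samples) - 1) / n_samples * period
  vals <- f(ts)
  co <- stats::fft(vals) / n_samples
  k <- 0:n_harmonics
  c_k <- co[k + 1]
  c_k[-1] <- 2 * c_k[-1]     # fold negative frequencies into one-sided form
  c_k[1] <- Re(c_k[1])
  list(coef = c_k, period = period, omega = 2 * pi / period)
}

#' Analytic velocity profile and wall shear rate of the phantom flow
#'
#' Evaluates the ground-truth axial velocity profile over radius and the wall
#' shear rate at time `t`, for either quasi-steady Poiseuille flow or the
#' Womersley solution built from a harmonic decomposition (>= 8 harmonics) of
#' the mean-velocity waveform. The tube radius follows the diameter waveform
#' quasi-statically; a radial velocity component `v_r = (r/R) dR/dt` carries
#' the fluid with the moving wall.
#'
#' @param config a [phantom_config()].
#' @param t time (s) within one cycle.
#' @param r radii (m) at which to evaluate the axial profile; default 64
#'   points spanning the lumen. Signed radii are allowed (profile is even).
#' @return list with `r`, `u` (axial velocity, m/s), `v_r` (radial velocity,
#'   m/s at `r`), `wall_shear_rate` (1/s, positive for forward flow), `R`
#'   (lumen radius, m), `dRdt` (m/s), `v_mean` (m/s).
#' @export
analytic_flow <- function(config, t, r = NULL) {
  R <- config$diameter_waveform(t) / 2
  if (!is.finite(R) || R <= 0) stop("nonpositive lumen radius at t = ", t)
  if (is.null(r)) r <- seq(0, R, length.out = 64)
  dRdt <- radius_rate(config, t)
  v_mean <- config$mean_velocity_waveform(t)
  rr <- pmin(abs(r) / R, 1)
  if (config$flow_model == "poiseuille") {
    u <- 2 * v_mean * (1 - rr^2)
    wsr <- 4 * v_mean / R
  } else {
    h <- config$.harmonics
    if (is.null(h)) stop("womersley mode requires harmonic decomposition (set in phantom_config)")
    u <- rep(0, length(r)); wsr <- 0
    omega <- h$omega
    for (k in seq_along(h$coef) - 1) {
      ck <- h$coef[k + 1]
      if (k == 0) {
        u <- u + Re(ck) * 2 * (1 - rr^2)
        wsr <- wsr + Re(ck) * 4 / R
      } else {
        alpha <- R * sqrt(k * omega * config$blood_density / config$blood_viscosity)
        beta <- complex(real = -1, imaginary = 1) / sqrt(2) * alpha  # i^{3/2} alpha
        j0b <- besselJ0c(beta)
        denom <- 1 - 2 * besselJ1c(beta) / (beta * j0b)
        phase <- exp(1i * k * omega * t)
        prof <- (1 - besselJ0c(beta * rr) / j0b) / denom
        u <- u + Re(ck * prof * phase)
        # du/dr at r = R: d/dr J0(beta r/R) = -(beta/R) J1(beta r/R)
        dprof_wall <- (beta / R) * besselJ1c(beta) / (j0b * denom)
        wsr <- wsr + Re(ck * (-dprof_wall) * phase)  # shear rate = -du/dr
      }
    }
  }
  list(r = r, u = u, v_r = (r / R) * dRdt, wall_shear_rate = wsr,
       R = R, dRdt = dRdt, v_mean = v_mean)
}

## dR/dt by central difference of the diameter waveform.
radius_rate <- function(config, t, h = NULL) {
  if (is.null(h)) h <- config$cycle_period * 1e-4
  (config$diameter_waveform(t + h) - config$diameter_waveform(t - h)) / (4 * h)
}

#' Analytic wall shear stress of the phantom at time t
#'
#' `tau = mu_b * wall shear rate` of the configured flow model, signed by
#' flow direction.
#' @inheritParams analytic_flow
#' @export
analytic_wss <- function(config, t) {
  vapply(t, function(ti) analytic_flow(config, ti, r = 0)$wall_shear_rate,
         numeric(1)) * config$blood_viscosity
}

#' Wall shear stress of steady Poiseuille flow
#'
#' The Hagen-Poiseuille closed form `tau = 8 mu v_mean / D` (equivalently
#' `4 mu v_mean / R`). Given waveforms, the time-averaged magnitude
#' (TAWSS_HP) is returned by [poiseuille_tawss()].
#'
#' @param mu dynamic viscosity (Pa s).
#' @param v_mean spatial-mean axial velocity (m/s), vectorised.
#' @param D lumen diameter (m), vectorised.
#' @return WSS in Pa.
#' @export
poiseuille_wss <- function(mu, v_mean, D) {
  stopifnot(all(D > 0))
  8 * mu * v_mean / D
}

#' @rdname poiseuille_wss
#' @param v_mean_fun,D_fun waveforms as functions of time (s).
#' @param period cycle period (s).
#' @param n time samples used for the average.
#' @export
poiseuille_tawss <- function(mu, v_mean_fun, D_fun, period, n = 512) {
  ts <- seq(0, period, length.out = n)
  mean(abs(poiseuille_wss(mu, v_mean_fun(ts), D_fun(ts))))
}
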