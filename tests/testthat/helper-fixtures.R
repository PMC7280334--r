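## Shared fixtures: synthetic speckle with an anisotropic correlation length
## (Fourier-domain Gaussian filter), exact sub-pixel translation by Fourier
## phase shift, and small phantom configurations.

make_speckle <- function(ny, nx, sigy = 2.5, sigx = 1.6, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(ny * nx), ny, nx)
  ky <- c(0:(ny %/% 2), -((ny - 1) %/% 2):-1) / ny
  kx <- c(0:(nx %/% 2), -((nx - 1) %/% 2):-1) / nx
  H <- exp(-2 * pi^2 * (sigy^2 * outer(ky^2, rep(1, nx)) +
                          sigx^2 * outer(rep(1, ny), kx^2)))
  Re(stats::fft(stats::fft(base) * H, inverse = TRUE)) / (ny * nx)
}

shift_speckle <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  ky <- c(0:(ny %/% 2), -((ny - 1) %/% 2):-1) / ny
  kx <- c(0:(nx %/% 2), -((nx - 1) %/% 2):-1) / nx
  ph <- exp(-2i * pi * (outer(ky * dy, rep(1, nx)) + outer(rep(1, ny), kx * dx)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (ny * nx)
}

## small, fast phantom: coarse grid, steady or default pulsatile flow
tiny_config <- function(seed = 5, steady = TRUE, v_mean = 0.25, ...) {
  args <- list(image_shape = c(96L, 48L),
               pixel_spacing = c(6e-5, 1.5e-4),
               noise_sd = 0.02, seed = seed, ...)
  if (steady) {
    args$flow_model <- "poiseuille"
    args$diameter_waveform <- function(t) rep(2.7e-3, length(t))
    args$mean_velocity_waveform <- function(t) rep(v_mean, length(t))
  }
  do.call(phantom_config, args)
}

## gridded velocity field built from an analytic function of physical (x, y)
field_from_fun <- function(fun, xs, ys, pixel_spacing = c(1, 1), times = 0) {
  gx <- xs * pixel_spacing[2]; gy <- ys * pixel_spacing[1]
  X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  Y <- matrix(gy, length(gy), length(gx))
  uv <- fun(as.vector(X), as.vector(Y))
  d <- c(length(ys), length(xs), 1)
  velocity_field(array(uv$u, d), array(uv$v, d), xs, ys,
                 valid = array(is.finite(uv$u), d), times = times,
                 pixel_spacing = pixel_spacing, pair_interval = 1)
}
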