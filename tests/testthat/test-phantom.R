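test_that("quasi-steady Poiseuille profile and wall shear match closed forms", {
  cfg <- tiny_config(v_mean = 0.1)
  fl <- analytic_flow(cfg, 0.1, r = c(0, 1.35e-3))
  expect_equal(fl$u[1], 0.2, tolerance = 1e-12)          # parabola peak = 2 x mean
  expect_equal(fl$u[2], 0, tolerance = 1e-12)            # no-slip at the wall
  # wall shear rate against a numerical derivative of the same profile
  h <- 1e-8
  u2 <- analytic_flow(cfg, 0.1, r = c(1.35e-3 - h, 1.35e-3))$u
  expect_equal(fl$wall_shear_rate, -(u2[2] - u2[1]) / h, tolerance = 1e-4)
  expect_equal(fl$wall_shear_rate * cfg$blood_viscosity,
               poiseuille_wss(cfg$blood_viscosity, 0.1, 2.7e-3),
               tolerance = 1e-10)
})

test_that("Womersley solution reduces to Poiseuille in the DC limit", {
  mk <- function(model) phantom_config(
    flow_model = model,
    diameter_waveform = function(t) rep(2.7e-3, length(t)),
    mean_velocity_waveform = function(t) rep(0.1, length(t)),
    image_shape = c(96L, 48L), pixel_spacing = c(6e-5, 1.5e-4))
  r <- seq(0, 1.35e-3, length.out = 40)
  dw <- analytic_flow(mk("womersley"), 0.07, r = r)$u -
    analytic_flow(mk("poiseuille"), 0.07, r = r)$u
  expect_lt(max(abs(dw)), 1e-9)
})

test_that("pulsatile Womersley flow conserves the imposed mean and its wall shear", {
  cfg <- tiny_config(steady = FALSE, seed = 2)
  t0 <- 0.12
  r <- seq(0, cfg$diameter_waveform(t0) / 2, length.out = 4001)
  fl <- analytic_flow(cfg, t0, r = r)
  # sectional mean of the profile equals the harmonic reconstruction of the
  # mean-velocity waveform (truncation of the raw waveform is expected)
  h <- cfg$.harmonics
  k <- seq_along(h$coef) - 1
  v_rec <- Re(sum(h$coef * exp(1i * k * h$omega * t0)))
  sec_mean <- 2 / fl$R^2 * sum(fl$u * fl$r) * (fl$r[2] - fl$r[1])
  expect_equal(sec_mean, v_rec, tolerance = 2e-3)
  # analytic wall shear against a one-sided numerical derivative
  eps <- 1e-8
  u2 <- analytic_flow(cfg, t0, r = c(fl$R - eps, fl$R))$u
  expect_equal(fl$wall_shear_rate, -(u2[2] - u2[1]) / eps, tolerance = 1e-3)
})

test_that("degenerate phantom configurations are rejected", {
  expect_error(phantom_config(diameter_waveform = function(t) rep(-1e-3, length(t))),
               "positive")
  expect_error(phantom_config(frame_interval = 1 / 1000), "n_angles / prf")
  expect_error(phantom_config(n_angles = 3, prf = 4500, cycle_period = -1))
})

test_that("advection follows the imposed velocity field", {
  cfg <- tiny_config()
  sc <- seed_scatterers(cfg)
  lum <- sc$compartment == "lumen"
  # zero velocity: nothing moves
  still <- advect_scatterers(sc, cfg, 0, dt = 1 / 1500,
                             velocity = function(s, r, t)
                               list(u_axial = rep(0, length(s)),
                                    v_radial = rep(0, length(s))))
  expect_identical(still$s, sc$s)
  expect_identical(still$r, sc$r)
  # uniform 0.5 m/s axial over one frame interval: 3.333e-4 m shift
  uni <- advect_scatterers(sc, cfg, 0, dt = 1 / 1500,
                           velocity = function(s, r, t)
                             list(u_axial = rep(0.5, length(s)),
                                  v_radial = rep(0, length(s))))
  expect_equal(uni$s[lum] - sc$s[lum], rep(0.5 / 1500, sum(lum)), tolerance = 1e-12)
  # parabolic analytic flow: a centreline scatterer moves twice the mean
  sc2 <- sc[lum, ][1:2, ]
  sc2$r <- c(0, 1e-6)
  dt <- 1 / cfg$prf
  adv <- advect_scatterers(sc2, cfg, 0, dt = dt)
  expect_equal(adv$s[1] - sc2$s[1], 2 * 0.25 * dt, tolerance = 1e-3)
})

test_that("a lumen scatterer crossing the wall raises an error", {
  cfg <- tiny_config()
  sc <- seed_scatterers(cfg)
  expect_error(
    advect_scatterers(sc, cfg, 0, dt = 1 / 1500,
                      velocity = function(s, r, t)
                        list(u_axial = rep(0, length(s)),
                             v_radial = rep(1.0, length(s)))),
    "crossed the wall")
})

test_that("replenishment restores washed-out lumen scatterers and never drains", {
  cfg <- tiny_config()
  sc <- seed_scatterers(cfg)
  n0 <- sum(sc$compartment == "lumen")
  # lumen scatterers whose rendered position falls inside the image (the
  # seeded segment extends beyond the image and only the image is refilled)
  geom <- echowss:::phantom_geometry(cfg)
  pos <- echowss:::vessel_to_image(geom, sc$s, sc$r)
  inimg <- sc$compartment == "lumen" &
    pos$x >= 0 & pos$x <= geom$extent["x"] & pos$y >= 0 & pos$y <= geom$extent["y"]
  # wash everything far downstream, then replenish
  sc2 <- sc
  lum <- sc2$compartment == "lumen"
  sc2$s[lum] <- sc2$s[lum] + 0.05
  set.seed(99)
  sc3 <- replenish_scatterers(sc2, cfg, 0)
  expect_gt(sum(sc3$compartment == "lumen"), 0.85 * sum(inimg))
  # steady run: census stays within 10% of the initial count
  set.seed(42)
  sc4 <- sc
  for (f in 1:20) {
    for (a in 1:3) sc4 <- advect_scatterers(sc4, cfg, (f - 1) / 1500 + (a - 1) / 4500,
                                            1 / 4500)
    sc4 <- replenish_scatterers(sc4, cfg, f / 1500)
  }
  expect_lt(abs(sum(sc4$compartment == "lumen") - n0) / n0, 0.10)
})

test_that("rendering is additive, localised and clipped silently", {
  cfg <- tiny_config()
  empty <- seed_scatterers(cfg)[0, ]
  expect_true(all(render_frame(empty, cfg, noise_sd = 0) == 0))
  # a single unit scatterer at the image centre peaks at the centre pixel
  one <- data.frame(s = 0, r = 0, amp = 1, compartment = "lumen")
  img <- render_frame(one, cfg, noise_sd = 0)
  pk <- which(img == max(img), arr.ind = TRUE)
  # the geometric centre falls between pixels; the peak must be adjacent to it
  expect_true(pk[1, 1] %in% 48:49 && pk[1, 2] %in% 24:25)
  # linearity over disjoint sets at zero noise
  sc <- seed_scatterers(cfg)
  a <- sc[sc$compartment == "lumen", ][1:50, ]
  b <- sc[sc$compartment == "tissue", ][1:50, ]
  expect_equal(render_frame(rbind(a, b), cfg, noise_sd = 0),
               render_frame(a, cfg, noise_sd = 0) + render_frame(b, cfg, noise_sd = 0),
               tolerance = 1e-12)
  # a scatterer far outside the image is clipped without error
  far <- data.frame(s = 1, r = 1, amp = 1, compartment = "lumen")
  expect_true(all(render_frame(far, cfg, noise_sd = 0) == 0))
})

test_that("a one-pixel lateral shift of the scatterers moves the correlation peak one lag", {
  cfg <- tiny_config()
  sc <- seed_scatterers(cfg)
  sc <- sc[sc$compartment == "lumen", ]
  A <- render_frame(sc, cfg, noise_sd = 0)
  sc2 <- sc
  # shift all scatterers by exactly one lateral pixel in image coordinates
  phi <- cfg$beam_to_flow_angle * pi / 180
  dximg <- cfg$pixel_spacing[2]
  sc2$s <- sc2$s + dximg * cos(phi)
  sc2$r <- sc2$r - dximg * sin(phi)
  B <- render_frame(sc2, cfg, noise_sd = 0)
  g <- echowss:::piv_grid(dim(A), 32L, 32L)
  mid <- g[g$cy > 30 & g$cy < 70, , drop = FALSE]
  cp <- correlate_windows(A, B, mid, 32L)
  k <- which(cp$valid)[1]
  pk <- subpixel_peak(cp$planes[, , k])
  expect_equal(pk$lag[1], 1, tolerance = 0.05)
  expect_equal(pk$lag[2], 0, tolerance = 0.05)
})

test_that("identical seeds give bit-identical sequences", {
  cfg <- tiny_config(seed = 11)
  s1 <- generate_sequence(cfg, frames = 1:2)
  s2 <- generate_sequence(cfg, frames = 1:2)
  expect_identical(s1$stacks[[1]]$data, s2$stacks[[1]]$data)
  expect_identical(s1$compound$data, s2$compound$data)
})

test_that("ground truth respects no-slip and mass conservation", {
  cfg <- tiny_config()  # static wall, steady flow
  geom <- echowss:::phantom_geometry(cfg)
  R <- 1.35e-3
  # velocity sampled just inside the wall tends to zero
  s_line <- seq(-2e-3, 2e-3, length.out = 21)
  pw <- echowss:::vessel_to_image(geom, s_line, rep(R * (1 - 1e-6), 21))
  tr <- truth_velocity_at(cfg, 0.1, pw$x, pw$y)
  expect_lt(max(sqrt(tr$u^2 + tr$v^2), na.rm = TRUE), 1e-5)
  # flux across two cross-sections agrees within 0.1%
  flux_at <- function(s0) {
    rr <- seq(-R, R, length.out = 2001)
    p <- echowss:::vessel_to_image(geom, rep(s0, length(rr)), rr)
    tv <- truth_velocity_at(cfg, 0.1, p$x, p$y)
    ua <- tv$u * geom$a[1] + tv$v * geom$a[2]
    sum(ua[tv$inside]) * (rr[2] - rr[1])
  }
  f1 <- flux_at(-1e-3); f2 <- flux_at(1e-3)
  expect_lt(abs(f1 - f2) / abs(f1), 1e-3)
})
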