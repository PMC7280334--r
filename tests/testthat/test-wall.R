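## a clean disk image: dark lumen (-1) in bright surroundings (+1)
disk_image <- function(n = 80, r = 18, noise = 0, seed = 1) {
  set.seed(seed)
  cy <- (n - 1) / 2; cx <- (n - 1) / 2
  d <- sqrt(outer((0:(n - 1) - cy)^2, (0:(n - 1) - cx)^2, "+"))
  img <- ifelse(d < r, -1, 1)
  if (noise > 0) img <- img + matrix(rnorm(n * n, 0, noise), n, n)
  list(img = img, truth = d < r)
}

disk_mask <- function(n, r) {
  cy <- (n - 1) / 2
  sqrt(outer((0:(n - 1) - cy)^2, (0:(n - 1) - cy)^2, "+")) < r
}

test_that("image augmentation separates wall and lumen signatures", {
  # static wall only: augmented image is essentially the normalised tissue image
  wallimg <- abs(make_speckle(32, 32, seed = 3)) + 0.2
  st <- array(rep(wallimg, 4), c(32, 32, 4)) +
    array(rnorm(32 * 32 * 4, 0, 1e-3), c(32, 32, 4))
  aug <- augment_images(image_stack(st, c(1, 1), 1))
  expect_gt(cor(as.vector(aug$data[, , 2]), as.vector(wallimg)), 0.99)
  expect_true(all(aug$data <= 1 + 1e-12 & aug$data >= -1 - 1e-12))
  # window length 1 equals the single-frame arithmetic (stack with real flow)
  dyn <- array(rep(wallimg, 4), c(32, 32, 4))
  for (k in 1:4) dyn[(6 + 4 * k):(8 + 4 * k), 12:15, k] <-
    dyn[(6 + 4 * k):(8 + 4 * k), 12:15, k] + 2
  fs <- svd_filter(image_stack(dyn, c(1, 1), 1))
  aug1 <- augment_images(image_stack(dyn, c(1, 1), 1), band = fs$band,
                         decomp = fs$decomp, window = 1L)
  byhand <- abs(fs$tissue$data) / max(abs(fs$tissue$data)) -
    abs(fs$blood$data) / max(abs(fs$blood$data))
  expect_equal(aug1$data, byhand, tolerance = 1e-12)
  expect_error(augment_images(image_stack(array(0, c(8, 8, 4)), c(1, 1), 1)),
               "all-zero")
})

test_that("the narrow-band level set finds a high-contrast disk", {
  di <- disk_image(noise = 0.05)
  # exact initialisation is a stationary point
  m1 <- suppressWarnings(sparse_field_levelset(di$img, di$truth, max_iter = 60))
  expect_gte(dice(m1, di$truth), 0.99)
  # a 20% smaller disk grows out to the boundary
  m2 <- suppressWarnings(sparse_field_levelset(di$img, disk_mask(80, 14),
                                               max_iter = 150))
  expect_gte(dice(m2, di$truth), 0.98)
  expect_error(sparse_field_levelset(di$img, matrix(FALSE, 80, 80)), "empty")
})

test_that("with zero contrast the contour moves by curvature only and shrinks", {
  flat <- matrix(0.5, 80, 80)
  init <- disk_mask(80, 20)
  m <- suppressWarnings(sparse_field_levelset(flat, init, max_iter = 25,
                                              tol = 0, reinit_every = 5))
  expect_lte(sum(m), sum(init))
  expect_gt(sum(m), 0)
})

test_that("level-set updates only touch the narrow band", {
  di <- disk_image(noise = 0)
  init <- disk_mask(80, 14)
  m <- suppressWarnings(sparse_field_levelset(di$img, init, band = 3,
                                              max_iter = 3, tol = 0,
                                              reinit_every = 100))
  changed <- m != init
  dist_to_front <- abs(echowss:::signed_distance(init))
  expect_true(all(dist_to_front[changed] <= 3 + 1.5))
})

test_that("tracking a static sequence reproduces the first mask", {
  di <- disk_image(noise = 0.02)
  st <- image_stack(array(rep(di$img, 3), c(80, 80, 3)), c(1, 1), 1)
  masks <- track_sequence(st, disk_mask(80, 16), iter_first = 120, iter_rest = 40)
  expect_gte(dice(masks[[2]], masks[[1]]), 0.99)
  expect_gte(dice(masks[[3]], di$truth), 0.98)
})

test_that("boundary classification labels sides and vessels", {
  # horizontal tube
  tube <- matrix(FALSE, 40, 60); tube[15:25, ] <- TRUE
  bd <- classify_boundaries(tube)
  expect_setequal(unique(bd$side), c("upper", "lower"))
  up <- bd[bd$side == "upper", ]; lo <- bd[bd$side == "lower", ]
  expect_true(all(up$y_px < lo$y_px))
  expect_true(all(bd$vessel == "primary"))
  # circular lumen: equal point counts (one per column per side)
  circ <- disk_mask(60, 20)
  bdc <- classify_boundaries(circ)
  expect_lte(abs(sum(bdc$side == "upper") - sum(bdc$side == "lower")), 1)
  # tube plus a separate small branch: primary and secondary
  two <- tube; two[32:36, 10:30] <- TRUE
  bd2 <- classify_boundaries(two)
  expect_setequal(unique(bd2$vessel), c("primary", "secondary"))
  expect_gt(sum(bd2$vessel == "primary"), sum(bd2$vessel == "secondary"))
})

test_that("directional peak fitting implements the half-maximum rule", {
  # profile 0,0,0.5,1,0.5,0 along the outward normal of the upper wall:
  # the wall point lands at the 0.5-crossing, two steps out
  ny <- 24; nx <- 16
  prof_vals <- c(0.5, 1, 0.5)             # at rows y = 3, 2, 1 going outward
  img <- matrix(0, ny, nx)
  img[4, ] <- 0.5; img[3, ] <- 1; img[2, ] <- 0.5   # rows 1-based: y_px 3,2,1
  mask <- matrix(FALSE, ny, nx); mask[7:18, ] <- TRUE  # upper wall at y_px 6
  bd <- directional_peak_fit(img, mask, search_len = 8L, back_len = 2L)
  up <- bd[bd$side == "upper", ]
  # mask edge y_px = 6; outward profile 0,0,0,0.5,1,0.5,0 peaks at y_px = 2;
  # the half-maximum crossing is the 0.5 sample on the lumen side, y_px = 3
  expect_equal(mean(up$y_px), 3, tolerance = 1e-6)
  # an ideal step edge puts the wall at the step midpoint
  img2 <- matrix(0, ny, nx); img2[1:3, ] <- 1
  bd2 <- directional_peak_fit(img2, mask, search_len = 8L, back_len = 2L)
  up2 <- bd2[bd2$side == "upper", ]
  expect_equal(mean(up2$y_px), 2.5, tolerance = 1e-6)
  # intensity rescaling does not move the boundary
  bd3 <- directional_peak_fit(10 * img, mask, search_len = 8L, back_len = 2L)
  expect_equal(bd3$y_px, bd$y_px, tolerance = 1e-9)
})

test_that("Savitzky-Golay boundary smoothing preserves polynomials and denoises", {
  mkbd <- function(y) data.frame(
    x_px = 0:99, y_px = y, x_m = 0:99, y_m = y,
    theta = 0, side = "upper", vessel = "primary", flagged = FALSE,
    stringsAsFactors = FALSE)
  line <- mkbd(rep(5, 100) + 0.02 * (0:99))
  sm <- smooth_boundary(line, window = 11L, order = 2L)
  ref <- approx(line$x_m, line$y_m, xout = sm$x_m, rule = 2)$y
  expect_lt(max(abs(sm$y_m - ref)), 1e-9)
  # a gentle quadratic arc is reproduced by a second-order filter
  arc <- mkbd(5 + 1e-4 * (0:99)^2)
  sma <- smooth_boundary(arc, window = 11L, order = 2L)
  refa <- 5 + 1e-4 * pmin(pmax(sma$x_m, 0), 99)^2
  expect_lt(max(abs(sma$y_m - refa)), 1e-6)
  # noise on a straight line is reduced by at least half (rms)
  set.seed(21)
  noisy <- mkbd(10 + rnorm(100, 0, 1))
  smn <- smooth_boundary(noisy, window = 21L, order = 2L)
  expect_lt(sqrt(mean((smn$y_m - 10)^2)), 0.5 * sqrt(mean((noisy$y_m - 10)^2)))
  # short chains come back unfiltered but flagged
  short <- mkbd(rep(2, 100))[1:5, ]
  expect_true(all(smooth_boundary(short, window = 11L)$flagged))
})

test_that("Dice coefficient matches hand counts and edge cases", {
  a <- matrix(FALSE, 20, 20); b <- a
  a[1:10, 1:10] <- TRUE            # |A| = 100
  b[6:15, 1:10] <- TRUE            # |B| = 100, overlap 50
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, matrix(FALSE, 20, 20)), 0.0)
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1.0)
  expect_error(dice(a, matrix(FALSE, 5, 5)), "shapes")
})

test_that("MADW measures mean nearest-point distance", {
  m <- cbind(seq(0, 10, by = 0.1), rep(0, 101))
  expect_equal(madw(m, m), 0)
  # a rigid normal offset is recovered to within half the sampling step
  gt <- cbind(seq(0, 10, by = 0.1), rep(0.37, 101))
  expect_equal(madw(m, gt), 0.37, tolerance = 0.05)
  # hand mean: ground-truth points at distances 1 and 3
  m2 <- rbind(c(0, 0), c(10, 0))
  gt2 <- rbind(c(0, 1), c(10, 3))
  expect_equal(madw(m2, gt2), 2)
  expect_equal(madw(gt2, m2, symmetric = TRUE), madw(m2, gt2, symmetric = TRUE))
  expect_error(madw(m2[0, ], gt2), "empty")
})

test_that("boundary_mask rasterises chains back to a lumen mask", {
  tube <- matrix(FALSE, 40, 60); tube[15:25, ] <- TRUE
  bd <- classify_boundaries(tube)
  m <- boundary_mask(bd, c(40, 60))
  expect_gte(dice(m, tube), 0.95)
})

test_that("the diameter waveform is flat for a static vessel", {
  cfg <- tiny_config(seed = 13)
  sq <- generate_sequence(cfg, frames = 1:4)
  bd0 <- sq$truth$wall$frames[[1]]
  D <- diameter_waveform(sq$compound, bd0, n_positions = 6L)
  expect_equal(length(D), 4L)
  expect_lt(max(abs(D - D[1])), 0.5 * cfg$pixel_spacing[1] + 1e-9)
  expect_equal(D[1], 2.7e-3, tolerance = 0.03)
  # single frame: the initial diameter
  D1 <- diameter_waveform(sq$compound[1], bd0)
  expect_equal(D1, D[1], tolerance = 1e-9)
})
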