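test_that("self-correlation peaks at zero lag with unit height", {
  A <- make_speckle(96, 96, seed = 2)
  g <- echowss:::piv_grid(dim(A), 32L, 32L)
  cp <- correlate_windows(A, A, g, 32L)
  for (k in which(cp$valid)[1:3]) {
    pk <- subpixel_peak(cp$planes[, , k])
    expect_equal(pk$lag, c(0, 0), tolerance = 1e-9)
    expect_equal(pk$value, 1, tolerance = 1e-9)
  }
  # a uniform window is flagged invalid, not an error
  U <- matrix(1, 96, 96)
  cpu <- correlate_windows(U, U, g[1, , drop = FALSE], 32L)
  expect_false(cpu$valid[1])
})

test_that("an integer translation is recovered exactly at the peak", {
  big <- make_speckle(160, 160, seed = 3)
  A <- big[1:128, 1:128]
  B <- big[3:130, 4:131]          # content displaced by (-2, -3)
  g <- echowss:::piv_grid(dim(A), 32L, 16L)
  cp <- correlate_windows(A, B, g, 32L)
  lags <- t(vapply(which(cp$valid), function(k)
    subpixel_peak(cp$planes[, , k])$lag, numeric(2)))
  expect_equal(mean(lags[, 1]), -3, tolerance = 0.03)
  expect_equal(mean(lags[, 2]), -2, tolerance = 0.03)
})

test_that("independent noise frames correlate weakly", {
  below <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    A <- matrix(rnorm(48 * 48), 48, 48)
    B <- matrix(rnorm(48 * 48), 48, 48)
    g <- data.frame(tl_y = 9, tl_x = 9, cy = 23.5, cx = 23.5)
    cp <- correlate_windows(A, B, g, 32L)
    if (max(cp$planes[, , 1]) < 0.5) below <- below + 1L
  }
  expect_gte(below, 48L)
})

test_that("ensemble averaging reproduces and stabilises single-pair planes", {
  A <- make_speckle(96, 96, seed = 5)
  B <- shift_speckle(A, 0.5, 0.5)
  g <- echowss:::piv_grid(dim(A), 32L, 32L)
  single <- correlate_windows(A, B, g, 32L)
  ens <- ensemble_correlate(list(list(A = A, B = B), list(A = A, B = B)), g, 32L)
  expect_equal(ens$planes, single$planes, tolerance = 1e-12)
  # noisy renders of the same displacement: the averaged plane's estimate is
  # at least as good as the median single-pair estimate
  set.seed(9)
  pairs <- lapply(1:3, function(i) {
    n1 <- matrix(rnorm(96 * 96, 0, 0.3), 96, 96)
    n2 <- matrix(rnorm(96 * 96, 0, 0.3), 96, 96)
    list(A = A + n1, B = B + n2)
  })
  node <- g[8, , drop = FALSE]
  errs <- vapply(pairs, function(p) {
    pk <- subpixel_peak(correlate_windows(p$A, p$B, node, 32L)$planes[, , 1])
    sqrt(sum((pk$lag - 0.5)^2))
  }, numeric(1))
  pk_e <- subpixel_peak(ensemble_correlate(pairs, node, 32L)$planes[, , 1])
  expect_lte(sqrt(sum((pk_e$lag - 0.5)^2)), median(errs) + 1e-6)
  # equal and opposite shifts average to a symmetric plane
  Bp <- shift_speckle(A, 0, 1); Bm <- shift_speckle(A, 0, -1)
  amb <- ensemble_correlate(list(list(A = A, B = Bp), list(A = A, B = Bm)),
                            node, 32L)$planes[, , 1]
  ctr <- 17
  expect_equal(amb[ctr, ctr + 1], amb[ctr, ctr - 1], tolerance = 0.05)
  expect_error(ensemble_correlate(list(), g, 32L), "empty")
})

test_that("sub-pixel fitting recovers analytic and imposed offsets", {
  xs <- (-16):15
  # separable Gaussian sampled off-centre by 0.3 px in x (columns)
  pl <- exp(-outer(xs^2, rep(1, 32)) / 8) * exp(-outer(rep(1, 32), (xs - 0.3)^2) / 8)
  pk <- subpixel_peak(pl)
  expect_equal(pk$lag[1], 0.3, tolerance = 0.01)
  expect_equal(pk$lag[2], 0, tolerance = 0.01)
  # symmetric plane: zero fractional offset
  pls <- exp(-outer(xs^2, rep(1, 32)) / 8) * exp(-outer(rep(1, 32), xs^2) / 8)
  expect_equal(subpixel_peak(pls)$lag, c(0, 0), tolerance = 1e-9)
  # border peak returns the integer lag flagged
  bp <- matrix(0, 32, 32); bp[1, 5] <- 1
  expect_true(subpixel_peak(bp)$border)
  # speckle pair with an imposed 0.25 px shift
  A <- make_speckle(96, 96, seed = 6)
  B <- shift_speckle(A, 0, 0.25)
  g <- echowss:::piv_grid(dim(A), 32L, 16L)
  cp <- correlate_windows(A, B, g, 32L)
  lags <- vapply(which(cp$valid), function(k)
    subpixel_peak(cp$planes[, , k])$lag[1], numeric(1))
  expect_lt(abs(mean(lags) - 0.25), 0.1)
})

test_that("sub-pixel sweep shows low bias and low peak locking", {
  A <- make_speckle(128, 128, sigy = 2, sigx = 2, seed = 7)
  g <- echowss:::piv_grid(dim(A), 32L, 16L)
  biases <- vapply(seq(0, 1, by = 0.1), function(dx) {
    B <- shift_speckle(A, 0, dx)
    cp <- correlate_windows(A, B, g, 32L)
    lags <- vapply(which(cp$valid), function(k)
      subpixel_peak(cp$planes[, , k])$lag[1], numeric(1))
    mean(lags) - dx
  }, numeric(1))
  expect_lt(abs(mean(biases)), 0.05)
  expect_lt(sqrt(mean(biases^2)), 0.1)
})

test_that("multipass recovers uniform translations and nulls", {
  # speckle fine enough that even the final 8 px windows hold several grains
  A <- make_speckle(128, 128, sigy = 1.5, sigx = 1.5, seed = 8)
  B <- shift_speckle(A, 1.7, 1.3)
  f <- multipass(list(list(A = A, B = B)), piv_config())
  ok <- f$valid[, , 1]
  err <- sqrt((f$u[, , 1][ok] - 1.3)^2 + (f$v[, , 1][ok] - 1.7)^2)
  expect_lt(mean(err), 0.15)
  expect_lt(abs(mean(f$u[, , 1][ok]) - 1.3), 0.05)
  expect_lt(abs(mean(f$v[, , 1][ok]) - 1.7), 0.05)
  # null case
  f0 <- multipass(list(list(A = A, B = A)), piv_config())
  expect_lt(max(abs(c(f0$u[, , 1][f0$valid[, , 1]], f0$v[, , 1][f0$valid[, , 1]]))), 0.02)
  # config violations
  expect_error(piv_config(window = 16, passes = 4), ">= 4 px")
  expect_error(piv_config(overlap = 0.9), "overlap")
})

test_that("refining passes do not increase the uniform-translation error", {
  A <- make_speckle(128, 128, sigy = 3, sigx = 1.6, seed = 10)
  B <- shift_speckle(A, 1.7, 1.3)
  err_for <- function(p) {
    f <- multipass(list(list(A = A, B = B)), piv_config(passes = p))
    ok <- f$valid[, , 1]
    mean(sqrt((f$u[, , 1][ok] - 1.3)^2 + (f$v[, , 1][ok] - 1.7)^2))
  }
  e1 <- err_for(1); e2 <- err_for(2)
  expect_lte(e2, e1 + 1e-3)
})

test_that("translation equivariance holds for integer content shifts", {
  big <- make_speckle(180, 180, seed = 11)
  A <- big[11:138, 11:138]; B <- big[13:140, 14:141]     # shift (-2, -3)
  A2 <- big[16:143, 17:144]; B2 <- big[18:145, 20:147]   # same relative shift
  f1 <- multipass(list(list(A = A, B = B)), piv_config(passes = 2))
  f2 <- multipass(list(list(A = A2, B = B2)), piv_config(passes = 2))
  ok <- f1$valid[, , 1] & f2$valid[, , 1]
  expect_lt(abs(mean(f1$u[, , 1][ok]) - mean(f2$u[, , 1][ok])), 0.05)
  expect_lt(abs(mean(f1$v[, , 1][ok]) - mean(f2$v[, , 1][ok])), 0.05)
})

test_that("the normalised median test rejects spikes but keeps smooth fields", {
  nyg <- 9; nxg <- 9
  u <- matrix(outer(1:nyg, 1:nxg, function(i, j) 0.1 * i + 0.05 * j), nyg, nxg)
  v <- u / 2
  f <- velocity_field(u, v, 0:(nxg - 1), 0:(nyg - 1))
  sm <- validate_vectors(f)
  expect_true(all(sm$valid))
  # a single 10x spike is rejected and replaced by the neighbour median
  us <- u; us[5, 5] <- 10 * max(u)
  fs <- velocity_field(us, v, 0:(nxg - 1), 0:(nyg - 1))
  vs <- validate_vectors(fs)
  expect_false(vs$valid[5, 5, 1])
  nb <- us[4:6, 4:6]; nb <- nb[-5]
  expect_equal(vs$u[5, 5, 1], median(nb), tolerance = 1e-9)
  # heavily corrupted field: 40% of nodes carry large random spikes; more
  # than 40% of vectors end up rejected
  set.seed(33)
  un <- u; vn <- v
  hit <- sample(nyg * nxg, round(0.45 * nyg * nxg))
  un[hit] <- un[hit] + rnorm(length(hit), 0, 20)
  vn[hit] <- vn[hit] + rnorm(length(hit), 0, 20)
  fc <- velocity_field(un, vn, 0:(nxg - 1), 0:(nyg - 1))
  vc <- suppressWarnings(validate_vectors(fc))
  expect_gt(mean(!vc$valid), 0.4)
})

test_that("pixel displacements convert to m/s through spacing and interval", {
  u <- matrix(2, 4, 4); v <- matrix(-1, 4, 4)
  f <- velocity_field(u, v, 0:3, 0:3, pixel_spacing = c(3e-5, 1.2e-4),
                      pair_interval = 1 / 1500, units = "px")
  m <- field_to_mps(f)
  expect_equal(m$u[1, 1, 1], 2 * 1.2e-4 * 1500)
  expect_equal(m$v[1, 1, 1], -1 * 3e-5 * 1500)
  expect_identical(field_to_mps(m), m)
})
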