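test_that("a constant stack has zero bandpass response and no candidates", {
  a <- array(123.4, dim = c(7, 32, 32))
  filt <- bandpass_filter(a, SIG_XY, SIG_Z)
  expect_true(all(abs(filt$data) < 1e-9))
  expect_equal(nrow(detect_candidates(filt)), 0)
})

test_that("the bandpass response peaks at a rendered spot's voxel", {
  center <- data.frame(z = 4, y = 17, x = 21, I = 1000)
  a <- render_spots_array(c(9, 40, 40), center, background = 50)
  filt <- bandpass_filter(a, SIG_XY, SIG_Z)
  w <- which(filt$data == max(filt$data), arr.ind = TRUE)[1, ]
  expect_equal(unname(w), c(4, 17, 21))
})

test_that("well-separated noiseless spots are all detected with no extras", {
  pos <- grid_positions(10, c(9, 64, 64), spacing = 16, margin = 12)
  pos$I <- 800
  # sub-voxel offsets so detection is not grid-aligned by construction
  pos$y <- pos$y + 0.3; pos$x <- pos$x - 0.2
  a <- render_spots_array(c(9, 64, 64), pos, background = 50)
  cand <- detect_candidates(bandpass_filter(a, SIG_XY, SIG_Z))
  expect_equal(nrow(cand), 10)
  for (i in seq_len(10)) {
    d <- sqrt((cand$z - pos$z[i])^2 + (cand$y - pos$y[i])^2 +
                (cand$x - pos$x[i])^2)
    expect_lte(min(d), sqrt(3))  # within one voxel of a true center
  }
})

test_that("two equal distant spots give two equal response maxima", {
  pos <- data.frame(z = c(5, 5), y = c(16, 16), x = c(12, 36), I = 500)
  a <- render_spots_array(c(9, 32, 48), pos, background = 10)
  cand <- detect_candidates(bandpass_filter(a, SIG_XY, SIG_Z))
  expect_equal(nrow(cand), 2)
  expect_equal(cand$response[1], cand$response[2], tolerance = 1e-9)
})

test_that("the Gaussian fit recovers a noiseless spot's parameters", {
  A <- 100; B <- 10
  sxy <- SIG_XY; sz <- SIG_Z
  I <- A * (2 * pi)^1.5 * sxy^2 * sz
  a <- render_spots_array(c(11, 32, 32),
                          data.frame(z = 5.0, y = 15.7, x = 12.3, I = I),
                          background = B)
  fit <- fit_spot(a, list(z = 5, y = 16, x = 12))
  expect_true(fit$pass)
  expect_lt(abs(fit$z0 - 5.0), 0.05)
  expect_lt(abs(fit$y0 - 15.7), 0.05)
  expect_lt(abs(fit$x0 - 12.3), 0.05)
  expect_lt(abs(fit$A - A) / A, 0.01)
  expect_lt(abs(fit$B - B) / B, 0.01)
  # integrated intensity matches the closed-form Gaussian integral
  closed <- fit$A * (2 * pi)^1.5 * fit$sigma_xy^2 * fit$sigma_z
  expect_equal(fit$I_int, closed, tolerance = 1e-12)
  expect_lt(abs(fit$I_int - I) / I, 0.01)
})

test_that("a flat window fails the fit", {
  a <- array(25, dim = c(7, 24, 24))
  fit <- fit_spot(a, list(z = 4, y = 12, x = 12))
  expect_false(fit$pass)
})

test_that("a peak outside the stack is an error", {
  a <- array(0, dim = c(5, 16, 16))
  expect_error(fit_spot(a, list(z = 9, y = 4, x = 4)), "outside")
})

test_that("integrated intensity is invariant to a constant offset", {
  I <- 900
  sp <- data.frame(z = 5, y = 14.4, x = 16.6, I = I)
  a <- render_spots_array(c(9, 28, 32), sp, background = 20)
  f1 <- fit_spot(a, list(z = 5, y = 14, x = 17))
  f2 <- fit_spot(a + 50, list(z = 5, y = 14, x = 17))
  expect_lt(abs(f1$I_int - f2$I_int) / f1$I_int, 1e-6)
  expect_equal(f2$B - f1$B, 50, tolerance = 1e-6)
})

test_that("fitting is equivariant under integer translation", {
  I <- 700
  a1 <- render_spots_array(c(9, 40, 40),
                           data.frame(z = 4.4, y = 15.2, x = 14.8, I = I))
  a2 <- render_spots_array(c(9, 40, 40),
                           data.frame(z = 5.4, y = 21.2, x = 22.8, I = I))
  f1 <- fit_spot(a1, list(z = 4, y = 15, x = 15))
  f2 <- fit_spot(a2, list(z = 5, y = 21, x = 23))
  expect_equal(f2$z0 - f1$z0, 1, tolerance = 1e-4)
  expect_equal(f2$y0 - f1$y0, 6, tolerance = 1e-4)
  expect_equal(f2$x0 - f1$x0, 8, tolerance = 1e-4)
  expect_equal(f1$I_int, f2$I_int, tolerance = 1e-6)
})

test_that("filter_spots matches a brute-force predicate on mixed input", {
  set.seed(4)
  n <- 60
  spots <- data.frame(
    peak_z = 1L, peak_y = 1L, peak_x = 1L,
    z0 = runif(n, 1, 9), y0 = runif(n, 1, 64), x0 = runif(n, 1, 64),
    A = runif(n, -5, 200), B = runif(n, 0, 100),
    sigma_xy = runif(n, 0.1, 5), sigma_z = runif(n, 0.1, 6),
    rss = runif(n), pass = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
  spots$I_int <- pmax(spots$A, 0) * (2 * pi)^1.5 *
    spots$sigma_xy^2 * spots$sigma_z
  b <- quality_bounds(amplitude = c(5, 150), sigma_xy = c(0.4, 3),
                      sigma_z = c(0.4, 4), intensity = c(10, 5000))
  got <- filter_spots(spots, b)
  want <- logical(n)
  for (i in seq_len(n)) {
    s <- spots[i, ]
    want[i] <- s$pass &&
      s$A >= 5 && s$A <= 150 &&
      s$sigma_xy >= 0.4 && s$sigma_xy <= 3 &&
      s$sigma_z >= 0.4 && s$sigma_z <= 4 &&
      s$I_int >= 10 && s$I_int <= 5000
  }
  expect_identical(got, spots[want, , drop = FALSE])
  # trivial cases: empty input, single over-wide spot
  expect_equal(nrow(filter_spots(spots[0, ], b)), 0)
  wide <- spots[1, ]; wide$pass <- TRUE; wide$sigma_xy <- 6
  expect_equal(nrow(filter_spots(wide, b)), 0)
})
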