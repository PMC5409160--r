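# Noise injection and temporal/spatial resampling.

gR <- smallGrid(xlim = c(0, 6), ylim = c(0, 0), zlim = c(20, 21.6),
                spacing = 0.2, prf = 10, duration = 10)
phR <- homogeneousPhantom(materialSpec(E = 3), center = c(3, 0, 20.8),
                          radius = 0.5)
fR <- simulateDisplacements(phR, tableExcitation(1), gR)

test_that("added noise hits the requested volume SNR and is reproducible", {
  fn <- addAWGN(fR, 25, seed = 2)
  noise <- fieldData(fn) - fieldData(fR)
  snr <- 10 * log10(mean(fieldData(fR)^2) / mean(noise^2))
  expect_lt(abs(snr - 25), 0.5)
  expect_identical(fieldData(addAWGN(fR, 25, seed = 2)), fieldData(fn))
  expect_false(identical(fieldData(addAWGN(fR, 25, seed = 3)),
                         fieldData(fn)))
  expect_identical(addAWGN(fR, Inf), fR)
  zero <- displacementField(array(0, dim(fieldData(fR))), gR)
  expect_error(addAWGN(zero, 25), "all-zero")
})

test_that("noise injection leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(addAWGN(fR, 25, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("temporal upsampling preserves original samples and refines 5x", {
  fu <- upsampleTime(fR, 50)
  expect_equal(gridPRF(fieldGrid(fu)), 50)
  d0 <- dim(fieldData(fR)); d1 <- dim(fieldData(fu))
  expect_equal(d1[4], (d0[4] - 1) * 5 + 1)
  keep <- seq(1, d1[4], by = 5)
  expect_equal(fieldData(fu)[, , , keep, drop = FALSE],
               fieldData(fR), tolerance = 1e-9)
  expect_identical(upsampleTime(fR, 10), fR)
  expect_error(upsampleTime(fu, 10), "decimation")
})

test_that("spline upsampling reproduces a smooth sinusoid within 1%", {
  # 0.25 kHz tone sampled at 10 kHz, far below Nyquist
  g1 <- gridSpec(xlim = c(0, 0.4), ylim = c(0, 0), zlim = c(20, 20.2),
                 spacing = 0.2, prf = 10, duration = 10)
  ax <- gridAxes(g1)
  d <- vapply(ax, length, integer(1))
  u <- array(rep(sin(2 * pi * 0.25 * ax$t), each = prod(d[1:3])), d)
  fu <- upsampleTime(displacementField(u, g1), 50)
  tN <- gridAxes(fieldGrid(fu))$t
  inner <- tN > 0.5 & tN < 9.5
  got <- fieldData(fu)[1, 1, 1, ]
  expect_lt(max(abs(got[inner] - sin(2 * pi * 0.25 * tN[inner]))), 0.01)
})

test_that("the vectorized spline matches the reference natural spline", {
  t0 <- seq(0, 10, by = 0.5)
  tN <- seq(0, 10, by = 0.1)
  y <- cbind(sin(t0), exp(-((t0 - 4)^2) / 3), t0^2 / 50)
  got <- swei4d:::.splineColumns(y, t0, tN)
  for (j in 1:3) {
    ref <- stats::spline(t0, y[, j], xout = tN, method = "natural")$y
    expect_equal(got[, j], ref, tolerance = 1e-10)
  }
})

test_that("spatial decimation subsamples and preserves constants", {
  g2 <- gridSpec(xlim = c(0, 6), ylim = c(-1.2, 1.2), zlim = c(20, 22.4),
                 spacing = 0.1, prf = 10, duration = 2)
  d <- gridDims(g2)
  fc <- displacementField(array(1.5, d), g2)
  fd <- decimateSpatial(fc, 0.3)
  expect_true(all(fieldData(fd) == 1.5))
  expect_equal(gridSpacing(fieldGrid(fd)), rep(0.3, 3))
  expect_equal(unname(dim(fieldData(fd))[1:3]), c(21L, 9L, 9L))
  expect_identical(decimateSpatial(fc, 0.1), fc)
  expect_error(decimateSpatial(fd, 0.2), "newSpacing")
})
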