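# Time-of-flight estimation: lag estimation, patch velocities, fusion,
# combination, median filtering, full reconstruction.

test_that("cross-correlation recovers integer and zero lags", {
  t <- seq(0, 12, by = 0.1)
  a <- exp(-(t - 4)^2 / 0.5) * cos(4 * (t - 4))   # zero-mean pulse
  b <- c(rep(0, 3), a[1:(length(a) - 3)])         # delayed by 3 samples
  r <- xcorrLag(a, b, prf = 10)
  expect_equal(r$dt, 3 / 10, tolerance = 1e-3)
  expect_gt(r$cc, 0.999)
  r0 <- xcorrLag(a, a, prf = 10)
  expect_equal(r0$dt, 0)
  expect_equal(r0$cc, 1)
  expect_error(xcorrLag(rep(1, 10), a[1:10], 10), "constant")
})

test_that("parabolic refinement resolves subsample shifts within 0.1 sample", {
  dense <- seq(0, 12, by = 0.001)
  pulse <- function(tt) exp(-(tt - 5)^2 / 0.8) * cos(2 * (tt - 5))
  coarse <- seq(0, 12, by = 0.1)
  a <- pulse(coarse)
  b <- pulse(coarse - 0.1 * 0.3)               # 0.3 samples via dense shift
  r <- xcorrLag(a, b, prf = 10)
  expect_lt(abs(r$dt * 10 - 0.3), 0.1)
})

test_that("boundary correlation peaks are flagged invalid", {
  t <- seq_len(40)
  a <- exp(-(t - 1)^2)                         # pulses at opposite ends:
  b <- exp(-(t - 40)^2)                        # peak at the maximal lag
  r <- xcorrLag(a, b, prf = 10)
  expect_false(r$valid)
})

test_that("patch velocities recover a plane pulse's speed and sign", {
  tt <- seq(0, 10, by = 0.02)                  # 50 kHz
  slab <- planePulseSlab(51, 8, tt, speed = 2, spacing = 0.1)
  pv <- patchVelocity(slab, 1, p = 6, dx = 0.1, prf = 50)
  mid <- pv$V[20:30, 4]
  expect_true(all(pv$valid[20:30, 4]))
  expect_equal(mid, rep(2, length(mid)), tolerance = 0.02)
  # reversed pulse gives the negative speed
  rev <- slab[, , rev(seq_along(tt))]
  pvr <- patchVelocity(rev, 1, p = 6, dx = 0.1, prf = 50)
  expect_equal(pvr$V[20:30, 4], rep(-2, 11), tolerance = 0.02)
  # no propagation across the second axis: invalid (near-zero lag)
  pvz <- patchVelocity(slab, 2, p = 6, dx = 0.1, prf = 50)
  expect_false(any(pvz$valid[20:30, 4]))
})

test_that("fusion is a correlation/distance-weighted mean (2-D oracle)", {
  set.seed(11)
  V <- matrix(rnorm(9, 2, 0.3), 3, 3)
  CC <- matrix(runif(9, 0.3, 1), 3, 3)
  valid <- matrix(TRUE, 3, 3); valid[1, 3] <- FALSE
  got <- fuseComponents2D(list(V = V, CC = CC, valid = valid), p = 2, w = 4)
  num <- 0; den <- 0
  for (i in 1:3) for (j in 1:3) {
    if (!valid[i, j]) next
    r <- sqrt((i - 2)^2 + (j - 2)^2); if (r == 0) r <- 1
    wgt <- CC[i, j]^2 / r
    num <- num + wgt * V[i, j]; den <- den + wgt
  }
  expect_equal(got$V[2, 2], num / den, tolerance = 1e-12)
})

test_that("fusion preserves uniform maps and degenerate neighbourhoods", {
  V <- matrix(1.7, 5, 5); CC <- matrix(0.8, 5, 5)
  valid <- matrix(TRUE, 5, 5)
  got <- fuseComponents2D(list(V = V, CC = CC, valid = valid), p = 2, w = 4)
  expect_equal(got$V[2:4, 2:4], matrix(1.7, 3, 3))
  # single valid estimate at the centre
  valid2 <- matrix(FALSE, 5, 5); valid2[3, 3] <- TRUE
  V2 <- matrix(0, 5, 5); V2[3, 3] <- 2.5
  got2 <- fuseComponents2D(list(V = V2, CC = CC, valid = valid2), p = 2, w = 4)
  expect_equal(got2$V[3, 3], 2.5)
})

test_that("3-D fusion matches the brute-force triple sum on a 5^3 block", {
  set.seed(12)
  V <- array(rnorm(125, 2, 0.5), c(5, 5, 5))
  CC <- array(runif(125, 0.2, 1), c(5, 5, 5))
  valid <- array(runif(125) > 0.1, c(5, 5, 5))
  valid[3, 3, 3] <- TRUE
  got <- fuseComponents3D(list(V = V, CC = CC, valid = valid), p = 2, w = 6)
  num <- 0; den <- 0
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    if (!valid[i, j, k]) next
    r <- sqrt((i - 3)^2 + (j - 3)^2 + (k - 3)^2); if (r == 0) r <- 1
    wgt <- CC[i, j, k]^2 / r
    num <- num + wgt * V[i, j, k]; den <- den + wgt
  }
  expect_equal(got$V[3, 3, 3], num / den, tolerance = 1e-12)
})

test_that("fused estimates stay within the valid neighbourhood range", {
  set.seed(13)
  for (rep in 1:5) {
    V <- matrix(rnorm(49, 2, 1), 7, 7)
    CC <- matrix(runif(49, 0.1, 1), 7, 7)
    valid <- matrix(runif(49) > 0.2, 7, 7)
    got <- fuseComponents2D(list(V = V, CC = CC, valid = valid), p = 2, w = 4)
    for (i in 3:5) for (j in 3:5) {
      if (!got$valid[i, j]) next
      nb <- V[(i - 1):(i + 1), (j - 1):(j + 1)]
      ok <- valid[(i - 1):(i + 1), (j - 1):(j + 1)]
      expect_gte(got$V[i, j], min(nb[ok]) - 1e-12)
      expect_lte(got$V[i, j], max(nb[ok]) + 1e-12)
    }
  }
})

test_that("component combination follows the reciprocal-quadrature algebra", {
  mk <- function(v) list(V = matrix(v, 1, 1), valid = matrix(TRUE, 1, 1))
  bad <- list(V = matrix(NA_real_, 1, 1), valid = matrix(FALSE, 1, 1))
  c0 <- sqrt(2) * 1.3
  expect_equal(combine2D(mk(c0), mk(c0))$V[1, 1], 1.3)
  expect_equal(combine2D(mk(2), mk(2))$V[1, 1], sqrt(2))
  # invalid component falls back to the other (unbounded limit)
  expect_equal(combine2D(mk(2), bad)$V[1, 1], 2)
  expect_false(combine2D(bad, bad)$valid[1, 1])
  # 3-D: equal components of sqrt(3) c give c; all-equal 2 -> 2/sqrt(3)
  expect_equal(combine3D(mk(sqrt(3) * 1.1), mk(sqrt(3) * 1.1),
                         mk(sqrt(3) * 1.1))$V[1, 1], 1.1)
  expect_equal(combine3D(mk(2), mk(2), mk(2))$V[1, 1], 2 / sqrt(3))
  # dropping one 3-D component reduces to the 2-D formula
  expect_equal(combine3D(mk(2), bad, mk(3))$V[1, 1],
               2 * 3 / sqrt(2^2 + 3^2))
  # label permutation symmetry
  expect_equal(combine3D(mk(1.5), mk(2.5), mk(4))$V[1, 1],
               combine3D(mk(4), mk(1.5), mk(2.5))$V[1, 1])
})

test_that("median filtering preserves constant maps exactly", {
  V <- array(2.2, c(9, 9))
  valid <- array(TRUE, c(9, 9))
  out <- swei4d:::.medianFilterND(V, valid, c(3, 3))
  expect_equal(out, V)
  V3 <- array(1.4, c(5, 5, 5)); valid3 <- array(TRUE, c(5, 5, 5))
  expect_equal(swei4d:::.medianFilterND(V3, valid3, c(3, 3, 3)), V3)
})

test_that("2-D and 3-D reconstructions agree on a homogeneous field", {
  g <- smallGrid(xlim = c(0, 8), ylim = c(-1.2, 1.2), zlim = c(19.6, 22.4),
                 spacing = 0.2, prf = 10, duration = 10)
  ph <- homogeneousPhantom(materialSpec(E = 12), center = c(4, 0, 21),
                           radius = 0.8)
  f <- simulateDisplacements(ph, tableExcitation(1), g)
  truth <- shearWaveSpeed(materialSpec(E = 12))
  m2 <- reconstructSWS(f, "image2d", cfg = patchConfig(3, 5))
  m3 <- reconstructSWS(f, "volume3d", cfg = patchConfig(3, 5))
  med2 <- stats::median(mapSpeeds(m2)[mapValid(m2)])
  iy <- which.min(abs(mapAxes(m3)$y))
  pl3 <- mapSpeeds(m3)[, iy, ]; va3 <- mapValid(m3)[, iy, ]
  med3 <- stats::median(pl3[va3])
  expect_lt(abs(med2 / truth - 1), 0.05)
  expect_lt(abs(med3 / truth - 1), 0.05)
  expect_lt(abs(med2 - med3) / truth, 0.05)
})
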