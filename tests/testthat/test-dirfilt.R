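# Directional filters: boundary weights, angular weighting, symmetry,
# selectivity, consistency across dimensionality.

negIdx <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))

test_that("quadrant filter boundary lines carry the boundary value exactly", {
  for (n in list(c(50, 64), c(51, 121))) {   # even (Nyquist) and odd axes
    kx <- swei4d:::.fftfreq(n[1], 0.2)
    om <- swei4d:::.fftfreq(n[2], 0.1)
    W <- filterWeights(quadrantFilter(kx, om, 0.5))
    expect_true(all(W[kx == 0, ] == 0.5))
    expect_true(all(W[, om == 0] == 0.5))
    expect_true(all(W %in% c(0, 0.5, 1)))
    # exact negation symmetry on the discrete grid
    expect_identical(W, W[negIdx(n[1]), negIdx(n[2])])
  }
})

test_that("angular filter matches cos^q with clamping", {
  kx <- swei4d:::.fftfreq(32, 0.2)
  kz <- swei4d:::.fftfreq(32, 0.2)
  A <- filterWeights(angularFilter(list(kx, kz), u = c(1, 0), q = 2))
  # k parallel to u
  i <- which(kx > 0)[1]
  expect_equal(A[i, kz == 0], 1)
  # k orthogonal
  expect_equal(A[kx == 0, which(kz > 0)[1]], 0)
  # 60 degrees, q = 2 -> 0.25
  A60 <- filterWeights(angularFilter(list(c(0, 0.5), c(0, sqrt(3) / 2)),
                                     u = c(1, 0), q = 2))
  expect_equal(A60[2, 2], 0.25)
  # negative cosines are clamped, DC is 1
  expect_true(all(A[kx < 0, ] == 0))
  expect_equal(A[kx == 0, kz == 0], 1)
  expect_error(angularFilter(list(kx, kz), u = c(0, 0)), "nonzero")
})

test_that("built filters stay within [0, 1] and are negation symmetric", {
  g <- gridSpec(xlim = c(0, 5), ylim = c(-1, 1), zlim = c(20, 22),
                spacing = 0.25, prf = 10, duration = 6.4)  # even time axis
  d <- gridDims(g)
  for (dim in 2:4) {
    W <- filterWeights(buildFilter(filterSpec(dim), g))
    expect_gte(min(W), 0)
    expect_lte(max(W), 1)
    dn <- dim(W)
    Wn <- W
    for (k in seq_along(dn)) {
      idx <- rep(list(quote(expr = )), length(dn))
      idx[[k]] <- negIdx(dn[k])
      Wn <- do.call(`[`, c(list(Wn), idx, list(drop = FALSE)))
    }
    expect_identical(W, array(Wn, dn))
  }
})

test_that("3-D filter is bounded by the boundary value on the kx = 0 plane", {
  g <- smallGrid()
  W <- filterWeights(buildFilter(filterSpec(3), fieldGrid(imagingPlane(
    wavePacketField(g)))))
  kx <- swei4d:::.fftfreq(dim(W)[1], gridSpacing(g)[1])
  expect_true(all(W[kx == 0, , ] <= 0.5 + 1e-12))
})

test_that("filtered output is real and energy never amplified", {
  g <- smallGrid(ylim = c(-0.6, 0.6), zlim = c(19, 22))
  f <- wavePacketField(g)
  for (dim in 2:4) {
    out <- applyFilter(f, filterSpec(dim))
    expect_true(all(is.finite(fieldData(out))))
    ein <- if (dim == 4) fieldEnergy(f) else fieldEnergy(imagingPlane(f))
    expect_lte(fieldEnergy(out), ein * (1 + 1e-12))
  }
  # imaginary residue of the symmetrized filter is numerically zero
  u <- fieldData(imagingPlane(f))
  slab <- array(u, dim(u)[c(1, 3, 4)])
  W <- filterWeights(buildFilter(filterSpec(3), fieldGrid(imagingPlane(f))))
  cplx <- fft(fft(slab) * W, inverse = TRUE) / length(slab)
  expect_lt(max(abs(Im(cplx))), 1e-8 * max(abs(Re(cplx))))
})

test_that("forward packets pass and reversed packets are rejected", {
  g <- smallGrid(ylim = c(-0.6, 0.6), zlim = c(19, 22))
  fwd <- wavePacketField(g, direction = 1)
  rev <- wavePacketField(g, direction = -1)
  for (dim in 2:4) {
    sp <- filterSpec(dim)
    eF <- if (dim == 4) fieldEnergy(applyFilter(fwd, sp)) / fieldEnergy(fwd)
      else fieldEnergy(applyFilter(fwd, sp)) / fieldEnergy(imagingPlane(fwd))
    eR <- if (dim == 4) fieldEnergy(applyFilter(rev, sp)) / fieldEnergy(rev)
      else fieldEnergy(applyFilter(rev, sp)) / fieldEnergy(imagingPlane(rev))
    expect_gt(eF, 0.9)
    expect_lt(eR, 0.1)
  }
})

test_that("angular transmission is non-increasing with propagation angle", {
  # single-direction plane waves at angles swept from +x toward -x in the
  # (x, z) plane: filter weight sampled on the propagation wave vector
  n <- 48; sp <- 0.2
  kx <- swei4d:::.fftfreq(n, sp); kz <- swei4d:::.fftfreq(n, sp)
  A <- filterWeights(angularFilter(list(kx, kz), u = c(1, 0), q = 2))
  trans <- vapply(seq(0, 180, by = 15) * pi / 180, function(th) {
    kv <- 0.8 * c(cos(th), sin(th))
    A[which.min(abs(kx - kv[1])), which.min(abs(kz - kv[2]))]
  }, numeric(1))
  expect_true(all(diff(trans) <= 1e-12))
  expect_equal(trans[1], 1)
  expect_lt(trans[length(trans)], 1e-12)
})

test_that("2-D, 3-D and 4-D filtering agree for fields constant in y and z", {
  g <- smallGrid(ylim = c(-0.6, 0.6), zlim = c(19, 22))
  f <- wavePacketField(g)
  outs <- lapply(2:4, function(dim)
    fieldData(imagingPlane(applyFilter(f, filterSpec(dim)))))
  expect_equal(outs[[1]], outs[[2]], tolerance = 1e-10)
  expect_equal(outs[[1]], outs[[3]], tolerance = 1e-10)
})

test_that("repeating a quadrant filter changes little beyond the first pass", {
  g <- smallGrid(ylim = c(0, 0), zlim = c(20, 21))
  f <- wavePacketField(g)
  sp <- filterSpec(2)
  once <- applyFilter(f, sp)
  twice <- applyFilter(once, sp)
  d1 <- fieldEnergy(imagingPlane(f)) - fieldEnergy(once)
  d2 <- fieldEnergy(once) - fieldEnergy(twice)
  expect_gte(d2, -1e-9)
  expect_lt(d2, d1)
})
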