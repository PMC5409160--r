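# Image-quality metrics: CNR, percent bias, ROI geometry, experiment driver.

mkMap <- function(speeds, valid = NULL, spacing = 0.2,
                  x = seq(0, 10, by = spacing), z = seq(14, 28, by = spacing)) {
  if (is.null(valid)) valid <- array(TRUE, dim(speeds))
  new("SWSMap", speeds = speeds, valid = valid,
      axes = list(x = x, z = z), spacing = rep(spacing, 2))
}

plantedMap <- function(inside = 2, outside = 1, sdIn = 0, sdOut = 0,
                       seed = 1) {
  x <- seq(0, 10, by = 0.2); z <- seq(14, 28, by = 0.2)
  set.seed(seed)
  sp <- matrix(rnorm(length(x) * length(z), outside, sdOut),
               length(x), length(z))
  DX <- outer(x - 5, rep(1, length(z)))
  Z <- outer(rep(1, length(x)), z)
  les <- DX^2 + (Z - 21)^2 < 2.5^2
  sp[les] <- rnorm(sum(les), inside, sdIn)
  mkMap(sp)
}

roiStd <- roiGeometry(lesionCenter = c(5, 21), roiDiameter = 4,
                      lesionRadius = 2.5, standoff = 0.5)

test_that("ROI masks are disjoint, strict-interior and correctly placed", {
  map <- plantedMap()
  mk <- roiMasks(map, roiStd)
  expect_false(any(mk$inside & mk$outside))
  x <- mapAxes(map)$x; z <- mapAxes(map)$z
  DX <- outer(x - 5, rep(1, length(z)))
  Z <- outer(rep(1, length(x)), z)
  expect_true(all((DX^2 + (Z - 21)^2)[mk$inside] < 4))
  # background ROIs live above and below the lesion, outside it
  expect_true(all(abs(Z[mk$outside] - 21) > 2.5))
})

test_that("CNR matches its closed form on planted maps", {
  flat <- plantedMap(inside = 1, outside = 1, sdIn = 0.2, sdOut = 0.2)
  expect_lt(abs(cnr(flat, roiStd)), 0.35)       # zero contrast, noisy
  m <- plantedMap(inside = 2, outside = 1, sdIn = 0.5, sdOut = 0.5, seed = 4)
  mk <- roiMasks(m, roiStd)
  vi <- mapSpeeds(m)[mk$inside]; vo <- mapSpeeds(m)[mk$outside]
  expect_equal(cnr(m, roiStd),
               (mean(vi) - mean(vo)) / sqrt(var(vi) + var(vo)))
  # affine rescaling of the whole map leaves CNR unchanged
  m2 <- mkMap(3 * mapSpeeds(m) + 0.7)
  expect_equal(cnr(m2, roiStd), cnr(m, roiStd), tolerance = 1e-12)
})

test_that("percent bias is exact, per-pixel and antisymmetric", {
  exact <- plantedMap(inside = 2, outside = 1)
  expect_true(all(percentBias(exact, roiStd, 2) == 0))
  up <- plantedMap(inside = 2.2)
  expect_true(all(abs(percentBias(up, roiStd, 2) - 10) < 1e-9))
  dn <- plantedMap(inside = 1.8)
  expect_equal(mean(percentBias(up, roiStd, 2)),
               -mean(percentBias(dn, roiStd, 2)), tolerance = 1e-9)
  expect_error(percentBias(up, roiStd, -1), "positive")
})

test_that("empty ROIs raise errors", {
  m <- plantedMap()
  m@valid[] <- FALSE
  expect_error(cnr(m, roiStd), "empty")
  expect_error(percentBias(m, roiStd, 2), "empty")
})

test_that("experiment driver tabulates filter x realization combinations", {
  ph <- lesionPhantom(12)
  expect_equal(nrow(evaluateExperiment(list(), list(filterSpec(2)),
                                       "image2d", ph)), 0)
  g <- deskGrid()
  f <- simulateDisplacements(ph, tableExcitation(1), g)
  res <- evaluateExperiment(list(f), list(NULL, filterSpec(2)), "image2d",
                            ph, cfg = patchConfig(3, 5))
  expect_equal(nrow(res), 2)
  expect_setequal(res$filter_dim, c(0L, 2L))
  expect_true(all(is.finite(res$cnr)))
  expect_true(all(res$n_lesion_px > 100))
})

test_that("noiseless homogeneous evaluation gives near-zero contrast and bias", {
  g <- deskGrid()
  ph0 <- homogeneousPhantom(materialSpec(E = 3), center = c(5, 0, 21),
                            radius = 2.5)
  f <- simulateDisplacements(ph0, tableExcitation(1), g)
  res <- evaluateExperiment(list(f), list(NULL), "image2d", ph0,
                            cfg = patchConfig(3, 5))
  expect_lt(abs(res$bias_median), 1)
  expect_lt(abs(res$cnr), 1)
})
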