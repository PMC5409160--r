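# Synthetic wavefield generator: arrival-time oracle, linearity, symmetry,
# reflection phenomenology.

gHom <- smallGrid(xlim = c(0, 10), ylim = c(-1, 1), zlim = c(20, 22),
                  spacing = 0.2, prf = 10, duration = 12)
phHom <- homogeneousPhantom(materialSpec(E = 3), center = c(5, 0, 21),
                            radius = 0.8)

test_that("pulse peak arrival time equals distance over configured speed", {
  f <- simulateDisplacements(phHom, tableExcitation(1), gHom)
  ax <- gridAxes(gHom)
  cb <- shearWaveSpeed(materialSpec(E = 3))
  iy <- which.min(abs(ax$y)); iz <- which.min(abs(ax$z - 21))
  for (xx in c(3, 5, 8)) {
    ix <- which.min(abs(ax$x - xx))
    tr <- fieldData(f)[ix, iy, iz, ]
    tPeak <- ax$t[which.max(tr)]
    expect_lt(abs(tPeak - xx / cb), 1 / gridPRF(gHom) + 1e-9)
  }
})

test_that("field scales linearly in the excitation amplitude", {
  e1 <- tableExcitation(1, A = 4)
  e2 <- tableExcitation(1, A = 8)
  f1 <- simulateDisplacements(phHom, e1, gHom, seed = 3L)
  f2 <- simulateDisplacements(phHom, e2, gHom, seed = 3L)
  expect_equal(2 * fieldData(f1), fieldData(f2), tolerance = 1e-12)
  f0 <- simulateDisplacements(phHom, tableExcitation(1, A = 0), gHom)
  expect_true(all(fieldData(f0) == 0))
})

test_that("homogeneous fields carry no secondary pulse", {
  f <- simulateDisplacements(phHom, tableExcitation(1), gHom)
  ax <- gridAxes(gHom)
  iy <- which.min(abs(ax$y)); iz <- which.min(abs(ax$z - 21))
  for (xx in c(3, 6)) {
    ix <- which.min(abs(ax$x - xx))
    tr <- abs(fieldData(f)[ix, iy, iz, ])
    pk <- which.max(tr)
    late <- tr[ax$t > ax$t[pk] + 2]
    expect_lt(max(late) / max(tr), 0.05)
  }
})

test_that("reflected amplitude grows with impedance contrast", {
  # isolate the secondary (reflected) energy at a background point proximal
  # to the lesion: everything arriving after the incident pulse has passed
  g <- deskGrid()
  ax <- gridAxes(g)
  iy <- which.min(abs(ax$y)); iz <- which.min(abs(ax$z - 21))
  ix <- which.min(abs(ax$x - 1.5))
  cb <- shearWaveSpeed(materialSpec(E = 3))
  rel <- vapply(c(6, 12, 18.75), function(E) {
    f <- simulateDisplacements(lesionPhantom(E), tableExcitation(1), g)
    tr <- abs(fieldData(f)[ix, iy, iz, ])
    pk <- which.max(tr)
    max(tr[ax$t > ax$t[pk] + 1.2]) / max(tr)
  }, numeric(1))
  expect_true(all(diff(rel) > 0))
  expect_gt(rel[3], 2 * rel[1])
})

test_that("fields are mirror symmetric about y = 0 for symmetric geometry", {
  g <- smallGrid(xlim = c(0, 8), ylim = c(-2, 2), zlim = c(19.5, 22.5),
                 spacing = 0.25, prf = 10, duration = 10)
  ph <- phantomSpec(materialSpec(3), materialSpec(12),
                    lesionCenter = c(5, 0, 21), lesionRadius = 1.2)
  f <- simulateDisplacements(ph, tableExcitation(1), g)
  u <- fieldData(f)
  ny <- dim(u)[2]
  expect_equal(u, u[, rev(seq_len(ny)), , ], tolerance = 1e-10)
})

test_that("generation is deterministic for a fixed seed", {
  g <- smallGrid()
  ph <- lesionPhantom(12, backgroundE = 3)
  ph@lesionCenter <- c(5, 0, 21); ph@lesionRadius <- 0.8
  f1 <- simulateDisplacements(ph, tableExcitation(1), g, seed = 7L)
  f2 <- simulateDisplacements(ph, tableExcitation(1), g, seed = 7L)
  expect_identical(fieldData(f1), fieldData(f2))
  f3 <- simulateDisplacements(ph, tableExcitation(1), g, seed = 8L)
  expect_false(identical(fieldData(f1), fieldData(f3)))
})

test_that("invalid geometry is rejected before compute", {
  g <- smallGrid()
  ph <- phantomSpec(materialSpec(3), materialSpec(12),
                    lesionCenter = c(9.5, 0, 21), lesionRadius = 2)
  expect_error(simulateDisplacements(ph, tableExcitation(1), g), "boundary")
  g1 <- gridSpec(xlim = c(0, 0.1), ylim = c(0, 0), zlim = c(20, 21),
                 spacing = 0.2, prf = 10, duration = 1)
  expect_error(simulateDisplacements(phHom, tableExcitation(1), g1),
               "degenerate")
})
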