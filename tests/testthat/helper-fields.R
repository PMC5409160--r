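# Shared fixtures: small grids and synthetic propagating wave packets built
# in code at test time.

smallGrid <- function(xlim = c(0, 10), ylim = c(-1, 1), zlim = c(19, 22),
                      spacing = 0.2, prf = 10, duration = 10) {
  gridSpec(xlim = xlim, ylim = ylim, zlim = zlim, spacing = spacing,
           prf = prf, duration = duration)
}

# Zero-mean modulated wave packet translating along +/- x at `speed` (m/s),
# constant across y and z. Its energy sits on the propagation branch of the
# (k, omega) plane, away from the zero-frequency boundary lines, which makes
# it the right probe for direction selectivity.
wavePacketField <- function(grid, speed = 1.5, x0 = 1.5, sigma = 0.5,
                            cycles_per_mm = 0.8, direction = 1) {
  ax <- gridAxes(grid)
  d <- vapply(ax, length, integer(1))
  u <- array(0, d)
  for (it in seq_len(d[4])) {
    tt <- if (direction > 0) ax$t[it] else max(ax$t) - ax$t[it]
    arg <- ax$x - x0 - speed * tt
    prof <- exp(-arg^2 / (2 * sigma^2)) * cos(2 * pi * cycles_per_mm * arg)
    u[, , , it] <- prof
  }
  displacementField(u, grid)
}

# Plane pulse translating along one spatial axis of a slab (time last).
planePulseSlab <- function(nAlong, nAcross, t, speed, spacing, x0 = 0.5,
                           sigma = 0.4) {
  ax <- (seq_len(nAlong) - 1) * spacing
  slab <- array(0, c(nAlong, nAcross, length(t)))
  for (it in seq_along(t)) {
    prof <- exp(-(ax - x0 - speed * t[it])^2 / (2 * sigma^2))
    slab[, , it] <- prof
  }
  slab
}

referenceMaterials <- function() {
  list(bg = materialSpec(E = 3), soft = materialSpec(E = 6),
       mid = materialSpec(E = 12), stiff = materialSpec(E = 18.75))
}
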