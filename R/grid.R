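# Grid accessors and show methods.

.axisFromExtent <- function(lim, d) {
  n <- floor((lim[2] - lim[1]) / d + 1e-9) + 1
  lim[1] + (seq_len(n) - 1) * d
}

#' Grid coordinate axes
#'
#' @param grid a \code{GridSpec}.
#' @return \code{gridAxes}: named list with numeric vectors \code{x},
#'   \code{y}, \code{z} (mm) and \code{t} (ms). \code{gridDims}: integer(4)
#'   array dimensions (nx, ny, nz, nt).
#' @export
gridAxes <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  list(x = .axisFromExtent(grid@extents[1, ], grid@spacing[1]),
       y = .axisFromExtent(grid@extents[2, ], grid@spacing[2]),
       z = .axisFromExtent(grid@extents[3, ], grid@spacing[3]),
       t = (seq_len(floor(grid@duration * grid@prf) + 1) - 1) / grid@prf)
}

#' @rdname gridAxes
#' @export
gridDims <- function(grid) {
  ax <- gridAxes(grid)
  vapply(ax, length, integer(1))
}

#' @rdname gridAxes
#' @export
gridSpacing <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  grid@spacing
}

#' @rdname gridAxes
#' @export
gridPRF <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  grid@prf
}

#' Displacement field accessors
#'
#' @param field a \code{DisplacementField}.
#' @return \code{fieldData}: the 4-D displacement array (micrometres);
#'   \code{fieldGrid}: the \code{GridSpec}; \code{fieldEnergy}: sum of squared
#'   displacements; \code{fieldProvenance}: the provenance list.
#' @export
fieldData <- function(field) {
  stopifnot(is(field, "DisplacementField"))
  field@data
}

#' @rdname fieldData
#' @export
fieldGrid <- function(field) {
  stopifnot(is(field, "DisplacementField"))
  field@grid
}

#' @rdname fieldData
#' @export
fieldEnergy <- function(field) {
  sum(fieldData(field)^2)
}

#' @rdname fieldData
#' @export
fieldProvenance <- function(field) {
  stopifnot(is(field, "DisplacementField"))
  field@provenance
}

#' SWS map accessors
#'
#' @param map an \code{SWSMap}.
#' @return \code{mapSpeeds}: speeds array (m/s); \code{mapValid}: logical
#'   mask; \code{mapAxes}: named list of coordinate vectors (mm).
#' @export
mapSpeeds <- function(map) {
  stopifnot(is(map, "SWSMap"))
  map@speeds
}

#' @rdname mapSpeeds
#' @export
mapValid <- function(map) {
  stopifnot(is(map, "SWSMap"))
  map@valid
}

#' @rdname mapSpeeds
#' @export
mapAxes <- function(map) {
  stopifnot(is(map, "SWSMap"))
  map@axes
}

#' Extract the y = 0 imaging plane of a field
#'
#' Returns the (x, z, t) slab at the y closest to 0, as used by the 2-D and
#' 3-D directional filters and by 2-D SWS reconstruction.
#'
#' @param field a \code{DisplacementField}.
#' @return A \code{DisplacementField} whose y dimension has length 1.
#' @export
imagingPlane <- function(field) {
  ax <- gridAxes(fieldGrid(field))
  iy <- which.min(abs(ax$y))
  if (length(ax$y) == 1L) return(field)
  g <- fieldGrid(field)
  g2 <- gridSpec(xlim = g@extents[1, ], ylim = rep(ax$y[iy], 2),
                 zlim = g@extents[3, ], spacing = g@spacing, prf = g@prf,
                 duration = g@duration)
  d <- fieldData(field)[, iy, , , drop = FALSE]
  displacementField(d, g2, c(fieldProvenance(field), list(plane = "y0")))
}

setMethod("show", "MaterialSpec", function(object) {
  cat(sprintf("MaterialSpec: E = %g kPa, rho = %g g/cm^3, nu = %g (c_T = %.3f m/s)\n",
              object@E, object@rho, object@nu, shearWaveSpeed(object)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec\n")
  cat(sprintf("  background: E = %g kPa (c_T = %.3f m/s)\n",
              object@background@E, shearWaveSpeed(object@background)))
  cat(sprintf("  lesion:     E = %g kPa (c_T = %.3f m/s)\n",
              object@lesion@E, shearWaveSpeed(object@lesion)))
  cat(sprintf("  sphere: centre (%s) mm, radius %g mm\n",
              paste(object@lesionCenter, collapse = ", "),
              object@lesionRadius))
})

setMethod("show", "GridSpec", function(object) {
  d <- gridDims(object)
  cat(sprintf("GridSpec: %d x %d x %d x %d (x, y, z, t)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, PRF %g kHz, %g ms\n",
              paste(object@spacing, collapse = "/"), object@prf,
              object@duration))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@data)
  cat(sprintf("DisplacementField: %d x %d x %d x %d (x, y, z, t)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  peak |displacement| %.3g um, PRF %g kHz, spacing %s mm\n",
              max(abs(range(object@data))), object@grid@prf,
              paste(object@grid@spacing, collapse = "/")))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf("FilterSpec: %d-D directional filter, u = (%s), q = %g, boundary = %g\n",
              object@dimensionality, paste(object@u, collapse = ", "),
              object@q, object@boundaryValue))
})

setMethod("show", "SWSMap", function(object) {
  d <- dim(object@speeds)
  v <- object@speeds[object@valid]
  cat(sprintf("SWSMap: %s (%s), %d/%d valid\n",
              paste(d, collapse = " x "),
              if (length(d) == 2) "x, z" else "x, y, z",
              sum(object@valid), length(object@valid)))
  if (length(v))
    cat(sprintf("  speeds: median %.3f m/s, range [%.3f, %.3f]\n",
                stats::median(v), min(v), max(v)))
})
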