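#' @import methods
NULL

#' Elastic material properties
#'
#' Linear elastic, nearly incompressible material described by Young's
#' modulus, density and Poisson's ratio. With \code{E} in kPa and \code{rho}
#' in g/cm^3 the expected shear wave speed \code{sqrt(E / (2 * rho * (1 + nu)))}
#' is numerically in m/s.
#'
#' @slot E Young's modulus (kPa).
#' @slot rho density (g/cm^3).
#' @slot nu Poisson's ratio (dimensionless, in [0, 0.5)).
#' @export
setClass("MaterialSpec",
  slots = c(E = "numeric", rho = "numeric", nu = "numeric"),
  prototype = prototype(E = 3, rho = 1, nu = 0.495),
  validity = function(object) {
    msg <- character()
    if (length(object@E) != 1 || !is.finite(object@E) || object@E <= 0)
      msg <- c(msg, "E must be a single positive number (kPa)")
    if (length(object@rho) != 1 || !is.finite(object@rho) || object@rho <= 0)
      msg <- c(msg, "rho must be a single positive number (g/cm^3)")
    if (length(object@nu) != 1 || !is.finite(object@nu) ||
        object@nu < 0 || object@nu >= 0.5)
      msg <- c(msg, "nu must lie in [0, 0.5)")
    if (length(msg)) msg else TRUE
  })

#' @param E Young's modulus (kPa).
#' @param rho density (g/cm^3).
#' @param nu Poisson's ratio.
#' @return A \code{MaterialSpec} object.
#' @rdname MaterialSpec-class
#' @export
#' @examples
#' bg <- materialSpec(E = 3)
#' shearWaveSpeed(bg)
materialSpec <- function(E, rho = 1, nu = 0.495) {
  new("MaterialSpec", E = as.numeric(E), rho = as.numeric(rho),
      nu = as.numeric(nu))
}

#' Phantom with a spherical inclusion
#'
#' Background medium plus a stiff (or soft) spherical lesion. The lesion
#' centre and radius are in mm on the simulation grid axes.
#'
#' @slot background,lesion \code{MaterialSpec} objects.
#' @slot lesionCenter numeric(3), lesion centre (x, y, z) in mm.
#' @slot lesionRadius lesion radius in mm.
#' @export
setClass("PhantomSpec",
  slots = c(background = "MaterialSpec", lesion = "MaterialSpec",
            lesionCenter = "numeric", lesionRadius = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@lesionCenter) != 3 || !all(is.finite(object@lesionCenter)))
      msg <- c(msg, "lesionCenter must be numeric(3) (mm)")
    if (length(object@lesionRadius) != 1 || !is.finite(object@lesionRadius) ||
        object@lesionRadius <= 0)
      msg <- c(msg, "lesionRadius must be a single positive number (mm)")
    if (length(msg)) msg else TRUE
  })

#' @param background,lesion \code{MaterialSpec} objects.
#' @param lesionCenter numeric(3), lesion centre (x, y, z) in mm.
#' @param lesionRadius lesion radius (mm).
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(background, lesion, lesionCenter = c(5, 0, 21),
                        lesionRadius = 2.5) {
  new("PhantomSpec", background = background, lesion = lesion,
      lesionCenter = as.numeric(lesionCenter),
      lesionRadius = as.numeric(lesionRadius))
}

#' Gaussian ARFI excitation
#'
#' Spatial distribution of the acoustic radiation force body load: a 3-D
#' Gaussian envelope with peak amplitude \code{A}, gated on for
#' \code{0 <= t < tOn}.
#'
#' @slot A peak amplitude. For the synthetic generator this acts as the
#'   peak-displacement calibration (micrometres).
#' @slot center numeric(3), source centre (x0, y0, z0) in mm.
#' @slot sigma numeric(3), Gaussian standard deviations (mm).
#' @slot tOn pulse duration (ms).
#' @export
setClass("ExcitationSpec",
  slots = c(A = "numeric", center = "numeric", sigma = "numeric",
            tOn = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@A) != 1 || !is.finite(object@A))
      msg <- c(msg, "A must be a single finite number")
    if (length(object@center) != 3 || !all(is.finite(object@center)))
      msg <- c(msg, "center must be numeric(3) (mm)")
    if (length(object@sigma) != 3 || !all(is.finite(object@sigma)) ||
        any(object@sigma <= 0))
      msg <- c(msg, "sigma must be numeric(3), all positive (mm)")
    if (length(object@tOn) != 1 || !is.finite(object@tOn) || object@tOn <= 0)
      msg <- c(msg, "tOn must be a single positive number (ms)")
    if (length(msg)) msg else TRUE
  })

#' @param A peak amplitude (micrometres of peak displacement for the
#'   synthetic generator).
#' @param center numeric(3) source centre (mm).
#' @param sigma numeric(3) Gaussian standard deviations (mm).
#' @param tOn pulse duration (ms).
#' @rdname ExcitationSpec-class
#' @export
excitationSpec <- function(A = 10, center = c(0, 0, 21),
                           sigma = c(0.21, 0.21, 4.25), tOn = 0.08) {
  new("ExcitationSpec", A = as.numeric(A), center = as.numeric(center),
      sigma = as.numeric(sigma), tOn = as.numeric(tOn))
}

#' Regular space-time sampling grid
#'
#' Cartesian grid for 4-D displacement volumes. Axes are
#' \code{min + (0:(n-1)) * spacing} per spatial dimension and
#' \code{(0:(nt-1)) / prf} in slow time.
#'
#' @slot extents 3 x 2 matrix of per-axis (min, max) in mm, rows x, y, z.
#' @slot spacing numeric(3), grid spacing (dx, dy, dz) in mm.
#' @slot prf temporal sampling rate (kHz).
#' @slot duration total tracked time (ms).
#' @export
setClass("GridSpec",
  slots = c(extents = "matrix", spacing = "numeric", prf = "numeric",
            duration = "numeric"),
  validity = function(object) {
    msg <- character()
    ex <- object@extents
    if (!is.numeric(ex) || !all(dim(ex) == c(3, 2)) || !all(is.finite(ex)))
      msg <- c(msg, "extents must be a finite 3 x 2 numeric matrix")
    else if (any(ex[, 2] < ex[, 1]))
      msg <- c(msg, "extents must satisfy min <= max per axis")
    if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be numeric(3), all positive (mm)")
    if (length(object@prf) != 1 || !is.finite(object@prf) || object@prf <= 0)
      msg <- c(msg, "prf must be a single positive number (kHz)")
    if (length(object@duration) != 1 || !is.finite(object@duration) ||
        object@duration <= 0)
      msg <- c(msg, "duration must be a single positive number (ms)")
    if (length(msg) == 0 && floor(object@duration * object@prf) + 1 < 2)
      msg <- c(msg, "grid must contain at least 2 time samples")
    if (length(msg)) msg else TRUE
  })

#' @param xlim,ylim,zlim numeric(2) per-axis extents (mm).
#' @param spacing grid spacing in mm; a scalar is recycled to all three axes.
#' @param prf temporal sampling rate (kHz).
#' @param duration total time (ms).
#' @rdname GridSpec-class
#' @export
gridSpec <- function(xlim = c(0, 10), ylim = c(-3, 3), zlim = c(14, 28),
                     spacing = 0.2, prf = 10, duration = 12) {
  ex <- rbind(x = as.numeric(xlim), y = as.numeric(ylim), z = as.numeric(zlim))
  colnames(ex) <- c("min", "max")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  new("GridSpec", extents = ex, spacing = as.numeric(spacing),
      prf = as.numeric(prf), duration = as.numeric(duration))
}

#' 4-D axial-displacement volume
#'
#' The pipeline's universal currency: axial (z) displacement in micrometres
#' sampled on a \code{GridSpec}, stored as a 4-D array indexed (x, y, z, t).
#'
#' @slot data 4-D numeric array (x, y, z, t), micrometres.
#' @slot grid the \code{GridSpec} the array is sampled on.
#' @slot provenance free-form list (seed, phantom summary, processing trail).
#' @export
setClass("DisplacementField",
  slots = c(data = "array", grid = "GridSpec", provenance = "list"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 4)
      msg <- c(msg, "data must be a 4-D array (x, y, z, t)")
    else {
      gd <- gridDims(object@grid)
      if (!all(d == gd))
        msg <- c(msg, sprintf("data dims (%s) do not match grid dims (%s)",
                              paste(d, collapse = "x"),
                              paste(gd, collapse = "x")))
    }
    if (anyNA(object@data) || any(is.infinite(range(object@data))))
      msg <- c(msg, "data must be finite")
    if (length(msg)) msg else TRUE
  })

#' @param data 4-D numeric array (x, y, z, t).
#' @param grid a \code{GridSpec}.
#' @param provenance list of free-form metadata.
#' @rdname DisplacementField-class
#' @export
displacementField <- function(data, grid, provenance = list()) {
  new("DisplacementField", data = data, grid = grid, provenance = provenance)
}

#' Directional filter specification
#'
#' @slot dimensionality 2, 3 or 4 (number of Fourier axes, time included).
#' @slot u unit propagation direction: length 2 for 3-D filters (kx, kz),
#'   length 3 for 4-D filters (kx, ky, kz); ignored by the 2-D filter.
#' @slot q angular cosine exponent (>= 0).
#' @slot boundaryValue weight on the zero-frequency (and Nyquist) lines.
#' @export
setClass("FilterSpec",
  slots = c(dimensionality = "integer", u = "numeric", q = "numeric",
            boundaryValue = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@dimensionality) != 1 ||
        !(object@dimensionality %in% 2:4))
      msg <- c(msg, "dimensionality must be 2, 3 or 4")
    else {
      need <- c(`2` = 2L, `3` = 2L, `4` = 3L)[as.character(object@dimensionality)]
      if (length(object@u) != need)
        msg <- c(msg, sprintf("u must have length %d for a %d-D filter",
                              need, object@dimensionality))
      else if (abs(sqrt(sum(object@u^2)) - 1) > 1e-8)
        msg <- c(msg, "u must be a unit vector")
    }
    if (length(object@q) != 1 || !is.finite(object@q) || object@q < 0)
      msg <- c(msg, "q must be a single number >= 0")
    if (length(object@boundaryValue) != 1 ||
        !is.finite(object@boundaryValue) ||
        object@boundaryValue < 0 || object@boundaryValue > 1)
      msg <- c(msg, "boundaryValue must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' @param dimensionality 2, 3 or 4.
#' @param u unit propagation direction (default +x).
#' @param q angular cosine exponent.
#' @param boundaryValue weight on quadrant boundaries.
#' @rdname FilterSpec-class
#' @export
filterSpec <- function(dimensionality, u = NULL, q = 2, boundaryValue = 0.5) {
  dimensionality <- as.integer(dimensionality)
  if (is.null(u))
    u <- if (identical(dimensionality, 4L)) c(1, 0, 0) else c(1, 0)
  new("FilterSpec", dimensionality = dimensionality, u = as.numeric(u),
      q = as.numeric(q), boundaryValue = as.numeric(boundaryValue))
}

#' Directional filter weights on the discrete frequency grid
#'
#' Real weights in [0, 1] over the unshifted discrete Fourier grid of the
#' slab they apply to, symmetric under simultaneous negation of all
#' frequency axes so that filtered output is real.
#'
#' @slot weights numeric array of filter weights.
#' @slot axes list of frequency coordinate vectors (cycles/mm, cycles/ms)
#'   matching \code{weights} dimensions, unshifted fft layout.
#' @export
setClass("FilterArray",
  slots = c(weights = "array", axes = "list"),
  validity = function(object) {
    msg <- character()
    r <- range(object@weights)
    if (r[1] < -1e-12 || r[2] > 1 + 1e-12)
      msg <- c(msg, "weights must lie in [0, 1]")
    if (length(object@axes) != length(dim(object@weights)))
      msg <- c(msg, "axes must have one entry per weights dimension")
    if (length(msg)) msg else TRUE
  })

#' Patch and window configuration for SWS estimation
#'
#' @slot p patch separation in pixels between the correlated trace pair.
#' @slot w window size in pixels of the weighted component fusion; the
#'   fusion neighbourhood has (w - p + 1) estimates per axis.
#' @slot prf working temporal sampling rate (kHz) the field is upsampled to
#'   before lag estimation.
#' @export
setClass("PatchConfig",
  slots = c(p = "integer", w = "integer", prf = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@p <= 0 || object@p >= object@w)
      msg <- c(msg, "need 0 < p < w")
    if ((object@w - object@p) %% 2 != 0)
      msg <- c(msg, "w - p must be even")
    if (length(object@prf) != 1 || !is.finite(object@prf) || object@prf <= 0)
      msg <- c(msg, "prf must be a single positive number (kHz)")
    if (length(msg)) msg else TRUE
  })

#' @param p patch separation (pixels).
#' @param w fusion window (pixels).
#' @param prf working PRF (kHz).
#' @rdname PatchConfig-class
#' @export
patchConfig <- function(p = 6, w = 10, prf = 50) {
  new("PatchConfig", p = as.integer(p), w = as.integer(w),
      prf = as.numeric(prf))
}

#' Reconstructed shear wave speed map
#'
#' 2-D image (x, z) or 3-D volume (x, y, z) of shear wave speeds with a
#' validity mask. Speeds are magnitudes in m/s.
#'
#' @slot speeds numeric array (2-D or 3-D), m/s.
#' @slot valid logical array, same shape; FALSE where no estimate exists.
#' @slot axes named list of spatial coordinate vectors (mm).
#' @slot spacing numeric pixel pitch per axis (mm).
#' @export
setClass("SWSMap",
  slots = c(speeds = "array", valid = "array", axes = "list",
            spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@speeds) == dim(object@valid)))
      msg <- c(msg, "speeds and valid must have the same shape")
    if (length(object@axes) != length(dim(object@speeds)))
      msg <- c(msg, "axes must have one entry per speeds dimension")
    v <- object@speeds[object@valid]
    if (length(v) && (anyNA(v) || any(is.infinite(v))))
      msg <- c(msg, "speeds must be finite where valid")
    if (length(msg)) msg else TRUE
  })

#' Region-of-interest geometry for lesion image-quality metrics
#'
#' A circular ROI inside the lesion plus two background half-circles of the
#' same diameter directly above and below the lesion at the same lateral
#' position, standing off from the lesion edge.
#'
#' @slot lesionCenter numeric(2), lesion centre (x, z) in the imaging plane (mm).
#' @slot roiDiameter ROI diameter (mm).
#' @slot lesionRadius lesion radius (mm), used to place the background ROIs.
#' @slot standoff gap between lesion edge and background ROI flat edge (mm).
#' @export
setClass("RoiGeometry",
  slots = c(lesionCenter = "numeric", roiDiameter = "numeric",
            lesionRadius = "numeric", standoff = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@lesionCenter) != 2 || !all(is.finite(object@lesionCenter)))
      msg <- c(msg, "lesionCenter must be numeric(2) (x, z) in mm")
    if (object@roiDiameter <= 0)
      msg <- c(msg, "roiDiameter must be positive")
    if (object@roiDiameter > 2 * object@lesionRadius)
      msg <- c(msg, "roiDiameter must not exceed the lesion diameter")
    if (object@standoff < 0)
      msg <- c(msg, "standoff must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @param lesionCenter numeric(2) lesion centre (x, z) (mm).
#' @param roiDiameter ROI diameter (mm).
#' @param lesionRadius lesion radius (mm).
#' @param standoff gap between lesion edge and background ROI (mm).
#' @rdname RoiGeometry-class
#' @export
roiGeometry <- function(lesionCenter, roiDiameter = 4, lesionRadius = 2.5,
                        standoff = 1) {
  new("RoiGeometry", lesionCenter = as.numeric(lesionCenter),
      roiDiameter = as.numeric(roiDiameter),
      lesionRadius = as.numeric(lesionRadius),
      standoff = as.numeric(standoff))
}
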