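# Material helpers: expected shear wave speed, shear impedance, reflection
# coefficient, and the Gaussian ARFI body-force envelope.

#' Expected shear wave speed of a linear elastic material
#'
#' For a linear elastic, nearly incompressible medium the shear wave speed is
#' \deqn{c_T = \sqrt{E / (2 \rho (1 + \nu))}.}
#' With \code{E} in kPa and \code{rho} in g/cm^3 the result is numerically in
#' m/s (equivalently mm/ms, the package's internal speed unit).
#'
#' @param material a \code{MaterialSpec}.
#' @return Shear wave speed in m/s.
#' @export
#' @examples
#' shearWaveSpeed(materialSpec(E = 3))      # ~1.0 m/s
#' shearWaveSpeed(materialSpec(E = 18.75))  # ~2.5 m/s
setGeneric("shearWaveSpeed", function(material) standardGeneric("shearWaveSpeed"))

#' @rdname shearWaveSpeed
#' @export
setMethod("shearWaveSpeed", "MaterialSpec", function(material) {
  validObject(material)
  sqrt(material@E / (2 * material@rho * (1 + material@nu)))
})

#' Shear impedance and interface reflection coefficient
#'
#' Shear impedance is \code{Z = rho * c_T}. The reflection coefficient of a
#' background/lesion interface is \code{(Z_les - Z_bg) / (Z_les + Z_bg)}; its
#' magnitude sets the relative amplitude of the reflected shear wave and
#' grows with the stiffness contrast. (Displacement continuity across the
#' interface gives a reflected displacement coefficient of opposite sign and
#' a transmitted coefficient \code{1 - R}; the generator uses those, with the
#' same magnitude.)
#'
#' @param material a \code{MaterialSpec}.
#' @return \code{shearImpedance}: impedance in (g/cm^3) * (m/s);
#'   \code{reflectionCoefficient}: dimensionless signed coefficient.
#' @export
shearImpedance <- function(material) {
  material@rho * shearWaveSpeed(material)
}

#' @param background,lesion \code{MaterialSpec} objects on either side of the
#'   interface.
#' @rdname shearImpedance
#' @export
reflectionCoefficient <- function(background, lesion) {
  zb <- shearImpedance(background)
  zl <- shearImpedance(lesion)
  (zl - zb) / (zl + zb)
}

#' Gaussian ARFI body-force envelope
#'
#' Force density of the impulsive excitation at a point and time:
#' \code{A * exp(-((x-x0)^2/(2 sx^2) + (y-y0)^2/(2 sy^2) + (z-z0)^2/(2 sz^2)))}
#' while the push is on (\code{0 <= t < tOn}) and 0 afterwards.
#'
#' @param excitation an \code{ExcitationSpec}.
#' @param point numeric(3) position (x, y, z) in mm, or an n x 3 matrix.
#' @param t time (ms); vectorized.
#' @return Force density in the units of \code{A}; recycled over points/times.
#' @export
gaussianBodyForce <- function(excitation, point, t) {
  validObject(excitation)
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3)
    dx <- sweep(point, 2, excitation@center)
    env <- exp(-rowSums(sweep(dx^2, 2, 2 * excitation@sigma^2, `/`)))
  } else {
    stopifnot(length(point) == 3)
    dx <- point - excitation@center
    env <- exp(-sum(dx^2 / (2 * excitation@sigma^2)))
  }
  gate <- as.numeric(t >= 0 & t < excitation@tOn)
  excitation@A * env * gate
}
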