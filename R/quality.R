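# Lesion image-quality metrics: contrast-to-noise ratio over lesion and
# background ROIs, within-lesion percent bias, and the experiment driver
# that sweeps filter configurations over noise realizations.

# y = 0 plane of an SWSMap (3-D maps are evaluated on that plane, as the
# reference analysis does).
.mapPlane <- function(map) {
  if (length(dim(mapSpeeds(map))) == 2L)
    return(list(speeds = mapSpeeds(map), valid = mapValid(map),
                x = mapAxes(map)$x, z = mapAxes(map)$z))
  iy <- which.min(abs(mapAxes(map)$y))
  list(speeds = mapSpeeds(map)[, iy, ], valid = mapValid(map)[, iy, ],
       x = mapAxes(map)$x, z = mapAxes(map)$z)
}

#' ROI masks on a speed map
#'
#' Pixel-centre membership masks for the lesion ROI (circle of
#' \code{roiDiameter} at the lesion centre) and the background ROI (union of
#' two half-circles of the same diameter directly above and below the lesion
#' at the same lateral position, standing off \code{standoff} mm from the
#' lesion edge, bulging away from it). Membership is strict
#' (\code{distance < radius}).
#'
#' @param map an \code{SWSMap}.
#' @param roi an \code{RoiGeometry}.
#' @return List of logical (x, z) masks \code{inside} and \code{outside}.
#' @export
roiMasks <- function(map, roi) {
  validObject(roi)
  pl <- .mapPlane(map)
  r <- roi@roiDiameter / 2
  cx <- roi@lesionCenter[1]; cz <- roi@lesionCenter[2]
  DX <- outer(pl$x - cx, rep(1, length(pl$z)))
  Z <- outer(rep(1, length(pl$x)), pl$z)
  inside <- DX^2 + (Z - cz)^2 < r^2
  zu <- cz - roi@lesionRadius - roi@standoff
  zl <- cz + roi@lesionRadius + roi@standoff
  upper <- (DX^2 + (Z - zu)^2 < r^2) & (Z <= zu)
  lower <- (DX^2 + (Z - zl)^2 < r^2) & (Z >= zl)
  list(inside = inside, outside = upper | lower)
}

#' Contrast-to-noise ratio of a lesion speed map
#'
#' \code{CNR = (S_i - S_o) / sqrt(sigma_i^2 + sigma_o^2)} where S and sigma
#' are the mean and standard deviation of valid speeds over the lesion ROI
#' (i) and the background ROI (o) of \code{\link{roiMasks}}. 3-D maps are
#' evaluated on their y = 0 plane.
#'
#' @param map an \code{SWSMap}.
#' @param roi an \code{RoiGeometry}.
#' @return CNR (dimensionless).
#' @export
cnr <- function(map, roi) {
  pl <- .mapPlane(map)
  mk <- roiMasks(map, roi)
  vi <- pl$speeds[mk$inside & pl$valid]
  vo <- pl$speeds[mk$outside & pl$valid]
  if (length(vi) < 2 || length(vo) < 2)
    stop("empty ROI: no valid pixels to evaluate")
  (mean(vi) - mean(vo)) / sqrt(stats::var(vi) + stats::var(vo))
}

#' Within-lesion percent bias
#'
#' Per-pixel percent bias \code{100 * (c_hat - c_T) / c_T} of the
#' reconstructed speed against the true lesion speed, over the valid pixels
#' of the lesion ROI (the same ROI used for CNR).
#'
#' @param map an \code{SWSMap}.
#' @param roi an \code{RoiGeometry}.
#' @param trueSpeed true lesion shear wave speed (m/s), > 0.
#' @return Numeric vector of per-pixel percent bias values.
#' @export
percentBias <- function(map, roi, trueSpeed) {
  if (!is.finite(trueSpeed) || trueSpeed <= 0)
    stop("trueSpeed must be positive")
  pl <- .mapPlane(map)
  mk <- roiMasks(map, roi)
  ci <- pl$speeds[mk$inside & pl$valid]
  if (!length(ci)) stop("empty lesion ROI")
  100 * (ci - trueSpeed) / trueSpeed
}

#' Default ROI geometry for a phantom
#'
#' Lesion ROI of 4 mm diameter at the lesion centre; background half-circles
#' standing off from the lesion edge by half the fusion window length.
#'
#' @param phantom a \code{PhantomSpec}.
#' @param cfg a \code{PatchConfig} (for the window-derived standoff).
#' @param spacing pixel pitch (mm).
#' @return An \code{RoiGeometry}.
#' @export
defaultRoi <- function(phantom, cfg = patchConfig(), spacing = 0.2) {
  roiGeometry(lesionCenter = phantom@lesionCenter[c(1, 3)],
              roiDiameter = 4, lesionRadius = phantom@lesionRadius,
              standoff = cfg@w * spacing / 2)
}

#' Evaluate filter configurations over noise realizations
#'
#' Runs directional filter then SWS reconstruction then image-quality
#' metrics for every (filter specification, realization) combination and
#' tabulates the results. Filter dimensionality 0 denotes no filtering (raw
#' y = 0 plane for \code{image2d}, raw volume for \code{volume3d}).
#'
#' @param fields list of \code{DisplacementField} realizations on a common
#'   grid (e.g. seeded noise realizations of one simulation).
#' @param filterSpecs list of \code{FilterSpec} objects and/or \code{NULL}
#'   entries (no filtering).
#' @param mode \code{"image2d"} or \code{"volume3d"}.
#' @param phantom the \code{PhantomSpec} the fields were simulated in (for
#'   the true lesion speed and ROI geometry).
#' @param cfg optional \code{PatchConfig} passed to the reconstruction.
#' @param roi optional \code{RoiGeometry}; default \code{\link{defaultRoi}}.
#' @return A data.frame with one row per (filter, realization): columns
#'   \code{filter_dim}, \code{realization}, \code{cnr}, \code{bias_mean},
#'   \code{bias_median}, \code{bias_iqr}, \code{n_lesion_px}.
#' @export
evaluateExperiment <- function(fields, filterSpecs, mode = "image2d",
                               phantom, cfg = NULL, roi = NULL) {
  empty <- data.frame(filter_dim = integer(), realization = integer(),
                      cnr = numeric(), bias_mean = numeric(),
                      bias_median = numeric(), bias_iqr = numeric(),
                      n_lesion_px = integer())
  if (!length(filterSpecs) || !length(fields)) return(empty)
  g <- fieldGrid(fields[[1]])
  for (f in fields)
    if (!identical(gridDims(fieldGrid(f)), gridDims(g)))
      stop("realizations must share a common grid")
  trueSpeed <- shearWaveSpeed(phantom@lesion)
  if (is.null(cfg))
    cfg <- if (max(g@spacing) >= 0.3 - 1e-9) patchConfig(4, 8) else patchConfig(6, 10)
  if (is.null(roi)) roi <- defaultRoi(phantom, cfg, max(g@spacing[c(1, 3)]))
  # precompute filters once per spec
  filts <- lapply(filterSpecs, function(sp) {
    if (is.null(sp)) return(NULL)
    gg <- if (sp@dimensionality == 4L) g else fieldGrid(imagingPlane(fields[[1]]))
    buildFilter(sp, gg)
  })
  rows <- list()
  for (ri in seq_along(fields)) {
    for (si in seq_along(filterSpecs)) {
      sp <- filterSpecs[[si]]
      fld <- if (is.null(sp)) {
        if (mode == "image2d") imagingPlane(fields[[ri]]) else fields[[ri]]
      } else {
        applyFilter(fields[[ri]], sp, filts[[si]])
      }
      map <- reconstructSWS(fld, mode, cfg = cfg)
      b <- percentBias(map, roi, trueSpeed)
      rows[[length(rows) + 1]] <- data.frame(
        filter_dim = if (is.null(sp)) 0L else sp@dimensionality,
        realization = ri,
        cnr = cnr(map, roi),
        bias_mean = mean(b),
        bias_median = stats::median(b),
        bias_iqr = stats::IQR(b),
        n_lesion_px = length(b))
    }
  }
  do.call(rbind, rows)
}
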