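# Pipeline commands tying the modules into reproducible end-to-end runs.
# Each command wraps the package functions, reads/writes the directory
# container, and logs per-stage summaries. The thin shell front-end in
# inst/cli/swei4d dispatches to these.

#' Simulate displacement fields from a run configuration
#'
#' Generates one noisy \code{DisplacementField} per noise seed of the
#' configuration and writes each to a container under \code{outDir}
#' (\code{field_seed<k>}). Logs the expected shear wave speeds of the
#' phantom materials.
#'
#' @param config a parsed configuration from \code{\link{readRunConfig}}, or
#'   a path to one.
#' @param outDir output directory.
#' @param quiet suppress log messages.
#' @return Character vector of container paths, invisibly.
#' @export
cmdSimulate <- function(config, outDir, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ph <- config$phantom
  if (!quiet)
    message(sprintf("expected SWS: background %.3f m/s, lesion %.3f m/s",
                    shearWaveSpeed(ph@background), shearWaveSpeed(ph@lesion)))
  base <- simulateDisplacements(ph, config$excitation, config$grid)
  paths <- character()
  for (s in config$noise$seeds) {
    f <- if (is.finite(config$noise$snr_db))
      addAWGN(base, config$noise$snr_db, seed = s) else base
    p <- file.path(outDir, sprintf("field_seed%d", s))
    writeDisplacementField(f, p)
    if (!quiet)
      message(sprintf("wrote %s (peak %.3g um, energy %.4g)", p,
                      max(abs(fieldData(f))), fieldEnergy(f)))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Directionally filter a stored displacement field
#'
#' @param inPath input container (from \code{\link{cmdSimulate}}).
#' @param spec a \code{FilterSpec}.
#' @param outPath output container.
#' @param quiet suppress log messages.
#' @return \code{outPath}, invisibly.
#' @export
cmdFilter <- function(inPath, spec, outPath, quiet = FALSE) {
  field <- readDisplacementField(inPath)
  out <- applyFilter(field, spec)
  if (!quiet)
    message(sprintf("%d-D filter: energy %.4g -> %.4g",
                    spec@dimensionality, fieldEnergy(imagingPlane(field)),
                    fieldEnergy(imagingPlane(out))))
  writeDisplacementField(out, outPath)
  invisible(outPath)
}

#' Reconstruct a speed map from a stored displacement field
#'
#' Upsamples to the working PRF and runs \code{\link{reconstructSWS}}.
#'
#' @param inPath input container.
#' @param mode \code{"image2d"} or \code{"volume3d"}.
#' @param outPath output container.
#' @param cfg optional \code{PatchConfig}.
#' @param medianMM optional median filter size (mm).
#' @param quiet suppress log messages.
#' @return \code{outPath}, invisibly.
#' @export
cmdReconstruct <- function(inPath, mode, outPath, cfg = NULL, medianMM = NULL,
                           quiet = FALSE) {
  mode <- match.arg(mode, c("image2d", "volume3d"))
  field <- readDisplacementField(inPath)
  map <- reconstructSWS(field, mode, cfg = cfg, medianMM = medianMM)
  if (!quiet) {
    v <- mapSpeeds(map)[mapValid(map)]
    message(sprintf("reconstructed %s: median %.3f m/s over %d valid px",
                    mode, stats::median(v), length(v)))
  }
  writeSWSMap(map, outPath)
  invisible(outPath)
}

#' Evaluate stored speed maps against a phantom
#'
#' Computes CNR and within-lesion percent-bias summaries for each stored
#' map and writes a CSV report (columns: \code{phantom_E_kpa},
#' \code{true_sws}, \code{filter_dim}, \code{estimator},
#' \code{realization_seed}, \code{cnr}, \code{bias_mean}, \code{bias_median},
#' \code{bias_iqr}).
#'
#' @param mapPaths character vector of map container paths.
#' @param phantom the \code{PhantomSpec} the fields were simulated in.
#' @param outCsv output CSV path.
#' @param filterDims integer vector parallel to \code{mapPaths} (0 = none).
#' @param seeds integer vector parallel to \code{mapPaths}.
#' @param estimator label (\code{"image2d"} or \code{"volume3d"}).
#' @param roi optional \code{RoiGeometry}.
#' @return The report data.frame, invisibly.
#' @export
cmdEvaluate <- function(mapPaths, phantom, outCsv,
                        filterDims = rep(0L, length(mapPaths)),
                        seeds = seq_along(mapPaths) - 1L,
                        estimator = "image2d", roi = NULL) {
  trueSpeed <- shearWaveSpeed(phantom@lesion)
  rows <- list()
  for (i in seq_along(mapPaths)) {
    map <- readSWSMap(mapPaths[i])
    if (is.null(roi))
      roi <- defaultRoi(phantom, spacing = max(map@spacing))
    b <- percentBias(map, roi, trueSpeed)
    rows[[i]] <- data.frame(
      phantom_E_kpa = phantom@lesion@E,
      true_sws = trueSpeed,
      filter_dim = filterDims[i],
      estimator = estimator,
      realization_seed = seeds[i],
      cnr = cnr(map, roi),
      bias_mean = mean(b),
      bias_median = stats::median(b),
      bias_iqr = stats::IQR(b))
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phantom_E_kpa = numeric(), true_sws = numeric(),
               filter_dim = integer(), estimator = character(),
               realization_seed = integer(), cnr = numeric(),
               bias_mean = numeric(), bias_median = numeric(),
               bias_iqr = numeric())
  utils::write.csv(report, outCsv, row.names = FALSE)
  invisible(report)
}

#' Run the lesion filter-comparison study
#'
#' Simulates a spherical-lesion phantom with a reference excitation on the
#' desk grid, generates seeded white-noise realizations at the stated SNR,
#' and evaluates every filter configuration with 2-D SWS reconstruction:
#' the experiment behind the CNR-versus-filter-dimensionality and
#' within-lesion-bias comparisons.
#'
#' @param lesionE lesion Young's modulus (kPa).
#' @param seeds integer vector of noise seeds (one realization each).
#' @param snrDb noise level (dB).
#' @param excitation an \code{ExcitationSpec}.
#' @param grid a \code{GridSpec}.
#' @param cfg a \code{PatchConfig}; the desk default keeps the reference
#'   configuration's physical kernel sizes (0.6 mm patch, 1.0 mm window).
#' @param filterSpecs list of filter configurations
#'   (default \code{\link{standardFilterSet}}).
#' @param mode estimator mode.
#' @return The \code{\link{evaluateExperiment}} data.frame.
#' @export
lesionFilterStudy <- function(lesionE, seeds = 0:9, snrDb = 25,
                              excitation = tableExcitation(1),
                              grid = deskGrid(), cfg = patchConfig(3, 5),
                              filterSpecs = standardFilterSet(),
                              mode = "image2d") {
  ph <- lesionPhantom(lesionE)
  base <- simulateDisplacements(ph, excitation, grid)
  fields <- lapply(seeds, function(s) addAWGN(base, snrDb, seed = s))
  evaluateExperiment(fields, filterSpecs, mode, ph, cfg = cfg)
}

#' Desk-scale study grid
#'
#' Reduced-extent grid for desk-scale runs of the lesion experiments:
#' x in [0, 10] mm, y in [-3, 3] mm, z in [14, 28] mm at 0.2 mm spacing,
#' 10 kHz PRF, 12 ms. Covers the 5 mm lesion at (5, 0, 21) mm, the 4 mm
#' lesion ROI and the background ROIs above and below it.
#'
#' @return A \code{GridSpec}.
#' @export
deskGrid <- function() {
  gridSpec(xlim = c(0, 10), ylim = c(-3, 3), zlim = c(14, 28),
           spacing = 0.2, prf = 10, duration = 12)
}

#' Full-scale study grid
#'
#' The full simulation extents (20 x 10 x 40 mm mesh reflected across y = 0,
#' truncated to 1--31 mm depth) at 0.1 mm spacing, 10 kHz, 12 ms. Large:
#' intended for offline runs, not tests.
#'
#' @return A \code{GridSpec}.
#' @export
paperScaleGrid <- function() {
  gridSpec(xlim = c(0, 20), ylim = c(-5, 5), zlim = c(1, 31),
           spacing = 0.1, prf = 10, duration = 12)
}

#' The four standard filter configurations
#'
#' \code{NULL} (no filtering) plus 2-D, 3-D and 4-D directional filters at
#' q = 2, boundary value 0.5, +x propagation.
#'
#' @return List of \code{NULL} and three \code{FilterSpec} objects, named
#'   \code{none}, \code{dim2}, \code{dim3}, \code{dim4}.
#' @export
standardFilterSet <- function() {
  list(none = NULL, dim2 = filterSpec(2), dim3 = filterSpec(3),
       dim4 = filterSpec(4))
}
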