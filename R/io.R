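# Hierarchical array-container I/O and run configuration.
#
# A container is a directory with attrs.json (grid metadata + provenance,
# jsonlite) and one raw little-endian float64 payload per dataset
# (displacement.bin or sws.bin), column-major in the array's storage order.
# Round-trips are exact.

.writeArrayBin <- function(arr, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(arr), con, size = 8, endian = "little")
}

.readArrayBin <- function(path, dims) {
  con <- file(path, "rb")
  on.exit(close(con))
  array(readBin(con, "double", n = prod(dims), size = 8, endian = "little"),
        dims)
}

#' Write / read a displacement field container
#'
#' Serializes a \code{DisplacementField} to a directory container: a
#' \code{displacement} dataset (raw float64, (x, y, z, t) column-major) plus
#' JSON attributes \code{dx_mm}, \code{dy_mm}, \code{dz_mm}, \code{prf_khz},
#' \code{origin_mm}, \code{dims} and \code{provenance}. The round trip
#' preserves data and metadata exactly.
#'
#' @param field a \code{DisplacementField}.
#' @param path container directory (created, overwriting any previous
#'   contents of the two files).
#' @return \code{writeDisplacementField}: \code{path}, invisibly;
#'   \code{readDisplacementField}: the \code{DisplacementField}.
#' @export
writeDisplacementField <- function(field, path) {
  stopifnot(is(field, "DisplacementField"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- fieldGrid(field)
  attrs <- list(dataset = "displacement",
                dims = dim(fieldData(field)),
                dx_mm = g@spacing[1], dy_mm = g@spacing[2],
                dz_mm = g@spacing[3],
                prf_khz = g@prf, duration_ms = g@duration,
                origin_mm = unname(g@extents[, 1]),
                extent_max_mm = unname(g@extents[, 2]),
                provenance = fieldProvenance(field))
  jsonlite::write_json(attrs, file.path(path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeArrayBin(fieldData(field), file.path(path, "displacement.bin"))
  invisible(path)
}

#' @rdname writeDisplacementField
#' @export
readDisplacementField <- function(path) {
  attrs <- jsonlite::read_json(file.path(path, "attrs.json"),
                               simplifyVector = TRUE)
  g <- gridSpec(xlim = c(attrs$origin_mm[1], attrs$extent_max_mm[1]),
                ylim = c(attrs$origin_mm[2], attrs$extent_max_mm[2]),
                zlim = c(attrs$origin_mm[3], attrs$extent_max_mm[3]),
                spacing = c(attrs$dx_mm, attrs$dy_mm, attrs$dz_mm),
                prf = attrs$prf_khz, duration = attrs$duration_ms)
  u <- .readArrayBin(file.path(path, "displacement.bin"), attrs$dims)
  prov <- attrs$provenance
  if (is.null(prov)) prov <- list()
  displacementField(u, g, as.list(prov))
}

#' Write / read a speed-map container
#'
#' Same container layout as the displacement container, with an \code{sws}
#' dataset, a \code{valid} mask dataset, and the map's axes as attributes.
#'
#' @param map an \code{SWSMap}.
#' @param path container directory.
#' @return \code{writeSWSMap}: \code{path}, invisibly; \code{readSWSMap}:
#'   the \code{SWSMap}.
#' @export
writeSWSMap <- function(map, path) {
  stopifnot(is(map, "SWSMap"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  attrs <- list(dataset = "sws",
                dims = dim(mapSpeeds(map)),
                axes = mapAxes(map),
                spacing_mm = map@spacing,
                units = "m/s")
  jsonlite::write_json(attrs, file.path(path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeArrayBin(mapSpeeds(map), file.path(path, "sws.bin"))
  .writeArrayBin(mapValid(map) * 1, file.path(path, "valid.bin"))
  invisible(path)
}

#' @rdname writeSWSMap
#' @export
readSWSMap <- function(path) {
  attrs <- jsonlite::read_json(file.path(path, "attrs.json"),
                               simplifyVector = TRUE)
  dims <- attrs$dims
  sp <- .readArrayBin(file.path(path, "sws.bin"), dims)
  va <- .readArrayBin(file.path(path, "valid.bin"), dims) > 0
  new("SWSMap", speeds = sp, valid = va,
      axes = lapply(attrs$axes, as.numeric),
      spacing = as.numeric(attrs$spacing_mm))
}

.configMaterial <- function(cf) {
  materialSpec(E = cf$E, rho = if (is.null(cf$rho)) 1 else cf$rho,
               nu = if (is.null(cf$nu)) 0.495 else cf$nu)
}

#' Read and validate a run configuration
#'
#' Parses a YAML (or JSON) run configuration into validated S4 objects. The
#' configuration mirrors the generator's parameter names: \code{phantom}
#' (background/lesion E, rho, nu; lesion_center; lesion_radius),
#' \code{excitation} (A, center or z0, sigma_x/sigma_y/sigma_z, t_on),
#' \code{grid} (xlim/ylim/zlim, spacing, prf_khz, duration_ms),
#' \code{noise} (snr_db, seeds), \code{filters} (list of dim/u/q/
#' boundary_value), \code{estimator} (p, w, working_prf_khz, median_mm,
#' mode). All invariants are checked before any compute.
#'
#' @param path configuration file path.
#' @return A named list with validated components \code{phantom},
#'   \code{excitation}, \code{grid}, \code{filters} (list of
#'   \code{FilterSpec} or NULL), \code{cfg} (\code{PatchConfig}),
#'   \code{noise} (list), \code{mode}, \code{median_mm}.
#' @export
readRunConfig <- function(path) {
  cf <- yaml::read_yaml(path)
  ph <- phantomSpec(.configMaterial(cf$phantom$background),
                    .configMaterial(cf$phantom$lesion),
                    lesionCenter = if (is.null(cf$phantom$lesion_center))
                      c(5, 0, 21) else unlist(cf$phantom$lesion_center),
                    lesionRadius = if (is.null(cf$phantom$lesion_radius))
                      2.5 else cf$phantom$lesion_radius)
  ec <- cf$excitation
  center <- if (!is.null(ec$center)) unlist(ec$center)
    else c(0, 0, if (is.null(ec$z0)) 21 else ec$z0)
  exc <- excitationSpec(A = if (is.null(ec$A)) 10 else ec$A,
                        center = center,
                        sigma = c(ec$sigma_x, ec$sigma_y, ec$sigma_z),
                        tOn = if (is.null(ec$t_on)) 0.08 else ec$t_on)
  gc <- cf$grid
  grid <- gridSpec(xlim = unlist(gc$xlim), ylim = unlist(gc$ylim),
                   zlim = unlist(gc$zlim),
                   spacing = if (is.null(gc$spacing)) 0.2 else gc$spacing,
                   prf = if (is.null(gc$prf_khz)) 10 else gc$prf_khz,
                   duration = if (is.null(gc$duration_ms)) 12 else gc$duration_ms)
  filters <- lapply(cf$filters, function(fs) {
    if (is.null(fs) || identical(fs$dim, 0L) || identical(fs$dim, 0)) return(NULL)
    filterSpec(fs$dim,
               u = if (is.null(fs$u)) NULL else unlist(fs$u),
               q = if (is.null(fs$q)) 2 else fs$q,
               boundaryValue = if (is.null(fs$boundary_value)) 0.5
                 else fs$boundary_value)
  })
  es <- cf$estimator
  cfg <- patchConfig(p = if (is.null(es$p)) 6 else es$p,
                     w = if (is.null(es$w)) 10 else es$w,
                     prf = if (is.null(es$working_prf_khz)) 50
                       else es$working_prf_khz)
  validObject(ph); validObject(exc); validObject(grid); validObject(cfg)
  list(phantom = ph, excitation = exc, grid = grid, filters = filters,
       cfg = cfg,
       noise = list(snr_db = if (is.null(cf$noise$snr_db)) 25
                      else cf$noise$snr_db,
                    seeds = if (is.null(cf$noise$seeds)) 0:9
                      else as.integer(unlist(cf$noise$seeds))),
       mode = if (is.null(es$mode)) "image2d" else es$mode,
       median_mm = es$median_mm)
}
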