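# Fourier-domain directional filters.
#
# Waves are separated by propagation direction in the discrete Fourier
# domain. Under R's fft sign convention (negative-exponent kernel on every
# axis) a pulse traveling toward +x occupies the (k_x, omega) quadrants of
# opposite sign; the quadrant filter passes those and rejects the rest. The
# 3-D/4-D filters multiply the quadrant filter with a one-sided cos^q
# angular weighting of the spatial-frequency direction, mirrored across
# omega so that the full filter is symmetric under simultaneous negation of
# all frequency axes (the condition for real-valued filtered output).

# Unshifted discrete frequency axis, numpy-fftfreq layout.
.fftfreq <- function(n, d = 1) {
  half <- ceiling(n / 2) - 1
  neg <- if (n - half - 1 > 0) -(n - half - 1):-1 else integer(0)
  c(0:half, neg) / (n * d)
}

# Indices of zero-frequency and (for even n) Nyquist bins: the bins whose
# sign is ambiguous under negation and which therefore carry the boundary
# weight.
.boundaryBins <- function(n) {
  b <- 1L
  if (n %% 2 == 0) b <- c(b, n %/% 2 + 1L)
  b
}

# Index permutation implementing k -> -k on the unshifted grid.
.negIndex <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))

#' Quadrant filter in (k_x, omega)
#'
#' Binary mask over the 2-D discrete Fourier grid that passes waves
#' traveling toward +x (weight 1), rejects the opposite direction (weight 0),
#' and takes \code{boundaryValue} on the quadrant boundaries: the k_x = 0 and
#' omega = 0 lines (plus Nyquist lines on even-length axes, whose sign is
#' ambiguous). The soft boundary avoids ringing from sharp filter edges.
#'
#' @param kxAxis,omegaAxis unshifted frequency axes (from the grid sizes);
#'   must include zero frequency.
#' @param boundaryValue weight on the boundary lines (default 0.5).
#' @return A \code{FilterArray} with 2-D weights (k_x by omega).
#' @export
quadrantFilter <- function(kxAxis, omegaAxis, boundaryValue = 0.5) {
  if (!any(kxAxis == 0) || !any(omegaAxis == 0))
    stop("frequency axes must include zero frequency")
  nx <- length(kxAxis); nt <- length(omegaAxis)
  W <- (outer(sign(kxAxis), sign(omegaAxis)) == -1) * 1
  W[.boundaryBins(nx), ] <- boundaryValue
  W[, .boundaryBins(nt)] <- boundaryValue
  new("FilterArray", weights = W, axes = list(kx = kxAxis, omega = omegaAxis))
}

#' Angular cos^q filter over spatial frequencies
#'
#' One-sided angular weighting of the spatial-frequency direction: at each
#' point k of the 2-D or 3-D spatial-frequency grid the weight is
#' \code{cos(theta)^q} with \code{cos(theta) = (u . k) / |k|}, clamped to 0
#' where the cosine is negative (a backward direction must not pass), and 1
#' at k = 0 where the direction is undefined. \code{\link{buildFilter}}
#' mirrors this one-sided lobe across omega when composing the full filter.
#'
#' @param kAxes list of 2 or 3 unshifted spatial-frequency axes.
#' @param u unit propagation direction, same length as \code{kAxes}.
#' @param q cosine exponent (>= 0).
#' @return A \code{FilterArray} over the spatial-frequency grid.
#' @export
angularFilter <- function(kAxes, u, q = 2) {
  nd <- length(kAxes)
  stopifnot(nd %in% 2:3, length(u) == nd)
  un <- sqrt(sum(u^2))
  if (un < 1e-12) stop("u must have nonzero length")
  u <- u / un
  dims <- vapply(kAxes, length, integer(1))
  dot <- array(0, dims)
  k2 <- array(0, dims)
  for (i in seq_len(nd)) {
    shape <- rep(1L, nd); shape[i] <- dims[i]
    ki <- array(rep(kAxes[[i]], each = prod(dims[seq_len(i - 1)])),
                dims)
    dot <- dot + u[i] * ki
    k2 <- k2 + ki^2
  }
  kn <- sqrt(k2)
  cosT <- ifelse(kn > 0, dot / kn, 1)
  W <- pmax(cosT, 0)^q
  W[kn == 0] <- 1
  names(kAxes) <- paste0("k", c("x", "y", "z")[seq_len(nd)])[seq_len(nd)]
  new("FilterArray", weights = W, axes = kAxes)
}

#' Filter array accessors
#'
#' @param filt a \code{FilterArray}.
#' @return \code{filterWeights}: the weights array; \code{filterAxes}: the
#'   frequency axes list.
#' @export
filterWeights <- function(filt) {
  stopifnot(is(filt, "FilterArray"))
  filt@weights
}

#' @rdname filterWeights
#' @export
filterAxes <- function(filt) {
  stopifnot(is(filt, "FilterArray"))
  filt@axes
}

#' Build a directional filter for a field grid
#'
#' Composes the full directional filter on the discrete Fourier grid of the
#' slab it will be applied to:
#' \itemize{
#'   \item 2-D: the quadrant filter over (k_x, omega);
#'   \item 3-D: angular cos^q filter over (k_x, k_z) times the quadrant
#'     filter, on the y = 0 slab's (k_x, k_z, omega) grid;
#'   \item 4-D: angular filter over (k_x, k_y, k_z) times the quadrant
#'     filter, on the full (k_x, k_y, k_z, omega) grid.
#' }
#' The one-sided angular lobe is evaluated on the omega < 0 half-space
#' (where +x waves carry k_x > 0 under the fft sign convention), mirrored to
#' omega > 0, and symmetrized (\code{max(a(k), a(-k))}) on the omega = 0 and
#' Nyquist planes, so the result is exactly symmetric under simultaneous
#' negation of all frequency axes and filtered output is real.
#'
#' @param spec a \code{FilterSpec}.
#' @param grid the \code{GridSpec} of the field the filter applies to.
#' @return A \code{FilterArray} whose weights match the transform shape of
#'   the processed slab.
#' @export
buildFilter <- function(spec, grid) {
  validObject(spec); validObject(grid)
  d <- gridDims(grid)
  sp <- grid@spacing
  kx <- .fftfreq(d[1], sp[1])
  om <- .fftfreq(d[4], 1 / grid@prf)
  Q <- filterWeights(quadrantFilter(kx, om, spec@boundaryValue))
  if (spec@dimensionality == 2L)
    return(quadrantFilter(kx, om, spec@boundaryValue))
  if (spec@dimensionality == 3L) {
    kz <- .fftfreq(d[3], sp[3])
    A <- filterWeights(angularFilter(list(kx, kz), spec@u, spec@q))
    An <- A[.negIndex(d[1]), .negIndex(d[3]), drop = FALSE]
    Amax <- pmax(A, An)
    W <- array(0, c(d[1], d[3], d[4]))
    bt <- .boundaryBins(d[4])
    for (it in seq_len(d[4])) {
      S <- if (it %in% bt) Amax else if (om[it] < 0) A else An
      W[, , it] <- S * Q[, it]
    }
    return(new("FilterArray", weights = W,
               axes = list(kx = kx, kz = kz, omega = om)))
  }
  ky <- .fftfreq(d[2], sp[2])
  kz <- .fftfreq(d[3], sp[3])
  A <- filterWeights(angularFilter(list(kx, ky, kz), spec@u, spec@q))
  An <- A[.negIndex(d[1]), .negIndex(d[2]), .negIndex(d[3]), drop = FALSE]
  Amax <- pmax(A, An)
  W <- array(0, c(d[1], d[2], d[3], d[4]))
  bt <- .boundaryBins(d[4])
  for (it in seq_len(d[4])) {
    S <- if (it %in% bt) Amax else if (om[it] < 0) A else An
    W[, , , it] <- S * Q[, it]
  }
  new("FilterArray", weights = W,
      axes = list(kx = kx, ky = ky, kz = kz, omega = om))
}

# N-D filtering core: forward fft, multiply, inverse, real part.
.filterArrayND <- function(arr, W) {
  out <- fft(fft(arr) * W, inverse = TRUE) / length(arr)
  Re(out)
}

#' Apply a directional filter to a displacement field
#'
#' Forward discrete Fourier transform of the processed slab, elementwise
#' multiplication by the filter of \code{\link{buildFilter}}, inverse
#' transform, real part. The processed slab depends on the filter
#' dimensionality: 2-D filters process each depth's (x, t) plane of the
#' y = 0 imaging plane independently; 3-D filters process the y = 0
#' (x, z, t) slab in one transform; 4-D filters process the full
#' (x, y, z, t) volume.
#'
#' @param field a \code{DisplacementField} (finite values).
#' @param spec a \code{FilterSpec}.
#' @param filt optional precomputed \code{FilterArray} from
#'   \code{\link{buildFilter}} (must match the processed slab's grid).
#' @return A \code{DisplacementField}: the full volume for 4-D filtering,
#'   the y = 0 plane (y dimension of length 1) for 2-D and 3-D filtering.
#' @export
applyFilter <- function(field, spec, filt = NULL) {
  stopifnot(is(field, "DisplacementField"))
  validObject(spec)
  if (anyNA(fieldData(field)))
    stop("field contains non-finite values")
  dim4 <- spec@dimensionality == 4L
  slab <- if (dim4) field else imagingPlane(field)
  g <- fieldGrid(slab)
  if (is.null(filt)) filt <- buildFilter(spec, g)
  W <- filterWeights(filt)
  u <- fieldData(slab)
  d <- dim(u)
  out <- if (spec@dimensionality == 2L) {
    stopifnot(all(dim(W) == d[c(1, 4)]))
    o <- u
    for (iz in seq_len(d[3]))
      o[, 1, iz, ] <- .filterArrayND(u[, 1, iz, ], W)
    o
  } else if (spec@dimensionality == 3L) {
    stopifnot(all(dim(W) == d[c(1, 3, 4)]))
    array(.filterArrayND(array(u, d[c(1, 3, 4)]), W), d)
  } else {
    stopifnot(all(dim(W) == d))
    .filterArrayND(u, W)
  }
  displacementField(out, g,
                    c(fieldProvenance(slab),
                      list(filtered = sprintf("%d-D directional", spec@dimensionality))))
}
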