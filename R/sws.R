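# Time-of-flight shear wave speed reconstruction: per-axis patch velocities
# from cross-correlation lags, correlation/distance-weighted component
# fusion, component combination, and median post-filtering.

# Slice an array along one axis at given indices (time stays last).
.sliceAxis <- function(arr, axis, idx) {
  nd <- length(dim(arr))
  args <- rep(list(quote(expr = )), nd)
  args[[axis]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

#' Per-axis patch velocity estimates
#'
#' For every pixel whose p-pixel patch fits in the slab, cross-correlates the
#' two displacement traces p pixels apart straddling the pixel along
#' \code{axis} (offsets -floor(p/2) and +ceiling(p/2)) and converts the lag
#' to a signed velocity component \code{V = p * dx / dt} (m/s). Estimates are
#' invalid where the correlation peak sits on the boundary, a trace is
#' constant, or \code{|dt|} is below one sample at the working PRF (the
#' velocity would be unbounded).
#'
#' @param slab numeric array with time as the last dimension (3-D (x, z, t)
#'   for 2-D imaging, 4-D (x, y, z, t) for volumetric imaging).
#' @param axis spatial axis index along which to estimate (1-based).
#' @param p patch separation in pixels.
#' @param dx pixel pitch along \code{axis} (mm).
#' @param prf sampling rate of the slab (kHz).
#' @param chunk number of trace pairs per FFT batch.
#' @return List of arrays over the slab's spatial dimensions: \code{V}
#'   (signed m/s, NA where invalid), \code{CC} (peak correlation), and
#'   \code{valid}.
#' @export
patchVelocity <- function(slab, axis, p, dx, prf, chunk = 4096L) {
  d <- dim(slab)
  nd <- length(d)
  nt <- d[nd]
  stopifnot(axis >= 1, axis < nd)
  n <- d[axis]
  om <- floor(p / 2)
  op <- p - om
  sdim <- d[-nd]
  V <- array(NA_real_, sdim)
  CC <- array(0, sdim)
  valid <- array(FALSE, sdim)
  lo <- 1L + om
  hi <- n - op
  if (hi < lo) stop("slab too small for the requested patch along this axis")
  centers <- lo:hi
  Asl <- .sliceAxis(slab, axis, centers - om)
  Bsl <- .sliceAxis(slab, axis, centers + op)
  # matricize: traces as columns
  dA <- dim(Asl)
  mA <- matrix(aperm(Asl, c(nd, seq_len(nd - 1))), nrow = nt)
  mB <- matrix(aperm(Bsl, c(nd, seq_len(nd - 1))), nrow = nt)
  m <- ncol(mA)
  lag <- numeric(m); cc <- numeric(m); ok <- logical(m)
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    r <- .nccBatch(mA[, s:e, drop = FALSE], mB[, s:e, drop = FALSE])
    lag[s:e] <- r$lag; cc[s:e] <- r$cc; ok[s:e] <- r$valid
  }
  dt <- lag / prf                       # ms
  ok <- ok & abs(lag) >= 1              # at least one sample of lag
  v <- ifelse(ok, p * dx / dt, NA_real_)
  # scatter back into full-size spatial arrays
  sub <- array(v, dA[-nd])
  subCC <- array(cc, dA[-nd])
  subOK <- array(ok, dA[-nd])
  ia <- lapply(sdim, seq_len)
  ia[[axis]] <- centers
  V <- do.call(`[<-`, c(list(V), ia, list(sub)))
  CC <- do.call(`[<-`, c(list(CC), ia, list(subCC)))
  valid <- do.call(`[<-`, c(list(valid), ia, list(subOK)))
  valid[is.na(V)] <- FALSE
  list(V = V, CC = CC, valid = valid)
}

# Shift a 2-D/3-D array by integer offsets, zero/FALSE fill.
.shiftArray <- function(arr, off, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (i in seq_along(d)) {
    o <- off[i]
    if (o >= 0) { src[[i]] <- seq_len(d[i] - o); dst[[i]] <- src[[i]] + o }
    else { src[[i]] <- seq_len(d[i] + o) - o; dst[[i]] <- seq_len(d[i] + o) }
    if (length(src[[i]]) == 0) return(out)
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(arr), src,
                                                       list(drop = FALSE))))))
}

# Correlation/distance-weighted neighbourhood mean of signed velocity
# estimates: weights CC^2 / r with r = 1 at the centre and the Euclidean
# pixel distance elsewhere, over the (w - p + 1)^nd window. Invalid
# estimates get weight 0; pixels whose window leaves the array are masked.
.fuseComponents <- function(V, CC, valid, p, w) {
  h <- (w - p) / 2
  d <- dim(V)
  nd <- length(d)
  Vz <- ifelse(valid, V, 0)
  Wt <- ifelse(valid, CC^2, 0)
  num <- array(0, d)
  den <- array(0, d)
  offs <- as.matrix(expand.grid(rep(list(-h:h), nd)))
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    r <- sqrt(sum(o^2))
    if (r == 0) r <- 1
    num <- num + .shiftArray(Vz * Wt, -o) / r
    den <- den + .shiftArray(Wt, -o) / r
  }
  ok <- den > 0
  out <- ifelse(ok, num / pmax(den, .Machine$double.eps), NA_real_)
  # edge policy: windows that leave the array are excluded
  if (h > 0) {
    for (i in seq_len(nd)) {
      edge <- c(seq_len(h), d[i] - seq_len(h) + 1L)
      ok <- do.call(`[<-`, c(list(ok), lapply(seq_len(nd), function(j)
        if (j == i) edge else seq_len(d[j])), list(FALSE)))
    }
    out[!ok] <- NA_real_
  }
  list(V = out, valid = ok)
}

#' Fuse per-axis velocity component maps
#'
#' Weighted neighbourhood mean of the signed component estimates over the
#' (w - p + 1)-pixel window per axis, with weights \code{CC^2 / r}: the
#' squared peak correlation coefficient over the Euclidean pixel distance to
#' the window centre (r = 1 at the centre). Invalid estimates get weight 0;
#' pixels whose window leaves the map are masked out.
#'
#' @param comp a component list from \code{\link{patchVelocity}} (fields
#'   \code{V}, \code{CC}, \code{valid}; 2-D arrays for
#'   \code{fuseComponents2D}, 3-D for \code{fuseComponents3D}).
#' @param p,w patch separation and window size (pixels).
#' @return List with the fused \code{V} and its \code{valid} mask.
#' @export
fuseComponents2D <- function(comp, p, w) {
  stopifnot(length(dim(comp$V)) == 2)
  .fuseComponents(comp$V, comp$CC, comp$valid, p, w)
}

#' @rdname fuseComponents2D
#' @export
fuseComponents3D <- function(comp, p, w) {
  stopifnot(length(dim(comp$V)) == 3)
  .fuseComponents(comp$V, comp$CC, comp$valid, p, w)
}

# Combine fused signed components into a speed via reciprocal quadrature:
# 1/V^2 = sum_i 1/V_i^2. Invalid components drop out (their reciprocal is 0,
# the unbounded-velocity limit); all-invalid pixels are invalid.
.combineComponents <- function(comps) {
  d <- dim(comps[[1]]$V)
  s2 <- array(0, d)
  anyValid <- array(FALSE, d)
  sgn <- array(1, d)
  for (c in comps) {
    ok <- c$valid & is.finite(c$V) & c$V != 0
    r <- ifelse(ok, 1 / c$V, 0)
    s2 <- s2 + r^2
    sgn <- sgn * ifelse(ok, sign(c$V), 1)
    anyValid <- anyValid | c$valid
  }
  ok <- anyValid & s2 > 0
  V <- ifelse(ok, sgn / sqrt(s2), NA_real_)
  list(V = V, valid = ok)
}

#' Combine fused velocity components into a speed map
#'
#' 2-D: \code{V = Vx Vz / sqrt(Vx^2 + Vz^2)}; 3-D:
#' \code{V = Vx Vy Vz / sqrt(Vx^2 Vy^2 + Vx^2 Vz^2 + Vy^2 Vz^2)} — both
#' equivalent to reciprocal quadrature of the components, which is how they
#' are evaluated so that an invalid (unbounded) component reduces smoothly to
#' the lower-dimensional formula. Signs are retained (product of component
#' signs); magnitude is taken at final map rendering.
#'
#' @param vx,vy,vz fused component lists (fields \code{V}, \code{valid}).
#' @return List with signed \code{V} and \code{valid}.
#' @export
combine2D <- function(vx, vz) .combineComponents(list(vx, vz))

#' @rdname combine2D
#' @export
combine3D <- function(vx, vy, vz) .combineComponents(list(vx, vy, vz))

# Median filter with an odd pixel kernel per axis; invalid pixels are
# excluded from neighbourhoods and stay invalid.
.medianFilterND <- function(V, valid, kernel) {
  d <- dim(V)
  nd <- length(d)
  offs <- as.matrix(expand.grid(lapply(kernel, function(k) -(k %/% 2):(k %/% 2))))
  stack <- matrix(NA_real_, length(V), nrow(offs))
  Vna <- ifelse(valid, V, NA_real_)
  for (i in seq_len(nrow(offs)))
    stack[, i] <- as.vector(.shiftArray(Vna, -offs[i, ], fill = NA_real_))
  out <- apply(stack, 1, stats::median, na.rm = TRUE)
  out[!valid] <- NA_real_
  out[is.nan(out)] <- NA_real_
  array(out, d)
}

.oddKernel <- function(mm, dx) {
  k <- ceiling(mm / dx - 1e-9)
  k + (1 - k %% 2)
}

#' Reconstruct a shear wave speed image or volume
#'
#' Full time-of-flight reconstruction pipeline: upsample the field in slow
#' time to the working PRF (spline), estimate per-axis patch velocities by
#' normalized cross-correlation with parabolic subsample lags, fuse each
#' component over the correlation/distance-weighted window, combine the
#' components, apply a median filter of the stated physical size (converted
#' to an odd pixel kernel), and return speed magnitudes with a validity mask.
#' \code{image2d} reconstructs the y = 0 plane from the (x, z) components;
#' \code{volume3d} reconstructs the full volume from (x, y, z) components.
#'
#' @param field a \code{DisplacementField} (filtered or raw).
#' @param mode \code{"image2d"} or \code{"volume3d"}.
#' @param cfg a \code{PatchConfig}; default \code{patchConfig(6, 10)} for
#'   spacing < 0.3 mm and \code{patchConfig(4, 8)} for coarser sampling.
#' @param medianMM median filter size (mm); default 0.5 for fine sampling,
#'   1.5 for spacing >= 0.3 mm.
#' @return An \code{SWSMap}.
#' @export
reconstructSWS <- function(field, mode = c("image2d", "volume3d"), cfg = NULL,
                           medianMM = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(field, "DisplacementField"))
  if (mode == "image2d") field <- imagingPlane(field)
  g <- fieldGrid(field)
  coarse <- max(g@spacing) >= 0.3 - 1e-9
  if (is.null(cfg)) cfg <- if (coarse) patchConfig(4, 8) else patchConfig(6, 10)
  if (is.null(medianMM)) medianMM <- if (coarse) 1.5 else 0.5
  if (g@prf < cfg@prf) field <- upsampleTime(field, cfg@prf)
  g <- fieldGrid(field)
  ax <- gridAxes(g)
  u <- fieldData(field)
  p <- cfg@p; w <- cfg@w
  if (mode == "image2d") {
    slab <- array(fieldData(imagingPlane(field)),
                  dim(fieldData(imagingPlane(field)))[c(1, 3, 4)])
    if (dim(slab)[1] <= w || dim(slab)[2] <= w)
      stop("field too small for the fusion window")
    vx <- fuseComponents2D(patchVelocity(slab, 1, p, g@spacing[1], g@prf), p, w)
    vz <- fuseComponents2D(patchVelocity(slab, 2, p, g@spacing[3], g@prf), p, w)
    cmb <- combine2D(vx, vz)
    kern <- .oddKernel(medianMM, g@spacing[c(1, 3)])
    # magnitude at map rendering, then the median filter on the speed image
    # (signed estimates cancel across symmetry planes; the median must not)
    Vf <- .medianFilterND(abs(cmb$V), cmb$valid, kern)
    valid <- cmb$valid & !is.na(Vf)
    sp <- Vf; sp[!valid] <- 0
    new("SWSMap", speeds = sp, valid = valid,
        axes = list(x = ax$x, z = ax$z), spacing = g@spacing[c(1, 3)])
  } else {
    d <- dim(u)
    if (any(d[1:3] <= w))
      stop("field too small for the fusion window")
    vx <- fuseComponents3D(patchVelocity(u, 1, p, g@spacing[1], g@prf), p, w)
    vy <- fuseComponents3D(patchVelocity(u, 2, p, g@spacing[2], g@prf), p, w)
    vz <- fuseComponents3D(patchVelocity(u, 3, p, g@spacing[3], g@prf), p, w)
    cmb <- combine3D(vx, vy, vz)
    kern <- .oddKernel(medianMM, g@spacing[1:3])
    Vf <- .medianFilterND(abs(cmb$V), cmb$valid, kern)
    valid <- cmb$valid & !is.na(Vf)
    sp <- Vf; sp[!valid] <- 0
    new("SWSMap", speeds = sp, valid = valid,
        axes = list(x = ax$x, y = ax$y, z = ax$z), spacing = g@spacing)
  }
}
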