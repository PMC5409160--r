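# Noise injection and temporal/spatial resampling.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Adds zero-mean Gaussian noise scaled so that the ratio of signal power to
#' noise power over the whole 4-D volume equals \code{snrDb} decibels
#' (power SNR, \code{10 * log10(P_signal / P_noise)}). Reproducible for a
#' fixed seed; the caller's RNG state is untouched.
#'
#' @param field a nonzero \code{DisplacementField}.
#' @param snrDb target signal-to-noise ratio in dB; \code{Inf} returns the
#'   input unchanged.
#' @param seed integer RNG seed.
#' @return A \code{DisplacementField} with noise added.
#' @export
addAWGN <- function(field, snrDb = 25, seed = 0L) {
  stopifnot(is(field, "DisplacementField"))
  if (is.infinite(snrDb) && snrDb > 0) return(field)
  if (!is.finite(snrDb)) stop("snrDb must be finite (or +Inf for no noise)")
  u <- fieldData(field)
  psig <- mean(u^2)
  if (psig == 0) stop("SNR undefined for an all-zero field")
  sigma <- sqrt(psig / 10^(snrDb / 10))
  noise <- .withSeed(seed, stats::rnorm(length(u), sd = sigma))
  displacementField(u + array(noise, dim(u)), fieldGrid(field),
                    c(fieldProvenance(field),
                      list(snr_db = snrDb, noise_seed = as.integer(seed))))
}

# Natural cubic spline interpolation of every column of Y (nt x m) from tOld
# to tNew, solved for all columns at once by a Thomas tridiagonal sweep.
# Matches stats::spline(method = "natural") per column.
.splineColumns <- function(Y, tOld, tNew) {
  n <- length(tOld)
  stopifnot(nrow(Y) == n, n >= 3)
  h <- diff(tOld)
  m <- ncol(Y)
  # second derivatives M[2..n-1]; M[1] = M[n] = 0
  rhs <- 6 * (sweep(Y[-(1:2), , drop = FALSE] - Y[-c(1, n), , drop = FALSE],
                    1, h[-1], `/`) -
              sweep(Y[-c(1, n), , drop = FALSE] - Y[-((n - 1):n), , drop = FALSE],
                    1, h[-(n - 1)], `/`))
  ni <- n - 2
  dia <- 2 * (h[-(n - 1)] + h[-1])
  low <- h[2:(n - 2)]
  # forward sweep (scalar coefficients, matrix RHS)
  cp <- numeric(ni)
  if (ni > 1) {
    cp[1] <- low[1] / dia[1]
    rhs[1, ] <- rhs[1, ] / dia[1]
    for (i in 2:ni) {
      denom <- dia[i] - low[i - 1] * cp[i - 1]
      if (i < ni) cp[i] <- low[i] / denom
      rhs[i, ] <- (rhs[i, ] - low[i - 1] * rhs[i - 1, ]) / denom
    }
    for (i in (ni - 1):1)
      rhs[i, ] <- rhs[i, ] - cp[i] * rhs[i + 1, ]
  } else {
    rhs[1, ] <- rhs[1, ] / dia[1]
  }
  M <- rbind(0, rhs, 0)
  # evaluate
  idx <- findInterval(tNew, tOld, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > n - 1] <- n - 1
  hi <- h[idx]
  dA <- (tOld[idx + 1] - tNew) / hi
  dB <- (tNew - tOld[idx]) / hi
  cA <- (dA^3 - dA) * hi^2 / 6
  cB <- (dB^3 - dB) * hi^2 / 6
  dA * Y[idx, , drop = FALSE] + dB * Y[idx + 1, , drop = FALSE] +
    cA * M[idx, , drop = FALSE] + cB * M[idx + 1, , drop = FALSE]
}

#' Upsample a field in slow time by cubic spline interpolation
#'
#' Resamples every voxel's displacement-through-time trace to a higher PRF
#' with a natural cubic spline. Values at the original sample instants are
#' preserved. Used to refine temporal resolution (10 kHz acquisition to a
#' 50 kHz working rate) before time-of-flight lag estimation.
#'
#' @param field a \code{DisplacementField}.
#' @param newPRF target sampling rate in kHz; must be >= the field's PRF.
#' @return A \code{DisplacementField} sampled at \code{newPRF}.
#' @export
upsampleTime <- function(field, newPRF = 50) {
  stopifnot(is(field, "DisplacementField"))
  g <- fieldGrid(field)
  if (newPRF < g@prf - 1e-12)
    stop("newPRF must be >= the current PRF (use decimation elsewhere)")
  if (abs(newPRF - g@prf) < 1e-12) return(field)
  ax <- gridAxes(g)
  tNew <- seq(0, max(ax$t), by = 1 / newPRF)
  u <- fieldData(field)
  d <- dim(u)
  Y <- matrix(aperm(u, c(4, 1, 2, 3)), nrow = d[4])
  Yn <- .splineColumns(Y, ax$t, tNew)
  un <- aperm(array(Yn, c(length(tNew), d[1], d[2], d[3])), c(2, 3, 4, 1))
  g2 <- gridSpec(xlim = g@extents[1, ], ylim = g@extents[2, ],
                 zlim = g@extents[3, ], spacing = g@spacing, prf = newPRF,
                 duration = max(tNew))
  displacementField(un, g2, c(fieldProvenance(field),
                              list(upsampled_prf_khz = newPRF)))
}

# Linear interpolation of `arr` along `axis` from oldAx onto newAx.
.resampleAxis <- function(arr, axis, oldAx, newAx) {
  idx <- findInterval(newAx, oldAx, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > length(oldAx) - 1] <- length(oldAx) - 1
  w <- (newAx - oldAx[idx]) / (oldAx[idx + 1] - oldAx[idx])
  w <- pmin(pmax(w, 0), 1)
  d <- dim(arr)
  perm <- c(axis, seq_along(d)[-axis])
  A <- matrix(aperm(arr, perm), nrow = d[axis])
  B <- A[idx, , drop = FALSE] * (1 - w) + A[idx + 1, , drop = FALSE] * w
  dNew <- d; dNew[axis] <- length(newAx)
  aperm(array(B, c(length(newAx), d[-axis])), order(perm))
}

#' Decimate a field to coarser isotropic spatial sampling
#'
#' Resamples the spatial axes to the requested isotropic spacing: plain
#' subsampling when \code{newSpacing} is an integer multiple of the current
#' spacing, linear interpolation otherwise. Emulates the sparser spatial
#' sampling of matrix-array acquisitions (e.g. 0.3 mm isotropic).
#'
#' @param field a \code{DisplacementField}.
#' @param newSpacing target isotropic spacing (mm); must be >= the current
#'   maximum spacing.
#' @return A \code{DisplacementField} on the coarser grid.
#' @export
decimateSpatial <- function(field, newSpacing) {
  stopifnot(is(field, "DisplacementField"))
  g <- fieldGrid(field)
  if (newSpacing < max(g@spacing) - 1e-12)
    stop("newSpacing must be >= the current spacing")
  if (all(abs(g@spacing - newSpacing) < 1e-12)) return(field)
  ax <- gridAxes(g)
  u <- fieldData(field)
  newAx <- list()
  for (i in 1:3) {
    old <- ax[[i]]
    if (length(old) == 1L) { newAx[[i]] <- old; next }
    ratio <- newSpacing / g@spacing[i]
    if (abs(ratio - round(ratio)) < 1e-9) {
      keep <- seq(1, length(old), by = round(ratio))
      newAx[[i]] <- old[keep]
      u <- switch(i,
                  u[keep, , , , drop = FALSE],
                  u[, keep, , , drop = FALSE],
                  u[, , keep, , drop = FALSE])
    } else {
      nn <- old[1] + (0:floor((old[length(old)] - old[1]) / newSpacing)) * newSpacing
      if (length(nn) < 2) nn <- old[c(1, length(old))]
      newAx[[i]] <- nn
      u <- .resampleAxis(u, i, old, nn)
    }
  }
  g2 <- gridSpec(xlim = range(newAx[[1]]), ylim = range(newAx[[2]]),
                 zlim = range(newAx[[3]]),
                 spacing = ifelse(vapply(newAx, length, 1L) > 1, newSpacing,
                                  g@spacing),
                 prf = g@prf, duration = g@duration)
  displacementField(u, g2, c(fieldProvenance(field),
                             list(decimated_mm = newSpacing)))
}
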