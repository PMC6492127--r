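## Calibration: FLASH phase time series + respiratory trace -> per-slice
## coupling coefficients (Hz per bellows unit).
##
## Pipeline: unwrapPhaseTemporal -> phaseToField -> averageFieldInMask ->
## detectOutlierFrames -> fitTraceCoupling; calibrateField() chains them.

#' Temporal phase unwrapping
#'
#' Unwraps the phase of every voxel over time (cumulative
#' nearest-multiple-of-2pi correction): after unwrapping, frame-to-frame
#' jumps are at most pi in magnitude and frame 1 is unchanged. No spatial
#' unwrapping is performed.
#'
#' @param series a \linkS4class{PhaseSeries}
#' @return the series with unwrapped phase and \code{unwrapped = TRUE}
#' @export
unwrapPhaseTemporal <- function(series) {
  stopifnot(is(series, "PhaseSeries"))
  ph <- series@phase
  nt <- dim(ph)[3L]
  if (nt < 2L) {
    .bfWarn("single-frame series: temporal unwrapping is a no-op")
    series@unwrapped <- TRUE
    return(series)
  }
  out <- ph
  for (t in 2:nt) {
    d <- .wrapDiff(ph[, , t] - ph[, , t - 1L])
    out[, , t] <- out[, , t - 1L] + d
  }
  series@phase <- out
  series@unwrapped <- TRUE
  series
}

#' Convert an unwrapped phase series to a field-offset series
#'
#' Per voxel, the time-averaged phase is subtracted and the deviation is
#' divided by 2*pi*TE, yielding a frequency offset in Hz with zero temporal
#' mean by construction:
#' \deqn{f_0(r,t) = (\phi(r,t) - \bar\phi(r)) / (2\pi\,TE).}
#'
#' @param series an unwrapped \linkS4class{PhaseSeries}
#' @return numeric array [nz, nx, nt] of field offsets (Hz)
#' @export
phaseToField <- function(series) {
  stopifnot(is(series, "PhaseSeries"))
  if (series@te <= 0) .bfStop("bf_parameter_error", "TE must be > 0")
  if (!isTRUE(series@unwrapped))
    .bfStop("bf_parameter_error", "phaseToField requires a temporally unwrapped series")
  ph <- series@phase
  meanPh <- apply(ph, c(1, 2), mean)
  sweep(ph, c(1, 2), meanPh, `-`) / (2 * pi * series@te)
}

#' Average a field series over the in-mask voxels of each axial plane
#'
#' For each slice row z, the field is averaged over the in-mask voxels of
#' that transverse plane, yielding a z-by-time profile. Slices whose mask is
#' empty are dropped with a warning and recorded in the result.
#'
#' @param fieldSeries numeric array [nz, nx, nt] from \code{\link{phaseToField}}
#' @param mask logical matrix [nz, nx] (cord mask on the sagittal grid)
#' @param zMm slice positions, mm
#' @param frameTimes frame times, seconds
#' @return a \linkS4class{FieldProfileSeries}
#' @export
averageFieldInMask <- function(fieldSeries, mask, zMm, frameTimes) {
  d <- dim(fieldSeries)
  stopifnot(length(d) == 3L, identical(dim(mask), d[1:2]), length(zMm) == d[1L])
  keep <- which(rowSums(mask) > 0)
  dropped <- setdiff(seq_len(d[1L]), keep)
  if (length(dropped))
    .bfWarn(sprintf("dropping %d slice(s) with empty mask: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (!length(keep))
    .bfStop("bf_insufficient_data_error", "mask is empty in every slice")
  f0 <- matrix(0, length(keep), d[3L])
  for (i in seq_along(keep)) {
    z <- keep[i]
    cols <- which(mask[z, ])
    sl <- matrix(fieldSeries[z, , ], nrow = d[2L], ncol = d[3L])
    f0[i, ] <- colMeans(sl[cols, , drop = FALSE])
  }
  new("FieldProfileSeries", zMm = zMm[keep], f0 = f0,
      frameTimes = frameTimes, dropped = as.integer(dropped))
}

#' Interpolate a respiratory trace at given times
#'
#' Linear interpolation; beyond the trace support the edge samples are held
#' constant, with a warning.
#'
#' @param trace a \linkS4class{RespTrace}
#' @param times evaluation times, seconds
#' @export
traceAtTimes <- function(trace, times) {
  stopifnot(is(trace, "RespTrace"))
  rng <- range(trace@time)
  if (any(times < rng[1] | times > rng[2]))
    .bfWarn("requested times outside trace support; holding edge values")
  stats::approx(trace@time, trace@value, xout = times, rule = 2)$y
}

#' Flag field-profile frames inconsistent with the linear trace model
#'
#' Two-pass scheme automating the exclusion of swallowing-affected time
#' points: a provisional per-slice least-squares coupling is fitted, and any
#' frame whose residual exceeds \code{k} times the MAD of that slice's
#' residuals in at least one slice is flagged.
#'
#' @param profile a \linkS4class{FieldProfileSeries}
#' @param traceAtFrames trace values resampled at the profile frame times
#' @param k MAD multiplier (default 4)
#' @return integer frame indices (possibly empty)
#' @export
detectOutlierFrames <- function(profile, traceAtFrames, k = 4) {
  stopifnot(is(profile, "FieldProfileSeries"))
  nt <- ncol(profile@f0)
  if (nt < 20L)
    .bfStop("bf_insufficient_data_error", "outlier detection needs at least 20 frames")
  if (length(traceAtFrames) != nt)
    .bfStop("bf_consistency_error", "traceAtFrames must match the number of frames")
  R <- traceAtFrames
  denom <- sum(R^2)
  if (denom == 0) return(integer())
  flagged <- logical(nt)
  for (z in seq_len(nrow(profile@f0))) {
    f <- profile@f0[z, ]
    cHat <- sum(R * f) / denom
    res <- f - R * cHat
    s <- stats::mad(res)
    if (s == 0) s <- sqrt(mean(res^2))
    if (s == 0) next
    flagged <- flagged | (abs(res) > k * s)
  }
  which(flagged)
}

#' Fit the per-slice trace-to-field coupling
#'
#' Least-squares fit of the linear model \eqn{f_0(z,t) = R(t)\,c(z)} (no
#' intercept; both sides are mean-removed upstream) over the non-excluded
#' frames inside a window from the start of the record. The solution is the
#' scalar normal-equation closed form per slice,
#' \eqn{c(z) = \sum_t R(t) f_0(z,t) / \sum_t R(t)^2}.
#'
#' @param profile a \linkS4class{FieldProfileSeries}
#' @param traceAtFrames trace values resampled at the profile frame times
#' @param windowS fit window in seconds from the start of the record
#'   (default 30)
#' @param excluded integer frame indices to exclude from the fit
#' @param minFrames minimum number of retained frames (default 10)
#' @return a \linkS4class{FieldCalibration}
#' @export
fitTraceCoupling <- function(profile, traceAtFrames, windowS = 30,
                             excluded = integer(), minFrames = 10L) {
  stopifnot(is(profile, "FieldProfileSeries"))
  nt <- ncol(profile@f0)
  if (length(traceAtFrames) != nt)
    .bfStop("bf_consistency_error", "traceAtFrames must match the number of frames")
  t0 <- profile@frameTimes[1L]
  inWin <- which(profile@frameTimes - t0 <= windowS)
  use <- setdiff(inWin, excluded)
  if (!length(use)) .bfStop("bf_fit_error", "all frames excluded from the fit")
  if (length(use) < minFrames)
    .bfStop("bf_fit_error",
            sprintf("only %d frames retained; need at least %d", length(use), minFrames))
  R <- traceAtFrames[use]
  denom <- sum(R^2)
  if (denom == 0 || stats::sd(R) == 0)
    .bfStop("bf_fit_error", "zero-variance trace: coupling fit is degenerate")
  nz <- nrow(profile@f0)
  coupling <- numeric(nz)
  residRms <- numeric(nz)
  for (z in seq_len(nz)) {
    f <- profile@f0[z, use]
    coupling[z] <- sum(R * f) / denom
    residRms[z] <- sqrt(mean((f - R * coupling[z])^2))
  }
  new("FieldCalibration", zMm = profile@zMm, coupling = coupling,
      residualRms = residRms, fitWindow = windowS,
      excludedFrames = as.integer(excluded), nFramesUsed = length(use))
}

#' End-to-end calibration from a FLASH phase series
#'
#' Chains temporal unwrapping, phase-to-field conversion, in-mask averaging,
#' trace resampling to the frame times, automatic outlier-frame rejection
#' (two-pass: provisional fit, flag, refit) and the windowed least-squares
#' coupling fit.
#'
#' @param series a \linkS4class{PhaseSeries} (wrapped phase is fine)
#' @param mask logical [nz, nx] cord mask on the sagittal grid
#' @param trace a synced \linkS4class{RespTrace}
#' @param windowS fit window, seconds (default 30)
#' @param outlierK MAD multiplier for outlier rejection; NA disables
#' @param minFrames minimum retained frames for the fit
#' @return a \linkS4class{FieldCalibration}
#' @export
calibrateField <- function(series, mask, trace, windowS = 30, outlierK = 4,
                           minFrames = 10L) {
  stopifnot(is(series, "PhaseSeries"), is(trace, "RespTrace"))
  if (!isTRUE(trace@synced))
    .bfWarn("calibrating against an unsynced trace; consider syncTrace() first")
  series <- unwrapPhaseTemporal(series)
  field <- phaseToField(series)
  profile <- averageFieldInMask(field, mask, series@zMm, series@frameTimes)
  R <- traceAtTimes(trace, profile@frameTimes)
  # The measured field has zero temporal mean by construction (the
  # time-averaged phase is subtracted), so the trace is re-centered over the
  # same calibration record; otherwise a constant residual biases the
  # no-intercept fit and the outlier test.
  R <- R - mean(R)
  excluded <- integer()
  if (is.finite(outlierK) && ncol(profile@f0) >= 20L)
    excluded <- detectOutlierFrames(profile, R, k = outlierK)
  fitTraceCoupling(profile, R, windowS = windowS, excluded = excluded,
                   minFrames = minFrames)
}
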