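## Correction: predict the breathing field during an imaging scan from the
## respiratory trace and demodulate the k-space data.
##
## The field is treated as constant over each readout train. The evaluation
## time per excitation is sequence-dependent (see fieldEventTimes): for
## multi-echo GRE the field is evaluated once per TR at the excitation; for
## interleaved EPI at excitation time + TE (the echo-train center).

#' Synchronize a respiratory trace with the sequence clock
#'
#' Rebases the time axis so that t = 0 at the chosen sequence trigger and
#' removes the per-scan mean of the bellows value (slow baseline drifts
#' between scans are absorbed by the mean removal).
#'
#' @param traceFile a raw \linkS4class{RespTrace} with trigger marks
#' @param scanStartTriggerIndex which trigger marks the scan start (default 1)
#' @return a synced \linkS4class{RespTrace}
#' @export
syncTrace <- function(traceFile, scanStartTriggerIndex = 1L) {
  stopifnot(is(traceFile, "RespTrace"))
  trig <- which(traceFile@trigger)
  if (!length(trig))
    .bfStop("bf_sync_error", "trace has no trigger marks; cannot synchronize")
  if (scanStartTriggerIndex < 1L || scanStartTriggerIndex > length(trig))
    .bfStop("bf_sync_error",
            sprintf("trigger index %d out of range (trace has %d triggers)",
                    scanStartTriggerIndex, length(trig)))
  i0 <- trig[scanStartTriggerIndex]
  new("RespTrace",
      time = traceFile@time - traceFile@time[i0],
      value = traceFile@value - mean(traceFile@value),
      trigger = traceFile@trigger, synced = TRUE)
}

#' Field evaluation times per excitation of an acquisition
#'
#' Returns, per unique excitation in the container, the time at which the
#' (readout-static) field is evaluated: the excitation time for single-line
#' multi-echo GRE/FLASH, excitation time + TE for EPI echo trains.
#'
#' @param set a \linkS4class{KSpaceData}
#' @return list with \code{exc} (sorted unique excitation ids) and
#'   \code{times} (seconds)
#' @export
fieldEventTimes <- function(set) {
  stopifnot(is(set, "KSpaceData"))
  ln <- set@lines
  exc <- sort(unique(ln$exc))
  tExc <- ln$tExc[match(exc, ln$exc)]
  type <- set@meta$type
  offset <- if (identical(type, "EPI4")) set@meta$teMs[1L] / 1000 else 0
  list(exc = exc, times = tExc + offset)
}

#' Predict the breathing field from a calibration and a trace
#'
#' \eqn{\hat f_0(z, e) = R(t_e)\, c(z)}: the synced trace is linearly
#' interpolated at the event times (edge-held beyond support, with a
#' warning) and scaled by the per-slice coupling. Slices absent from the
#' calibration take the nearest calibrated slice along z, with a warning
#' (linear extrapolation is deliberately avoided: the coupling profile is
#' nonlinear near the thorax).
#'
#' @param calib a \linkS4class{FieldCalibration}
#' @param trace a synced \linkS4class{RespTrace}
#' @param eventTimes field evaluation times, seconds
#' @param sliceZMm z positions (mm) of the slices to predict for
#' @return a \linkS4class{PredictedField}
#' @export
predictField <- function(calib, trace, eventTimes, sliceZMm) {
  stopifnot(is(calib, "FieldCalibration"), is(trace, "RespTrace"))
  R <- traceAtTimes(trace, eventTimes)
  idx <- vapply(sliceZMm, function(z) which.min(abs(calib@zMm - z)), integer(1))
  if (any(abs(calib@zMm[idx] - sliceZMm) > 1e-6))
    .bfWarn("some slices absent from the calibration; using nearest-slice coupling")
  f0Hat <- outer(calib@coupling[idx], R)
  new("PredictedField", f0Hat = f0Hat, eventTimes = as.numeric(eventTimes),
      zMm = as.numeric(sliceZMm))
}

#' Phase offset accrued by a field offset over the readout time
#'
#' \eqn{\Delta\hat\phi_0 = 2\pi\, \hat f_0\, t_{RO}} (radians). Vectorized
#' over both arguments.
#'
#' @param f0Hat field offset, Hz
#' @param tRo time since the last RF excitation, seconds (>= 0)
#' @export
phaseOffset <- function(f0Hat, tRo) {
  if (any(tRo < 0)) .bfStop("bf_parameter_error", "tRo must be >= 0")
  2 * pi * f0Hat * tRo
}

#' Demodulate k-space data with a predicted field
#'
#' Multiplies every sample of line l, slice z by
#' \eqn{\exp(-i\,2\pi \hat f_0(z, e(l))\, t_{RO}(l))}. Magnitudes are
#' preserved exactly. The predicted field must cover every (slice,
#' excitation) pair present in the container.
#'
#' @param set a \linkS4class{KSpaceData}
#' @param field a \linkS4class{PredictedField} whose columns follow the
#'   sorted unique excitation ids of \code{set} (as built by
#'   \code{\link{predictField}} on \code{\link{fieldEventTimes}} output)
#' @return the demodulated \linkS4class{KSpaceData}
#' @export
demodulate <- function(set, field) {
  stopifnot(is(set, "KSpaceData"), is(field, "PredictedField"))
  ln <- set@lines
  exc <- sort(unique(ln$exc))
  if (ncol(field@f0Hat) != length(exc))
    .bfStop("bf_coverage_error",
            "predicted field does not cover every excitation in the container")
  nSlice <- dim(set@data)[4L]
  if (nrow(field@f0Hat) != nSlice)
    .bfStop("bf_coverage_error",
            "predicted field does not cover every slice in the container")
  excCol <- match(ln$exc, exc)
  if (anyNA(excCol))
    .bfStop("bf_coverage_error", "line with excitation id missing from field")
  out <- set@data
  for (z in seq_len(nSlice)) {
    ph <- .phaseSign * 2 * pi * field@f0Hat[z, excCol] * ln$tRo
    mod <- exp(-1i * ph)
    # multiply every readout sample of line l (and every coil) by mod[l]
    out[, , , z] <- out[, , , z, drop = FALSE] *
      rep(mod, each = dim(set@data)[1L])
  }
  set@data <- out
  set@meta$demodulated <- TRUE
  set
}

#' Predict and demodulate in one step
#'
#' Convenience wrapper: computes the field evaluation times of the
#' acquisition, predicts the field from the calibration and trace, and
#' demodulates. Optionally dumps the predicted field as a CSV
#' (slice, event_time, f0_hat) for audit.
#'
#' @param set a \linkS4class{KSpaceData}
#' @param calib a \linkS4class{FieldCalibration}
#' @param trace a synced \linkS4class{RespTrace}
#' @param fieldDumpCsv optional path for the predicted-field audit CSV
#' @return the demodulated \linkS4class{KSpaceData}
#' @export
correctAcquisition <- function(set, calib, trace, fieldDumpCsv = NULL) {
  ev <- fieldEventTimes(set)
  zs <- set@meta$zMm
  if (is.null(zs)) .bfStop("bf_configuration_error", "container meta lacks zMm")
  field <- predictField(calib, trace, ev$times, zs)
  if (!is.null(fieldDumpCsv)) {
    df <- expand.grid(slice = seq_along(zs), event = seq_along(ev$times))
    df$event_time <- ev$times[df$event]
    df$f0_hat <- field@f0Hat[cbind(df$slice, df$event)]
    utils::write.csv(df[, c("slice", "event_time", "f0_hat")], fieldDumpCsv,
                     row.names = FALSE)
  }
  demodulate(set, field)
}

#' Remodulate (inverse of demodulate)
#'
#' Applies the phase with the opposite sign; \code{remodulate(demodulate(s,
#' f), f)} recovers \code{s} to machine precision.
#'
#' @inheritParams demodulate
#' @export
remodulate <- function(set, field) {
  neg <- field
  neg@f0Hat <- -field@f0Hat
  out <- demodulate(set, neg)
  out@meta$demodulated <- set@meta$demodulated %||% FALSE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
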