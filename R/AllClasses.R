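## Central S4 containers. Accessors live in accessors.R; operations on these
## objects live in the module files (io.R, calibration.R, correction.R,
## reconstruction.R, simulation.R, analysis.R).

#' RespTrace: a sampled respiratory bellows signal
#'
#' Holds the bellows samples with an explicit time base (the bellows sampling
#' rate is not assumed), optional sequence trigger marks, and a flag saying
#' whether the trace has been synchronized to the sequence clock (time rebased
#' to a trigger, per-scan mean removed).
#'
#' @slot time numeric, seconds, strictly increasing
#' @slot value numeric, bellows units (mean-removed once synced)
#' @slot trigger logical, TRUE at samples carrying a sequence trigger mark
#' @slot synced logical(1)
#' @export
setClass("RespTrace", representation(
  time = "numeric", value = "numeric", trigger = "logical", synced = "logical"
))

setValidity("RespTrace", function(object) {
  n <- length(object@time)
  if (n < 2L) return("trace must contain at least 2 samples")
  if (length(object@value) != n || length(object@trigger) != n)
    return("time, value and trigger must have equal length")
  if (any(!is.finite(object@time)) || any(!is.finite(object@value)))
    return("time and value must be finite")
  if (any(diff(object@time) <= 0)) return("time must be strictly increasing")
  if (length(object@synced) != 1L) return("synced must be logical(1)")
  if (isTRUE(object@synced)) {
    rms <- sqrt(mean(object@value^2))
    if (rms > 0 && abs(mean(object@value)) > 1e-9 * rms)
      return("synced trace must have (numerically) zero mean value")
  }
  TRUE
})

#' PhaseSeries: complex single-slice image time series (FLASH calibration)
#'
#' Magnitude/phase arrays of a sagittal slice over time; rows index axial
#' z positions (row 1 = most superior), columns the in-plane direction.
#'
#' @slot magnitude numeric array [nz, nx, nt]
#' @slot phase numeric array [nz, nx, nt], radians
#' @slot te numeric(1), echo time in seconds
#' @slot frameTimes numeric(nt), seconds, strictly increasing
#' @slot zMm numeric(nz), slice positions (mm, increasing inferiorly)
#' @slot unwrapped logical(1), TRUE after temporal unwrapping
#' @export
setClass("PhaseSeries", representation(
  magnitude = "array", phase = "array", te = "numeric",
  frameTimes = "numeric", zMm = "numeric", unwrapped = "logical"
))

setValidity("PhaseSeries", function(object) {
  dp <- dim(object@phase)
  if (length(dp) != 3L) return("phase must be a 3-d array [nz, nx, nt]")
  if (!identical(dim(object@magnitude), dp))
    return("magnitude and phase dimensions must match")
  if (any(!is.finite(object@phase))) return("phase must be finite")
  if (length(object@te) != 1L || object@te <= 0) return("TE must be a single value > 0")
  if (length(object@frameTimes) != dp[3L])
    return("frameTimes length must equal the number of frames")
  if (dp[3L] >= 2L && any(diff(object@frameTimes) <= 0))
    return("frameTimes must be strictly increasing")
  if (length(object@zMm) != dp[1L]) return("zMm length must equal nz")
  TRUE
})

#' FieldProfileSeries: measured field offsets along z over time
#'
#' @slot zMm numeric(nz)
#' @slot f0 numeric matrix [nz, nt], field offset in Hz
#' @slot frameTimes numeric(nt), seconds
#' @slot dropped integer, indices of slices dropped for empty masks
#' @export
setClass("FieldProfileSeries", representation(
  zMm = "numeric", f0 = "matrix", frameTimes = "numeric", dropped = "integer"
))

setValidity("FieldProfileSeries", function(object) {
  if (nrow(object@f0) != length(object@zMm)) return("f0 must have one row per slice")
  if (ncol(object@f0) != length(object@frameTimes))
    return("f0 must have one column per frame")
  if (any(!is.finite(object@f0))) return("f0 must be finite")
  TRUE
})

#' FieldCalibration: per-slice trace-to-field coupling coefficients
#'
#' The result of the calibration fit: for each axial slice z the coupling
#' coefficient converting bellows units into a field offset in Hz, together
#' with fit diagnostics.
#'
#' @slot zMm numeric(nz)
#' @slot coupling numeric(nz), Hz per bellows unit
#' @slot residualRms numeric(nz), Hz
#' @slot fitWindow numeric(1), seconds of calibration data used
#' @slot excludedFrames integer, frame indices excluded from the fit
#' @slot nFramesUsed integer(1)
#' @export
setClass("FieldCalibration", representation(
  zMm = "numeric", coupling = "numeric", residualRms = "numeric",
  fitWindow = "numeric", excludedFrames = "integer", nFramesUsed = "integer"
))

setValidity("FieldCalibration", function(object) {
  nz <- length(object@zMm)
  if (length(object@coupling) != nz) return("coupling must have one entry per slice")
  if (length(object@residualRms) != nz) return("residualRms must have one entry per slice")
  if (any(!is.finite(object@coupling))) return("coupling must be finite")
  if (any(object@residualRms < 0)) return("residualRms must be >= 0")
  TRUE
})

#' KSpaceData: multi-coil Cartesian k-space with per-line timing
#'
#' One acquired phase-encode line per record: \code{data[, l, c, s]} holds the
#' complex readout samples of line \code{l} for coil \code{c} and slice
#' \code{s}; \code{lines} annotates every line with its 0-based phase-encode
#' index \code{kIndex}, excitation id \code{exc} (1-based), echo, shot,
#' excitation time \code{tExc} (s since scan start), readout time \code{tRo}
#' (s since the last RF excitation, at the line's echo center), absolute
#' sample time \code{tAbs = tExc + tRo}, and readout polarity (+1/-1 for
#' EPI odd/even train lines).
#'
#' @slot data complex array [nKx, nLine, nCoil, nSlice]
#' @slot lines data.frame with columns kIndex, exc, shot, echo, tExc, tRo,
#'   tAbs, polarity
#' @slot meta list sequence descriptor: type, teMs (strictly increasing),
#'   trMs, matrix c(nKx, nKy), fovMm, shots, senseFactor, zMm, plus flags
#'   (refCorrected, demodulated)
#' @export
setClass("KSpaceData", representation(
  data = "array", lines = "data.frame", meta = "list"
))

.requiredLineCols <- c("kIndex", "exc", "shot", "echo", "tExc", "tRo", "tAbs", "polarity")

setValidity("KSpaceData", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be [nKx, nLine, nCoil, nSlice]")
  if (!is.complex(object@data)) return("data must be complex")
  miss <- setdiff(.requiredLineCols, names(object@lines))
  if (length(miss)) return(paste("lines is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@lines) != d[2L])
    return("lines must have one row per k-space line in data")
  if (any(!is.finite(object@lines$tAbs))) return("every sample needs finite tAbs")
  if (any(object@lines$tRo < 0)) return("tRo must be >= 0")
  m <- object@meta
  if (is.null(m$matrix) || length(m$matrix) != 2L)
    return("meta$matrix must give c(nKx, nKy)")
  if (d[1L] != m$matrix[1L]) return("data readout length must match meta$matrix[1]")
  if (any(object@lines$kIndex < 0L | object@lines$kIndex >= m$matrix[2L]))
    return("kIndex out of matrix bounds")
  if (!is.null(m$teMs) && length(m$teMs) > 1L && any(diff(m$teMs) <= 0))
    return("meta TE list must be strictly increasing")
  if (!is.null(m$zMm) && length(m$zMm) != d[4L])
    return("meta$zMm must have one entry per slice")
  TRUE
})

#' PredictedField: trace-predicted field offset per (slice, excitation)
#'
#' @slot f0Hat numeric matrix [nSlice, nExc], Hz
#' @slot eventTimes numeric(nExc), seconds (field evaluation times)
#' @slot zMm numeric(nSlice)
#' @export
setClass("PredictedField", representation(
  f0Hat = "matrix", eventTimes = "numeric", zMm = "numeric"
))

setValidity("PredictedField", function(object) {
  if (any(!is.finite(object@f0Hat))) return("f0Hat must be finite")
  if (ncol(object@f0Hat) != length(object@eventTimes))
    return("f0Hat needs one column per excitation event")
  if (nrow(object@f0Hat) != length(object@zMm))
    return("f0Hat needs one row per slice")
  TRUE
})

#' PhantomSpec: digital cervical-cord phantom
#'
#' Proton-density, T2* and cord-mask volumes on the reconstruction grid.
#' Slice 1 is the most superior; zMm increases inferiorly.
#'
#' @slot pd numeric array [nx, ny, nz], arbitrary proton-density units
#' @slot t2sMs numeric array [nx, ny, nz], T2* in ms (> 0 inside the object)
#' @slot cordMask logical array [nx, ny, nz]
#' @slot zMm numeric(nz)
#' @slot voxelMm numeric(3)
#' @export
setClass("PhantomSpec", representation(
  pd = "array", t2sMs = "array", cordMask = "array",
  zMm = "numeric", voxelMm = "numeric"
))

setValidity("PhantomSpec", function(object) {
  d <- dim(object@pd)
  if (length(d) != 3L) return("pd must be [nx, ny, nz]")
  if (!identical(dim(object@t2sMs), d) || !identical(dim(object@cordMask), d))
    return("pd, t2sMs and cordMask dimensions must match")
  obj <- object@pd > 0
  if (any(object@t2sMs[obj] <= 0)) return("T2* must be > 0 inside the object")
  if (any(object@cordMask & !obj)) return("cord mask must lie inside the object support")
  if (length(object@zMm) != d[3L]) return("zMm must have one entry per slice")
  TRUE
})

#' CoilSensitivities: complex receive sensitivity maps
#'
#' @slot sens complex array [nx, ny, nCoil]
#' @slot support logical matrix [nx, ny]; RSS over coils must be > 0 inside
#' @export
setClass("CoilSensitivities", representation(sens = "array", support = "matrix"))

setValidity("CoilSensitivities", function(object) {
  d <- dim(object@sens)
  if (length(d) != 3L) return("sens must be [nx, ny, nCoil]")
  if (any(!is.finite(Mod(object@sens)))) return("sensitivities must be finite")
  if (!identical(dim(object@support), d[1:2])) return("support must match the image grid")
  rss <- sqrt(apply(Mod(object@sens)^2, c(1, 2), sum))
  if (any(rss[object@support] <= 0)) return("RSS over coils must be > 0 inside support")
  TRUE
})

#' ImageVolume: reconstructed images
#'
#' @slot data complex or numeric array [nx, ny, nSlice, nEcho]
#' @slot voxelMm numeric(3)
#' @slot teMs numeric(nEcho) echo annotation (may be NA for combined images)
#' @slot info list of reconstruction diagnostics (iterations, residuals, ...)
#' @export
setClass("ImageVolume", representation(
  data = "array", voxelMm = "numeric", teMs = "numeric", info = "list"
))

setValidity("ImageVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be [nx, ny, nSlice, nEcho]")
  if (any(!is.finite(Mod(object@data)))) return("image values must be finite")
  if (length(object@teMs) != d[4L]) return("teMs must have one entry per echo")
  TRUE
})

#' T2StarMap: voxel-wise monoexponential fit results
#'
#' @slot t2sMs numeric array [nx, ny, nSlice], ms; NA where invalid
#' @slot s0 numeric array, signal units
#' @slot rmse numeric array, fit residual RMS
#' @slot valid logical array
#' @export
setClass("T2StarMap", representation(
  t2sMs = "array", s0 = "array", rmse = "array", valid = "array"
))

setValidity("T2StarMap", function(object) {
  d <- dim(object@t2sMs)
  if (!identical(dim(object@s0), d) || !identical(dim(object@rmse), d) ||
      !identical(dim(object@valid), d))
    return("all maps must share dimensions")
  v <- object@valid
  if (any(object@t2sMs[v] <= 0, na.rm = TRUE)) return("T2* must be > 0 where valid")
  if (any(object@rmse[v] < 0, na.rm = TRUE)) return("fit RMSE must be >= 0")
  TRUE
})

#' TSNRMap: temporal signal-to-noise ratio maps
#'
#' @slot tsnr numeric array; NA where undefined (zero temporal SD)
#' @slot mean numeric array
#' @slot sd numeric array (sample SD, N-1)
#' @slot valid logical array
#' @export
setClass("TSNRMap", representation(
  tsnr = "array", mean = "array", sd = "array", valid = "array"
))

setValidity("TSNRMap", function(object) {
  d <- dim(object@tsnr)
  if (!identical(dim(object@mean), d) || !identical(dim(object@sd), d) ||
      !identical(dim(object@valid), d))
    return("all maps must share dimensions")
  v <- object@valid
  if (any(!is.finite(object@tsnr[v]))) return("tSNR must be finite where valid")
  if (any(object@tsnr[v] < 0)) return("tSNR must be >= 0 where valid")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "RespTrace", function(object) {
  cat(sprintf(
    "RespTrace: %d samples over %.1f s, %d trigger marks, %s\n",
    length(object@time), diff(range(object@time)), sum(object@trigger),
    if (object@synced) "synced (mean-removed)" else "raw"))
})

setMethod("show", "FieldCalibration", function(object) {
  cat(sprintf(
    "FieldCalibration: %d slices, coupling %.2f..%.2f Hz/unit, residual RMS %.2f..%.2f Hz\n",
    length(object@zMm), min(object@coupling), max(object@coupling),
    min(object@residualRms), max(object@residualRms)))
  cat(sprintf("  fit window %.1f s, %d frames used, %d excluded\n",
              object@fitWindow, object@nFramesUsed, length(object@excludedFrames)))
})

setMethod("show", "KSpaceData", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "KSpaceData (%s): %d x %d samples/line x lines, %d coil(s), %d slice(s)\n",
    if (is.null(object@meta$type)) "?" else object@meta$type, d[1], d[2], d[3], d[4]))
  cat(sprintf("  %d excitations, matrix %d x %d%s%s\n",
              length(unique(object@lines$exc)),
              object@meta$matrix[1], object@meta$matrix[2],
              if (isTRUE(object@meta$demodulated)) ", demodulated" else "",
              if (isTRUE(object@meta$refCorrected)) ", ref-corrected" else ""))
})

setMethod("show", "PhantomSpec", function(object) {
  d <- dim(object@pd)
  cat(sprintf("PhantomSpec: %d x %d x %d, voxel %s mm, cord %d voxels\n",
              d[1], d[2], d[3], paste(object@voxelMm, collapse = "x"),
              sum(object@cordMask)))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %d x %d, %d slice(s), %d echo(es)%s\n",
              d[1], d[2], d[3], d[4],
              if (is.complex(object@data)) " (complex)" else ""))
})
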