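## On-disk formats. Image volumes use NIfTI-1; complex images are stored as
## magnitude/phase NIfTI pairs (phase in radians, (-pi, pi]), matching how
## scanners export FLASH phase. The respiratory trace is a CSV with header
## time,value,trigger and an explicit time column (no sampling rate is
## assumed). K-space lives in a single-file R-native container (see
## writeKSpace). Calibrations travel as JSON.

#' Read a respiratory trace CSV
#'
#' Expects a CSV with header \code{time,value,trigger}: time in seconds
#' (strictly increasing), value in arbitrary bellows units, trigger 0/1
#' sequence-trigger marks.
#'
#' @param path path to the CSV file
#' @return a raw (unsynced) \linkS4class{RespTrace}
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) .bfStop("bf_format_error", paste("no such trace file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("time", "value", "trigger"), names(df))
  if (length(miss))
    .bfStop("bf_format_error",
            paste("trace CSV is missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) < 2L)
    .bfStop("bf_insufficient_data_error", "trace must contain at least 2 samples")
  if (any(diff(df$time) <= 0))
    .bfStop("bf_format_error", "trace time column must be strictly increasing")
  new("RespTrace", time = as.numeric(df$time), value = as.numeric(df$value),
      trigger = as.logical(df$trigger != 0), synced = FALSE)
}

#' Write a respiratory trace CSV
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces the doubles bit-identically.
#'
#' @param trace a \linkS4class{RespTrace}
#' @param path output path
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "RespTrace"))
  df <- data.frame(time = sprintf("%.17g", trace@time),
                   value = sprintf("%.17g", trace@value),
                   trigger = as.integer(trace@trigger))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- k-space container -----------------------------------------------------

.kspaceDatasets <- c("data", "lines", "meta")

#' Write a k-space container to disk
#'
#' Single-file R-native serialization of the three datasets \code{data}
#' (complex samples), \code{lines} (per-line k index and timing) and
#' \code{meta} (sequence descriptor); complex data and timing arrays round
#' trip losslessly.
#'
#' @param set a \linkS4class{KSpaceData}
#' @param path output path (conventionally \code{.rds})
#' @export
writeKSpace <- function(set, path) {
  stopifnot(is(set, "KSpaceData"))
  saveRDS(list(data = set@data, lines = set@lines, meta = set@meta,
               format = "breathfield-kspace-1"), path)
  invisible(path)
}

#' Read a k-space container
#'
#' @param path path written by \code{\link{writeKSpace}}
#' @return a \linkS4class{KSpaceData}
#' @export
readKSpace <- function(path) {
  if (!file.exists(path)) .bfStop("bf_format_error", paste("no such k-space file:", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    .bfStop("bf_format_error", paste("not a k-space container:", conditionMessage(e))))
  if (!is.list(obj))
    .bfStop("bf_format_error", "not a k-space container (expected a dataset list)")
  miss <- setdiff(.kspaceDatasets, names(obj))
  if (length(miss))
    .bfStop("bf_format_error",
            paste("k-space container is missing dataset(s):", paste(miss, collapse = ", ")))
  missCols <- setdiff(.requiredLineCols, names(obj$lines))
  if (length(missCols))
    .bfStop("bf_consistency_error",
            paste("k-space line table is missing:", paste(missCols, collapse = ", ")))
  if (length(dim(obj$data)) != 4L || nrow(obj$lines) != dim(obj$data)[2L])
    .bfStop("bf_consistency_error", "k-space array shapes are mutually inconsistent")
  out <- new("KSpaceData", data = obj$data, lines = obj$lines, meta = obj$meta)
  v <- validObject(out, test = TRUE)
  if (!isTRUE(v)) .bfStop("bf_consistency_error", paste("invalid k-space container:", v))
  out
}

## ---- NIfTI magnitude/phase pairs -------------------------------------------

#' Write a complex image series as a magnitude/phase NIfTI pair
#'
#' Writes \code{<prefix>_mag.nii.gz} and \code{<prefix>_phase.nii.gz}; phase
#' in radians, range (-pi, pi].
#'
#' @param img complex array (2-d to 4-d)
#' @param prefix output path prefix
#' @param voxelMm voxel dimensions, mm
#' @return character(2) of the written paths
#' @export
writeNiftiPair <- function(img, prefix, voxelMm = c(1, 1, 1)) {
  stopifnot(is.complex(img))
  magPath <- paste0(prefix, "_mag.nii.gz")
  phsPath <- paste0(prefix, "_phase.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(Mod(img), pixdim = voxelMm), magPath)
  RNifti::writeNifti(RNifti::asNifti(wrapToPi(Arg(img)), pixdim = voxelMm), phsPath)
  c(magPath, phsPath)
}

#' Read a magnitude/phase NIfTI pair back into a complex array
#'
#' @param prefix path prefix used by \code{\link{writeNiftiPair}}
#' @export
readNiftiPair <- function(prefix) {
  magPath <- paste0(prefix, "_mag.nii.gz")
  phsPath <- paste0(prefix, "_phase.nii.gz")
  if (!file.exists(magPath) || !file.exists(phsPath))
    .bfStop("bf_format_error", paste("missing NIfTI pair for prefix", prefix))
  mag <- .plainArray(RNifti::readNifti(magPath))
  phs <- .plainArray(RNifti::readNifti(phsPath))
  if (!identical(dim(mag), dim(phs)))
    .bfStop("bf_consistency_error", "magnitude and phase NIfTI dimensions differ")
  mag * exp(1i * phs)
}

#' Write / read a real-valued NIfTI volume
#'
#' Convenience wrappers for masks and quantitative maps.
#' @param vol numeric/logical array
#' @param path file path
#' @param voxelMm voxel dimensions, mm
#' @export
writeNiftiVolume <- function(vol, path, voxelMm = c(1, 1, 1)) {
  RNifti::writeNifti(RNifti::asNifti(vol * 1, pixdim = voxelMm), path)
  invisible(path)
}

#' @rdname writeNiftiVolume
#' @export
readNiftiVolume <- function(path) {
  if (!file.exists(path)) .bfStop("bf_format_error", paste("no such NIfTI file:", path))
  .plainArray(RNifti::readNifti(path))
}

# strip niftiImage class/attributes down to a plain numeric array
.plainArray <- function(x) array(as.vector(x), dim(x))

## ---- calibration JSON ------------------------------------------------------

#' Write a field calibration to JSON
#'
#' @param calib a \linkS4class{FieldCalibration}
#' @param path output path
#' @export
writeCalibration <- function(calib, path) {
  stopifnot(is(calib, "FieldCalibration"))
  jsonlite::write_json(
    list(z_mm = calib@zMm, coupling_hz_per_unit = calib@coupling,
         residual_rms_hz = calib@residualRms, fit_window_s = calib@fitWindow,
         excluded_frames = calib@excludedFrames, n_frames_used = calib@nFramesUsed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a field calibration from JSON
#'
#' @param path path written by \code{\link{writeCalibration}}
#' @export
readCalibration <- function(path) {
  if (!file.exists(path)) .bfStop("bf_format_error", paste("no such calibration:", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("z_mm", "coupling_hz_per_unit", "residual_rms_hz", "fit_window_s")
  miss <- setdiff(need, names(j))
  if (length(miss))
    .bfStop("bf_format_error",
            paste("calibration JSON is missing:", paste(miss, collapse = ", ")))
  new("FieldCalibration", zMm = as.numeric(j$z_mm),
      coupling = as.numeric(j$coupling_hz_per_unit),
      residualRms = as.numeric(j$residual_rms_hz),
      fitWindow = as.numeric(j$fit_window_s),
      excludedFrames = as.integer(if (is.null(j$excluded_frames)) integer() else j$excluded_frames),
      nFramesUsed = as.integer(if (is.null(j$n_frames_used)) NA_integer_ else j$n_frames_used))
}
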