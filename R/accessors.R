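## Accessor generics: slot access stays behind these.

#' @rdname accessors
#' @param x a breathfield object
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("traceValue", function(x) standardGeneric("traceValue"))
#' @rdname accessors
#' @export
setGeneric("traceTrigger", function(x) standardGeneric("traceTrigger"))
#' @rdname accessors
#' @export
setGeneric("isSynced", function(x) standardGeneric("isSynced"))

#' Accessors for breathfield S4 containers
#'
#' Small read-only accessors: \code{traceTime}/\code{traceValue}/
#' \code{traceTrigger}/\code{isSynced} for \code{RespTrace};
#' \code{zMm} (slice positions) for calibrations, profiles, phantoms and
#' k-space; \code{couplingHz}/\code{residualRmsHz}/\code{excludedFrames} for
#' \code{FieldCalibration}; \code{kData}/\code{kLines}/\code{kMeta} for
#' \code{KSpaceData}; \code{imageData}/\code{echoTimesMs} for
#' \code{ImageVolume}; \code{protonDensity}/\code{t2starTruth}/\code{cordMask}
#' for \code{PhantomSpec}; \code{coilMaps} for \code{CoilSensitivities};
#' \code{mapValues} for the quantitative map classes.
#'
#' @name accessors
NULL

setMethod("traceTime", "RespTrace", function(x) x@time)
setMethod("traceValue", "RespTrace", function(x) x@value)
setMethod("traceTrigger", "RespTrace", function(x) x@trigger)
setMethod("isSynced", "RespTrace", function(x) x@synced)

#' @rdname accessors
#' @export
setGeneric("zMm", function(x) standardGeneric("zMm"))
setMethod("zMm", "FieldCalibration", function(x) x@zMm)
setMethod("zMm", "FieldProfileSeries", function(x) x@zMm)
setMethod("zMm", "PhantomSpec", function(x) x@zMm)
setMethod("zMm", "PhaseSeries", function(x) x@zMm)
setMethod("zMm", "PredictedField", function(x) x@zMm)
setMethod("zMm", "KSpaceData", function(x) x@meta$zMm)

#' @rdname accessors
#' @export
setGeneric("couplingHz", function(x) standardGeneric("couplingHz"))
setMethod("couplingHz", "FieldCalibration", function(x) x@coupling)

#' @rdname accessors
#' @export
setGeneric("residualRmsHz", function(x) standardGeneric("residualRmsHz"))
setMethod("residualRmsHz", "FieldCalibration", function(x) x@residualRms)

#' @rdname accessors
#' @export
setGeneric("excludedFrames", function(x) standardGeneric("excludedFrames"))
setMethod("excludedFrames", "FieldCalibration", function(x) x@excludedFrames)

#' @rdname accessors
#' @export
setGeneric("kData", function(x) standardGeneric("kData"))
setMethod("kData", "KSpaceData", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("kLines", function(x) standardGeneric("kLines"))
setMethod("kLines", "KSpaceData", function(x) x@lines)

#' @rdname accessors
#' @export
setGeneric("kMeta", function(x) standardGeneric("kMeta"))
setMethod("kMeta", "KSpaceData", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
setMethod("imageData", "ImageVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("echoTimesMs", function(x) standardGeneric("echoTimesMs"))
setMethod("echoTimesMs", "ImageVolume", function(x) x@teMs)
setMethod("echoTimesMs", "KSpaceData", function(x) x@meta$teMs)

#' @rdname accessors
#' @export
setGeneric("protonDensity", function(x) standardGeneric("protonDensity"))
setMethod("protonDensity", "PhantomSpec", function(x) x@pd)

#' @rdname accessors
#' @export
setGeneric("t2starTruth", function(x) standardGeneric("t2starTruth"))
setMethod("t2starTruth", "PhantomSpec", function(x) x@t2sMs)

#' @rdname accessors
#' @export
setGeneric("cordMask", function(x) standardGeneric("cordMask"))
setMethod("cordMask", "PhantomSpec", function(x) x@cordMask)

#' @rdname accessors
#' @export
setGeneric("coilMaps", function(x) standardGeneric("coilMaps"))
setMethod("coilMaps", "CoilSensitivities", function(x) x@sens)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
setMethod("mapValues", "T2StarMap", function(x) x@t2sMs)
setMethod("mapValues", "TSNRMap", function(x) x@tsnr)

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
setMethod("validMask", "T2StarMap", function(x) x@valid)
setMethod("validMask", "TSNRMap", function(x) x@valid)

#' @rdname accessors
#' @export
setGeneric("fieldProfile", function(x) standardGeneric("fieldProfile"))
setMethod("fieldProfile", "FieldProfileSeries", function(x) x@f0)
setMethod("fieldProfile", "PredictedField", function(x) x@f0Hat)
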