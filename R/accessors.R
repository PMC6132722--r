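#' @rdname accessors
#' @export
setMethod("gridDim", "VelocityField4D", function(object) dim(object@velocity)[1:3])

#' @rdname accessors
#' @export
setMethod("gridDim", "SegmentationSeries", function(object) dim(object@labels)[1:3])

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VelocityField4D", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "SegmentationSeries", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("timeStamps", "VelocityField4D", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("timeStamps", "SegmentationSeries", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("timeStamps", "FlowCurveSet", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("nPhases", "VelocityField4D", function(object) dim(object@velocity)[4])

#' @rdname accessors
#' @export
setMethod("nPhases", "SegmentationSeries", function(object) dim(object@labels)[4])

.inferPeriod <- function(times, period) {
  if (!is.na(period)) return(period)
  if (length(times) < 2L) stopf("cannot infer cycle period from a single phase")
  max(times) + stats::median(diff(times))
}

#' @rdname accessors
#' @export
setMethod("cyclePeriod", "VelocityField4D",
          function(object) .inferPeriod(object@times, object@period))

#' @rdname accessors
#' @export
setMethod("cyclePeriod", "SegmentationSeries",
          function(object) .inferPeriod(object@times, object@period))

#' @rdname accessors
#' @export
setMethod("cyclePeriod", "FlowCurveSet",
          function(object) .inferPeriod(object@times, object@period))

#' @rdname accessors
#' @export
setMethod("gridOrigin", "VelocityField4D", function(object) object@origin)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "SegmentationSeries", function(object) object@origin)

#' @rdname accessors
#' @export
setMethod("voxelVolume", "VelocityField4D", function(object) prod(object@spacing))

#' @rdname accessors
#' @export
setMethod("voxelVolume", "SegmentationSeries", function(object) prod(object@spacing))

#' @rdname velocityData
#' @export
setMethod("velocityData", "VelocityField4D", function(object) object@velocity)

#' @rdname venc
#' @export
setMethod("venc", "VelocityField4D", function(object) object@venc)

#' @rdname labelData
#' @export
setMethod("labelData", "SegmentationSeries", function(object) object@labels)

#' FTLE value accessor
#' @param object an [FTLEField-class]
#' @return array of FTLE values (1/ms) with `NA` at flagged seeds
#' @export
ftleValues <- function(object) {
  stopifnot(is(object, "FTLEField"))
  out <- object@values
  out[object@flagged] <- NA_real_
  out
}
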