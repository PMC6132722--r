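#' Grid and timing accessors
#'
#' Small accessor generics shared by the velocity-field and segmentation
#' containers: grid dimensions, voxel spacing (mm), time stamps (ms), number
#' of phases, cycle period (ms) and grid origin (mm).
#'
#' @param object a [VelocityField4D-class] or [SegmentationSeries-class]
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("timeStamps", function(object) standardGeneric("timeStamps"))

#' @rdname accessors
#' @export
setGeneric("nPhases", function(object) standardGeneric("nPhases"))

#' @rdname accessors
#' @export
setGeneric("cyclePeriod", function(object) standardGeneric("cyclePeriod"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))

#' Velocity array accessor
#' @param object a [VelocityField4D-class]
#' @return 5D array (x, y, z, phase, component) in cm/s
#' @export
setGeneric("velocityData", function(object) standardGeneric("velocityData"))

#' VENC accessor
#' @param object a [VelocityField4D-class]
#' @export
setGeneric("venc", function(object) standardGeneric("venc"))

#' Segmentation label accessor
#' @param object a [SegmentationSeries-class]
#' @return 4D integer array (x, y, z, phase)
#' @export
setGeneric("labelData", function(object) standardGeneric("labelData"))

#' Particle advection through a velocity field
#'
#' Integrates particle trajectories with classical 4th-order Runge-Kutta.
#' The velocity may be a gridded [VelocityField4D-class] (sampled by
#' trilinear interpolation in space and linear interpolation in time, with
#' cyclic wrapping over the cardiac cycle) or a continuous velocity model
#' given as `function(t, pos)` returning cm/s for positions in mm and time
#' in ms. A negative `horizon` integrates backward in time.
#'
#' @param field velocity source
#' @param seeds n x 3 matrix of start positions, mm
#' @param t0 start time, ms
#' @param horizon signed integration horizon, ms (nonzero)
#' @param dt positive step size, ms; must satisfy `dt < |horizon|`
#' @param bloodMask optional [SegmentationSeries-class] or 3D/4D logical
#'   array; particles leaving the mask are frozen at the exit position and
#'   flagged
#' @return a [FlowMap-class]
#' @export
setGeneric("advect", function(field, seeds, t0, horizon, dt = NULL,
                              bloodMask = NULL) standardGeneric("advect"))
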