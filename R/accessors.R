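## Accessor generics and show methods.

#' @rdname ThermalFrame-class
#' @param object,x a package object.
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))
#' @rdname ThermalFrame-class
#' @export
setMethod("framePixels", "ThermalFrame", function(x) x@pixels)

#' @rdname ThermalFrame-class
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @rdname ThermalFrame-class
#' @export
setMethod("calibration", "ThermalFrame", function(x) x@calibration)
#' @rdname DetectorConfig-class
#' @export
setMethod("calibration", "DetectorConfig", function(x) x@calibration)
#' @rdname SceneConfig-class
#' @export
setMethod("calibration", "SceneConfig", function(x) x@calibration)

#' @rdname ThermalFrame-class
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))
#' @rdname ThermalFrame-class
#' @export
setMethod("frameId", "ThermalFrame", function(x) x@frameId)

#' @rdname ThermalFrame-class
#' @export
setGeneric("frameTimestamp", function(x) standardGeneric("frameTimestamp"))
#' @rdname ThermalFrame-class
#' @export
setMethod("frameTimestamp", "ThermalFrame", function(x) x@timestamp)

#' @rdname ThermalFrame-class
#' @export
setMethod("dim", "ThermalFrame", function(x) dim(x@pixels))

#' @rdname HenTemplate-class
#' @export
setGeneric("templateMask", function(x) standardGeneric("templateMask"))
#' @rdname HenTemplate-class
#' @export
setMethod("templateMask", "HenTemplate", function(x) x@mask)

#' @rdname HenTemplate-class
#' @export
setGeneric("templateShape", function(x) standardGeneric("templateShape"))
#' @rdname HenTemplate-class
#' @export
setMethod("templateShape", "HenTemplate", function(x) x@shape)

#' @rdname HenTemplate-class
#' @export
setGeneric("templateDims", function(x) standardGeneric("templateDims"))
#' @rdname HenTemplate-class
#' @export
setMethod("templateDims", "HenTemplate", function(x) x@dims)

setMethod("show", "ThermalCalibration", function(object) {
  cat(sprintf("ThermalCalibration: t = %.3f degC + level * %.4f degC\n",
              object@tAtZero, object@degPerLevel))
})

setMethod("show", "ThermalFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ThermalFrame '%s': %d x %d pixels, levels [%d, %d]\n",
              object@frameId, d[1L], d[2L],
              min(object@pixels), max(object@pixels)))
  cat(sprintf("  timestamp: %s\n", format(object@timestamp)))
  show(object@calibration)
})

setMethod("show", "HenTemplate", function(object) {
  cat(sprintf("HenTemplate: %s %g x %g px (%d x %d mask, %d fg pixels)\n",
              object@shape, object@dims[1L], object@dims[2L],
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
  cat(sprintf("  calibrated for floor shift %g degC\n",
              object@shiftAssociation))
})

setMethod("show", "DetectorConfig", function(object) {
  cat("DetectorConfig:\n")
  cat(sprintf("  shift %g degC | NCC threshold %g | CPT %g px\n",
              object@shift, object@nccThreshold, object@cpt))
  cat(sprintf("  particle filter: opening radius %g, min area %g px\n",
              object@openingRadius, object@minParticleArea))
  cat(sprintf("  floor statistic: %s | slot %g s | %d rotation angles\n",
              object@floorMethod, object@slotSeconds, length(object@angles)))
  show(object@template)
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d raster, floor %g degC (noise sd %g)\n",
              object@raster[1L], object@raster[2L], object@floorTemp,
              object@floorNoiseSd))
  cat(sprintf("  hen axes %g x %g px (jitter sd %g), deltaT [%g, %g] degC\n",
              object@henAxes[1L], object@henAxes[2L], object@henAxesJitterSd,
              object@henDeltaT[1L], object@henDeltaT[2L]))
  cat(sprintf("  artifact rates: footprint %g, egg %g, hotpatch %g | seed %d\n",
              object@artifactRates[["footprint"]],
              object@artifactRates[["egg"]],
              object@artifactRates[["hotpatch"]], object@seed))
})
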