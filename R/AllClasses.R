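## Central S4 classes. Raster convention throughout the package: matrices are
## indexed (row, col), origin top-left, 1-based in R code; the nominal camera
## raster is 240 rows x 320 columns.

#' Linear intensity-temperature calibration
#'
#' Maps 8-bit grey levels to degrees Celsius and back: a grey level \code{L}
#' corresponds to \code{tAtZero + L * degPerLevel}. The calibration is carried
#' by every \linkS4class{ThermalFrame} so that temperature shifts expressed in
#' degrees translate into well-defined intensity shifts (under the default
#' 0.1 degC/level, a 1 degC shift is 10 grey levels).
#'
#' @slot tAtZero numeric(1); temperature (degC) mapped to intensity 0.
#' @slot degPerLevel numeric(1); degrees Celsius per grey level, > 0.
#' @aliases ThermalCalibration
#' @seealso [intensityOf()], [temperatureOf()]
#' @export
setClass("ThermalCalibration",
  representation(tAtZero = "numeric", degPerLevel = "numeric"),
  prototype(tAtZero = 0, degPerLevel = 0.1))

setValidity("ThermalCalibration", function(object) {
  if (length(object@tAtZero) != 1L || !is.finite(object@tAtZero))
    return("'tAtZero' must be a single finite number")
  if (length(object@degPerLevel) != 1L || !is.finite(object@degPerLevel) ||
      object@degPerLevel <= 0)
    return("'degPerLevel' must be a single positive number")
  TRUE
})

#' @param tAtZero temperature (degC) corresponding to grey level 0.
#' @param degPerLevel degrees Celsius per grey level (strictly positive).
#' @return \code{thermalCalibration()} returns a \code{ThermalCalibration}.
#' @examples
#' cal <- thermalCalibration(0, 0.1)
#' intensityOf(9, cal)      # 90
#' temperatureOf(90, cal)   # 9
#' @rdname ThermalCalibration-class
#' @export
thermalCalibration <- function(tAtZero = 0, degPerLevel = 0.1) {
  new("ThermalCalibration", tAtZero = tAtZero, degPerLevel = degPerLevel)
}

#' A calibrated grey-scale thermographic frame
#'
#' An 8-bit grey-level raster together with the calibration that maps its
#' intensities to temperatures, a timestamp, and an opaque frame identifier.
#'
#' @slot pixels integer matrix of grey levels in [0, 255], (row, col) indexed.
#' @slot calibration a \linkS4class{ThermalCalibration}.
#' @slot timestamp POSIXct acquisition instant.
#' @slot frameId character(1) label.
#' @aliases ThermalFrame
#' @export
setClass("ThermalFrame",
  representation(pixels = "matrix", calibration = "ThermalCalibration",
                 timestamp = "POSIXct", frameId = "character"))

setValidity("ThermalFrame", function(object) {
  px <- object@pixels
  if (!is.numeric(px) || length(dim(px)) != 2L)
    return("'pixels' must be a numeric matrix")
  if (nrow(px) < 1L || ncol(px) < 1L)
    return("'pixels' must have at least one row and one column")
  if (anyNA(px) || any(px < 0) || any(px > 255) || any(px != round(px)))
    return("'pixels' must be integers in [0, 255]")
  if (length(object@frameId) != 1L)
    return("'frameId' must be a single string")
  TRUE
})

#' @param pixels numeric/integer matrix of grey levels in [0, 255].
#' @param calibration a \linkS4class{ThermalCalibration}.
#' @param timestamp POSIXct; defaults to the current time.
#' @param frameId character(1) identifier.
#' @return \code{thermalFrame()} returns a \code{ThermalFrame}.
#' @rdname ThermalFrame-class
#' @export
thermalFrame <- function(pixels, calibration = thermalCalibration(),
                         timestamp = Sys.time(), frameId = "frame") {
  storage.mode(pixels) <- "integer"
  new("ThermalFrame", pixels = pixels, calibration = calibration,
      timestamp = as.POSIXct(timestamp), frameId = frameId)
}

#' Binary hen template
#'
#' A binary mask (1 = template foreground) searched in binarized frames by
#' normalized cross-correlation. Elliptical templates describe the full hen
#' body seen at a floor-temperature shift of 1 degC; triangular templates
#' describe the head region that remains visible at larger shifts.
#'
#' @slot mask integer matrix of 0/1, tight bounding box of the shape.
#' @slot shape character(1), \code{"ellipse"} or \code{"triangle"}.
#' @slot dims numeric(2); (major, minor) axes for ellipses, (base, height)
#'   for triangles, in pixels.
#' @slot shiftAssociation numeric(1); the floor-temperature shift (degC) the
#'   template geometry was calibrated for.
#' @aliases HenTemplate
#' @seealso [makeEllipseTemplate()], [makeTriangleTemplate()],
#'   [calibrateTemplate()]
#' @export
setClass("HenTemplate",
  representation(mask = "matrix", shape = "character", dims = "numeric",
                 shiftAssociation = "numeric"))

setValidity("HenTemplate", function(object) {
  if (!object@shape %in% c("ellipse", "triangle"))
    return("'shape' must be \"ellipse\" or \"triangle\"")
  m <- object@mask
  if (!all(m %in% c(0L, 1L))) return("'mask' must contain only 0 and 1")
  if (sum(m) < 1L) return("'mask' must contain at least one foreground pixel")
  if (length(object@dims) != 2L || any(object@dims <= 0))
    return("'dims' must be two positive lengths in pixels")
  TRUE
})

#' Detector configuration
#'
#' All tunable parameters of the detection pipeline. Defaults mirror the
#' operational set-up selected after calibration sweeps: a 1 degC floor
#' shift, a 135 x 63 pixel elliptical template, a colored-pixel threshold of
#' 1736 pixels, and 2-second monitoring slots.
#'
#' @slot shift numeric(1); temperature shift (degC) added to the estimated
#'   floor temperature to form the Background Color Threshold. Must be > 0.
#' @slot template a \linkS4class{HenTemplate}.
#' @slot nccThreshold numeric(1) in (0, 1]; minimum normalized
#'   cross-correlation score accepted as a pattern match.
#' @slot cpt numeric(1); Colored Pixels Threshold, the fallback minimum
#'   foreground pixel count that still declares a detection.
#' @slot minParticleArea numeric(1); connected components smaller than this
#'   (pixels) are removed by the particle filter.
#' @slot openingRadius numeric(1); disc radius (pixels) of the morphological
#'   opening applied before the area cut.
#' @slot floorMethod character(1); \code{"mode"} or \code{"trimmed-mean"},
#'   the floor-temperature statistic.
#' @slot slotSeconds numeric(1); monitoring slot duration in seconds.
#' @slot calibration a \linkS4class{ThermalCalibration} used when frames do
#'   not carry their own.
#' @slot angles numeric; rotation grid (degrees) searched during matching.
#' @aliases DetectorConfig
#' @seealso [detectorConfig()], [detectFrame()], [runMonitoring()]
#' @export
setClass("DetectorConfig",
  representation(shift = "numeric", template = "HenTemplate",
                 nccThreshold = "numeric", cpt = "numeric",
                 minParticleArea = "numeric", openingRadius = "numeric",
                 floorMethod = "character", slotSeconds = "numeric",
                 calibration = "ThermalCalibration", angles = "numeric"))

setValidity("DetectorConfig", function(object) {
  if (object@shift <= 0) return("'shift' must be > 0")
  if (object@cpt <= 0) return("'cpt' must be > 0")
  if (object@slotSeconds <= 0) return("'slotSeconds' must be > 0")
  if (object@nccThreshold <= 0 || object@nccThreshold > 1)
    return("'nccThreshold' must lie in (0, 1]")
  if (object@minParticleArea < 0 || object@openingRadius < 0)
    return("'minParticleArea' and 'openingRadius' must be >= 0")
  if (!object@floorMethod %in% c("mode", "trimmed-mean"))
    return("'floorMethod' must be \"mode\" or \"trimmed-mean\"")
  if (length(object@angles) < 1L) return("'angles' must be non-empty")
  TRUE
})

#' Synthetic thermal scene configuration
#'
#' Parameters of the synthetic frame generator: a floor at ambient
#' temperature with per-pixel Gaussian camera noise, hen-shaped warm
#' ellipses with a hotter head disc, and the residual-heat artifact classes
#' observed in the field (foot imprints, eggs laid on the floor, warm floor
#' patches).
#'
#' @slot raster integer(2); (rows, cols) of the frame, default (240, 320).
#' @slot floorTemp numeric(1); ambient floor temperature (degC), default 8.
#' @slot floorNoiseSd numeric(1); per-pixel noise s.d. (degC), default 0.04
#'   (the camera's thermal sensitivity).
#' @slot henAxes numeric(2); mean full (major, minor) ellipse axes of a hen
#'   body in pixels, default (135, 63).
#' @slot henAxesJitterSd numeric(1); s.d. (pixels) of per-hen axis jitter.
#' @slot henDeltaT numeric(2); range (degC) from which each hen's body
#'   contrast above the floor is drawn uniformly, default [1, 4].
#' @slot headRadius numeric(1); radius (pixels) of the hotter head disc
#'   (+1 degC above the body), drawn inside one end of the body ellipse.
#' @slot artifactRates numeric(3), named \code{footprint}, \code{egg},
#'   \code{hotpatch}; per-frame occurrence probabilities.
#' @slot cameraOffsetSd numeric(1); s.d. (degC) of a per-sequence constant
#'   temperature offset emulating absolute-accuracy error (default 0 = off).
#'   Relative thresholding makes the detector invariant to it.
#' @slot calibration a \linkS4class{ThermalCalibration}.
#' @slot seed integer(1); base random seed for deterministic rendering.
#' @aliases SceneConfig
#' @seealso [sceneConfig()], [renderFrame()], [renderSequence()]
#' @export
setClass("SceneConfig",
  representation(raster = "integer", floorTemp = "numeric",
                 floorNoiseSd = "numeric", henAxes = "numeric",
                 henAxesJitterSd = "numeric", henDeltaT = "numeric",
                 headRadius = "numeric", artifactRates = "numeric",
                 cameraOffsetSd = "numeric",
                 calibration = "ThermalCalibration", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (length(object@raster) != 2L || any(object@raster < 1L))
    return("'raster' must be two positive integers (rows, cols)")
  if (object@floorNoiseSd < 0) return("'floorNoiseSd' must be >= 0")
  if (length(object@henDeltaT) != 2L || any(object@henDeltaT <= 0))
    return("'henDeltaT' must be a positive range (degC above floor)")
  r <- object@artifactRates
  if (length(r) != 3L ||
      !all(c("footprint", "egg", "hotpatch") %in% names(r)) ||
      any(r < 0) || any(r > 1))
    return("'artifactRates' must be probabilities named footprint, egg, hotpatch")
  TRUE
})
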