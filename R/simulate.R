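## Synthetic thermal-scene generator: floor at ambient temperature with
## Gaussian camera noise, hen-shaped warm ellipses with a hotter head disc,
## and the residual-heat artifact classes seen in the field (foot imprints,
## eggs laid on the floor, warm floor patches). Provides ground truth so the
## whole pipeline can be benchmarked without hardware.

#' Build a synthetic scene configuration
#'
#' Defaults emulate the experimental conditions: a floor at 8 degC ambient
#' (operating range 5-13 degC), per-pixel noise at the camera sensitivity
#' of 0.04 degC, hen bodies of 135 x 63 pixel mean axes at 1-4 degC above
#' the floor with a +1 degC head disc, and occasional artifacts.
#'
#' @param raster (rows, cols), default c(240, 320).
#' @param floorTemp floor temperature in degC.
#' @param floorNoiseSd per-pixel Gaussian noise s.d. in degC.
#' @param henAxes mean full (major, minor) hen body axes in pixels.
#' @param henAxesJitterSd per-hen axis jitter s.d. in pixels.
#' @param henDeltaT range (degC) of the hen body contrast above the floor.
#' @param headRadius radius (pixels) of the head disc, drawn inside one end
#'   of the body ellipse at body + 1 degC.
#' @param artifactRates named per-frame probabilities for \code{footprint}
#'   (two +0.5 degC discs of radius 3-5 px), \code{egg} (one disc of radius
#'   8-12 px at hen body temperature), and \code{hotpatch} (one +1.5 degC
#'   patch of radius 8-16 px).
#' @param cameraOffsetSd s.d. (degC) of a per-sequence constant offset
#'   emulating the camera's absolute-accuracy error; 0 disables it.
#' @param calibration a \linkS4class{ThermalCalibration}.
#' @param seed integer base seed; frames are rendered from per-slot streams
#'   derived from it, so sequences are reproducible slot by slot.
#' @return a \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(raster = c(240L, 320L),
                        floorTemp = 8.0,
                        floorNoiseSd = 0.04,
                        henAxes = c(135, 63),
                        henAxesJitterSd = 4,
                        henDeltaT = c(1.0, 4.0),
                        headRadius = 12,
                        artifactRates = c(footprint = 0.10, egg = 0.05,
                                          hotpatch = 0.05),
                        cameraOffsetSd = 0,
                        calibration = thermalCalibration(),
                        seed = 1L) {
  new("SceneConfig", raster = as.integer(raster), floorTemp = floorTemp,
      floorNoiseSd = floorNoiseSd, henAxes = henAxes,
      henAxesJitterSd = henAxesJitterSd, henDeltaT = henDeltaT,
      headRadius = headRadius, artifactRates = artifactRates,
      cameraOffsetSd = cameraOffsetSd, calibration = calibration,
      seed = as.integer(seed))
}

## Set temperature `value` inside a rotated filled ellipse. Major axis along
## the unit vector (sin angle, cos angle) in (row, col) coordinates.
paintEllipse <- function(temp, center, a, b, angleDeg, value) {
  th <- angleDeg * pi / 180
  h <- nrow(temp); w <- ncol(temp)
  rr <- max(1L, floor(center[1L] - a)):min(h, ceiling(center[1L] + a))
  cc <- max(1L, floor(center[2L] - a)):min(w, ceiling(center[2L] + a))
  dr <- matrix(rr - center[1L], length(rr), length(cc))
  dc <- matrix(cc - center[2L], length(rr), length(cc), byrow = TRUE)
  along <- dr * sin(th) + dc * cos(th)
  across <- dr * cos(th) - dc * sin(th)
  inside <- (along / a)^2 + (across / b)^2 <= 1
  sub <- temp[rr, cc, drop = FALSE]
  sub[inside] <- value
  temp[rr, cc] <- sub
  temp
}

paintDisc <- function(temp, center, radius, value) {
  paintEllipse(temp, center, radius, radius, 0, value)
}

#' Render one synthetic thermographic frame
#'
#' The temperature field is the floor plus Gaussian pixel noise; each hen is
#' a rotated filled ellipse at its body contrast above the floor with a
#' hotter (+1 degC) head disc inside one end; artifacts are painted
#' according to their per-frame rates; the field is then quantized through
#' the calibration into grey levels. Rendering is deterministic in
#' \code{(seed, slotIndex)}.
#'
#' @param scene a \linkS4class{SceneConfig}.
#' @param slotIndex integer slot number (selects the random stream).
#' @param henCount number of hens to place (0 or more).
#' @param henDeltaT optional fixed body contrast (degC above floor);
#'   overrides the scene's sampling range.
#' @return list with \code{frame} (a \linkS4class{ThermalFrame}) and
#'   \code{truth}: \code{occupied} flag, \code{hens} data.frame
#'   (centroid, planted axes, angle, body contrast) and \code{artifacts}
#'   data.frame (type, centre, radius).
#' @export
renderFrame <- function(scene, slotIndex, henCount = 0L,
                        henDeltaT = NULL) {
  set.seed(childSeed(scene@seed, slotIndex))
  H <- scene@raster[1L]; W <- scene@raster[2L]
  temp <- matrix(scene@floorTemp, H, W)
  if (scene@floorNoiseSd > 0)
    temp <- temp + matrix(rnorm(H * W, 0, scene@floorNoiseSd), H, W)

  hens <- data.frame(centroidRow = numeric(0), centroidCol = numeric(0),
                     major = numeric(0), minor = numeric(0),
                     angle = numeric(0), deltaT = numeric(0))
  for (k in seq_len(henCount)) {
    major <- scene@henAxes[1L] + rnorm(1, 0, scene@henAxesJitterSd)
    minor <- scene@henAxes[2L] + rnorm(1, 0, scene@henAxesJitterSd)
    if (minor > major) { tmp <- major; major <- minor; minor <- tmp }
    a <- major / 2; b <- minor / 2
    margin <- ceiling(a) + 2
    if (H - 2 * margin < 1 || W - 2 * margin < 1)
      stop("hen ellipse cannot be placed inside the raster")
    ctr <- c(runif(1, 1 + margin, H - margin),
             runif(1, 1 + margin, W - margin))
    ang <- runif(1, 0, 180)
    dt <- if (is.null(henDeltaT))
      runif(1, scene@henDeltaT[1L], scene@henDeltaT[2L]) else henDeltaT
    body <- scene@floorTemp + dt
    temp <- paintEllipse(temp, ctr, a, b, ang, body)
    ## head disc inside one end of the body ellipse, 1 degC hotter
    hr <- min(scene@headRadius, b - 1)
    hd <- a - hr - 2
    headCtr <- ctr + hd * c(sin(ang * pi / 180), cos(ang * pi / 180))
    temp <- paintDisc(temp, headCtr, hr, body + 1)
    hens[k, ] <- list(ctr[1L], ctr[2L], major, minor, ang, dt)
  }

  artifacts <- data.frame(type = character(0), row = numeric(0),
                          col = numeric(0), radius = numeric(0))
  addArtifact <- function(type, centre, radius, value) {
    temp <<- paintDisc(temp, centre, radius, value)
    artifacts[nrow(artifacts) + 1L, ] <<-
      list(type, centre[1L], centre[2L], radius)
  }
  randomCentre <- function(margin) c(runif(1, 1 + margin, H - margin),
                                     runif(1, 1 + margin, W - margin))
  if (runif(1) < scene@artifactRates[["footprint"]]) {
    base <- randomCentre(12)
    for (i in 1:2) {
      r <- runif(1, 3, 5)
      addArtifact("footprint", base + runif(2, -6, 6), r,
                  scene@floorTemp + 0.5)
    }
  }
  if (runif(1) < scene@artifactRates[["egg"]]) {
    r <- runif(1, 8, 12)
    eggDt <- runif(1, scene@henDeltaT[1L], scene@henDeltaT[2L])
    addArtifact("egg", randomCentre(r + 2), r, scene@floorTemp + eggDt)
  }
  if (runif(1) < scene@artifactRates[["hotpatch"]]) {
    r <- runif(1, 8, 16)
    addArtifact("hotpatch", randomCentre(r + 2), r, scene@floorTemp + 1.5)
  }

  if (scene@cameraOffsetSd > 0) {
    ## per-sequence constant absolute-accuracy offset: a deterministic
    ## function of the base seed only, so every slot sees the same shift
    u <- (childSeed(scene@seed, 1999999999L) %% 100003L + 0.5) / 100003
    temp <- temp + stats::qnorm(u, 0, scene@cameraOffsetSd)
  }

  px <- matrix(as.integer(intensityOf(temp, scene@calibration)), H, W)
  frame <- thermalFrame(px, scene@calibration,
                        timestamp = as.POSIXct("2026-01-01", tz = "UTC") +
                          slotIndex * 2,
                        frameId = sprintf("synthetic-%06d", slotIndex))
  list(frame = frame,
       truth = list(occupied = as.integer(henCount > 0), hens = hens,
                    artifacts = artifacts))
}

#' Render a synthetic frame sequence with ground truth
#'
#' Renders one frame per slot according to an occupancy schedule. With
#' \code{dir} given, frames are written as PNG files named with synthetic
#' timestamps (\code{henmon-YYYYMMDD-HHMMSS.png}) plus a \code{truth.tsv}
#' aligned to slots; otherwise frames are returned in memory.
#'
#' @param scene a \linkS4class{SceneConfig}.
#' @param nSlots number of slots (>= 0).
#' @param occupancy per-slot hen counts, recycled to \code{nSlots}
#'   (default all empty).
#' @param dir optional output directory (created if missing).
#' @param slotSeconds slot duration used for the synthetic timestamps.
#' @return list with \code{frames} (list of \linkS4class{ThermalFrame}s;
#'   omitted when writing to \code{dir}), \code{truth} (data.frame
#'   \code{slot}, \code{occupied}), and when writing, \code{dir} and
#'   \code{truthPath}.
#' @export
renderSequence <- function(scene, nSlots, occupancy = 0L, dir = NULL,
                           slotSeconds = 2) {
  stopifnot(nSlots >= 0)
  occupancy <- rep_len(as.integer(occupancy), nSlots)
  truth <- data.frame(slot = seq_len(nSlots) - 1L, occupied =
                        as.integer(occupancy > 0L))
  if (is.null(dir)) {
    frames <- vector("list", nSlots)
    for (i in seq_len(nSlots))
      frames[[i]] <- renderFrame(scene, i - 1L, occupancy[i])$frame
    return(list(frames = frames, truth = truth))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t0 <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  for (i in seq_len(nSlots)) {
    fr <- renderFrame(scene, i - 1L, occupancy[i])$frame
    stamp <- format(t0 + (i - 1L) * slotSeconds, "%Y%m%d-%H%M%S")
    writeFrame(fr, file.path(dir, sprintf("henmon-%s.png", stamp)))
  }
  truthPath <- file.path(dir, "truth.tsv")
  write.table(truth, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(truth = truth, dir = dir, truthPath = truthPath)
}
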