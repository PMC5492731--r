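## The monitoring loop: per-frame detection (pre-processing -> pattern
## recognition -> colored-pixel fallback) and slot-based logging.

#' Build a detector configuration
#'
#' Defaults correspond to the operational set-up selected after the
#' calibration sweeps: floor shift 1 degC, elliptical 135 x 63 template,
#' NCC acceptance threshold 0.5, Colored Pixels Threshold 1736, 2-second
#' slots.
#'
#' @param shift floor-temperature shift in degC (> 0).
#' @param template a \linkS4class{HenTemplate}.
#' @param nccThreshold NCC acceptance score in (0, 1].
#' @param cpt Colored Pixels Threshold in pixels (> 0).
#' @param minParticleArea,openingRadius particle filter settings.
#' @param floorMethod floor statistic, \code{"mode"} or
#'   \code{"trimmed-mean"}.
#' @param slotSeconds monitoring slot duration in seconds.
#' @param calibration fallback \linkS4class{ThermalCalibration}.
#' @param angles rotation grid in degrees (default depends on the template
#'   shape, see [matchTemplate()]).
#' @return a \linkS4class{DetectorConfig}.
#' @export
detectorConfig <- function(shift = 1.0,
                           template = makeEllipseTemplate(135, 63),
                           nccThreshold = 0.5,
                           cpt = 1736,
                           minParticleArea = 30,
                           openingRadius = 1,
                           floorMethod = "mode",
                           slotSeconds = 2,
                           calibration = thermalCalibration(),
                           angles = NULL) {
  if (is.null(angles)) angles <- defaultAngles(template)
  new("DetectorConfig", shift = shift, template = template,
      nccThreshold = nccThreshold, cpt = cpt,
      minParticleArea = minParticleArea, openingRadius = openingRadius,
      floorMethod = floorMethod, slotSeconds = slotSeconds,
      calibration = calibration, angles = angles)
}

## The decision rule: a hen is detected when pattern recognition succeeds
## or, failing that, when the colored-pixel count strictly exceeds the CPT.
hdFlag <- function(matched, cp, cpt) {
  as.integer(matched || cp > cpt)
}

#' Detect hens in a single frame
#'
#' Runs the full per-frame pipeline in order: intensity histogram, floor
#' temperature estimate, Background Color Threshold at the configured
#' shift, binarization, small-particle filter, colored-pixel count, and
#' template matching by normalized cross-correlation over the rotation
#' grid. The Hens Detected (HD) flag is 1 when the pattern matcher succeeds
#' or when the colored-pixel count strictly exceeds the Colored Pixels
#' Threshold.
#'
#' @param frame a \linkS4class{ThermalFrame}.
#' @param config a \linkS4class{DetectorConfig}.
#' @return list of class \code{"DetectionResult"}: \code{hd} (0/1),
#'   \code{matched}, \code{cp}, \code{bct}, \code{match} (see
#'   [matchTemplate()]), \code{frameId}, \code{warnings} (character).
#' @examples
#' scene <- sceneConfig(seed = 7)
#' fr <- renderFrame(scene, 1, henCount = 1)$frame
#' detectFrame(fr, detectorConfig())$hd
#' @export
detectFrame <- function(frame, config = detectorConfig()) {
  cal <- calibration(frame)
  warnings <- character(0)
  bg <- estimateFloor(frame, config@floorMethod)
  bct <- withCallingHandlers(
    computeBCT(bg, config@shift, cal),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  mask <- filterSmallParticles(binarize(frame, bct),
                               config@minParticleArea,
                               config@openingRadius)
  cp <- countColoredPixels(mask)
  match <- if (cp > 0L) {
    matchTemplate(mask, config@template, config@nccThreshold, config@angles)
  } else {
    ## NCC over a blank mask is 0 everywhere by the constant-window rule
    list(found = FALSE, score = 0,
         location = c(NA_integer_, NA_integer_), angle = NA_real_)
  }
  structure(list(hd = hdFlag(match$found, cp, config@cpt),
                 matched = match$found, cp = cp,
                 bct = as.integer(bct), match = match,
                 frameId = frameId(frame), warnings = warnings),
            class = "DetectionResult")
}

#' @export
print.DetectionResult <- function(x, ...) {
  cat(sprintf(
    "DetectionResult '%s': HD = %d (matched %s, CP = %d, BCT = %d)\n",
    x$frameId, x$hd, if (x$matched) "yes" else "no", x$cp, x$bct))
  if (x$matched)
    cat(sprintf("  best match: R = %.3f at (%d, %d), angle %g deg\n",
                x$match$score, x$match$location[1L], x$match$location[2L],
                x$match$angle))
  invisible(x)
}

logColumns <- c("slot_start", "slot_end", "hd", "cp", "bct", "shift_c",
                "template_id", "ncc_score", "warnings")

#' Run the slot-based monitoring loop
#'
#' Frames are grouped by timestamp into consecutive slots of
#' \code{slotSeconds}; a slot is positive when at least one of its frames
#' detects a hen. One record is produced per slot and appended to the text
#' log (UTF-8 TSV with a header row) as it is closed, so a partial run
#' leaves a valid log.
#'
#' @param frames a list of \linkS4class{ThermalFrame}s with non-decreasing
#'   timestamps, or a directory path containing \code{.png}/\code{.bmp}
#'   frames (read in timestamp order).
#' @param config a \linkS4class{DetectorConfig}.
#' @param logPath optional path of the TSV log to write.
#' @return data.frame of monitoring records with columns
#'   \code{slot_start}, \code{slot_end}, \code{hd}, \code{cp} (largest CP in
#'   the slot), \code{bct}, \code{shift_c}, \code{template_id},
#'   \code{ncc_score} (best score in the slot), \code{warnings}.
#' @export
runMonitoring <- function(frames, config = detectorConfig(),
                          logPath = NULL) {
  if (is.character(frames) && length(frames) == 1L) {
    paths <- list.files(frames, pattern = "\\.(png|bmp)$",
                        ignore.case = TRUE, full.names = TRUE)
    frames <- lapply(paths, readFrame, calibration = config@calibration)
    frames <- frames[order(vapply(frames, function(f)
      as.numeric(frameTimestamp(f)), numeric(1)))]
  }
  templateId <- sprintf("%s-%gx%g", config@template@shape,
                        config@template@dims[1L], config@template@dims[2L])
  empty <- data.frame(slot_start = character(0), slot_end = character(0),
                      hd = integer(0), cp = integer(0), bct = integer(0),
                      shift_c = numeric(0), template_id = character(0),
                      ncc_score = numeric(0), warnings = character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(logPath))
    write.table(empty, logPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  if (length(frames) == 0L) return(empty)

  ts <- vapply(frames, function(f) as.numeric(frameTimestamp(f)), numeric(1))
  if (is.unsorted(ts)) stop("frame timestamps must be non-decreasing")
  slotIndex <- floor((ts - ts[1L]) / config@slotSeconds)
  records <- empty
  for (s in unique(slotIndex)) {
    slotFrames <- frames[slotIndex == s]
    slotStart <- ts[1L] + s * config@slotSeconds
    results <- list()
    errs <- character(0)
    for (f in slotFrames) {
      res <- tryCatch(detectFrame(f, config), error = function(e) e)
      if (inherits(res, "error")) {
        errs <- c(errs, paste0("frame error: ", conditionMessage(res)))
      } else {
        results[[length(results) + 1L]] <- res
      }
    }
    rec <- data.frame(
      slot_start = formatTimestamp(slotStart),
      slot_end = formatTimestamp(slotStart + config@slotSeconds),
      hd = if (length(results)) max(vapply(results, `[[`, 0L, "hd")) else 0L,
      cp = if (length(results))
        max(vapply(results, `[[`, 0L, "cp")) else NA_integer_,
      bct = if (length(results))
        results[[1L]]$bct else NA_integer_,
      shift_c = config@shift,
      template_id = templateId,
      ncc_score = if (length(results))
        max(vapply(results, function(r) r$match$score, 0)) else NA_real_,
      warnings = paste(c(errs, unlist(lapply(results, `[[`, "warnings"))),
                       collapse = "; "),
      stringsAsFactors = FALSE)
    records <- rbind(records, rec)
    if (!is.null(logPath))
      write.table(rec, logPath, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE, append = TRUE,
                  fileEncoding = "UTF-8")
  }
  records
}

formatTimestamp <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS3Z")
}

#' Read a monitoring log back into records
#'
#' @param path TSV log written by [runMonitoring()].
#' @return data.frame with the same columns as the [runMonitoring()] value.
#' @export
readMonitoringLog <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    slot_start = "character", slot_end = "character", hd = "integer",
    cp = "integer", bct = "integer", shift_c = "numeric",
    template_id = "character", ncc_score = "numeric",
    warnings = "character"))
}
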