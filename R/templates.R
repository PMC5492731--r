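## Hen templates: rasterized ellipse/triangle masks and geometry calibration
## from annotated single-hen frames.

#' Elliptical hen template
#'
#' Filled axis-aligned ellipse rasterized into a tight
#' \code{(minor + 1) x (major + 1)} mask: the full-body hen shape seen at a
#' floor-temperature shift of 1 degC (operational size 135 x 63 pixels).
#'
#' @param major,minor full axis lengths in pixels; \code{major >= minor >= 3}.
#' @param shift the floor shift (degC) the template is associated with.
#' @return a \linkS4class{HenTemplate}.
#' @examples
#' tpl <- makeEllipseTemplate(135, 63)
#' sum(templateMask(tpl))   # close to pi * 135/2 * 63/2
#' @export
makeEllipseTemplate <- function(major, minor, shift = 1) {
  if (!(major >= minor && minor >= 3))
    stop("ellipse template requires major >= minor >= 3")
  h <- as.integer(minor) + 1L
  w <- as.integer(major) + 1L
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- ((c - cc) / (major / 2))^2 + ((r - cr) / (minor / 2))^2 <= 1
  mask <- matrix(0L, h, w)
  mask[inside] <- 1L
  new("HenTemplate", mask = mask, shape = "ellipse",
      dims = c(major, minor), shiftAssociation = shift)
}

#' Triangular hen template
#'
#' Filled isosceles triangle, base horizontal at the bottom edge and apex
#' centred at the top: the head-scale shape that remains visible at floor
#' shifts of 2-3 degC (operational sizes 35 x 16 and 18 x 12 pixels).
#'
#' @param base,height base and height in pixels; both >= 3.
#' @param shift the floor shift (degC) the template is associated with.
#' @return a \linkS4class{HenTemplate}.
#' @export
makeTriangleTemplate <- function(base, height, shift = 2) {
  if (base < 3 || height < 3)
    stop("triangle template requires base >= 3 and height >= 3")
  h <- as.integer(height)
  w <- as.integer(base)
  mask <- matrix(0L, h, w)
  cc <- (w + 1) / 2
  for (r in seq_len(h)) {
    halfWidth <- (base / 2) * r / h
    cols <- which(abs(seq_len(w) - cc) <= halfWidth)
    mask[r, cols] <- 1L
  }
  new("HenTemplate", mask = cropMask(mask), shape = "triangle",
      dims = c(base, height), shiftAssociation = shift)
}

#' Calibrate template geometry from annotated frames
#'
#' Reproduces the template set-up procedure: every frame is annotated as
#' containing exactly one hen; segmentation is run at the requested floor
#' shift; the largest particle of each frame (the hen) is measured; and the
#' per-feature means over frames define the template. At a shift of 1 degC
#' almost the whole hen is visible, so the equivalent-ellipse axes are
#' collected and an elliptical template is returned; at larger shifts only
#' the head remains visible, so the oriented-rectangle sides are collected
#' and a triangular template (base x height) is returned. Feature means are
#' rounded to the nearest pixel for the template dimensions.
#'
#' @param frames list of single-hen \linkS4class{ThermalFrame}s.
#' @param shift floor-temperature shift in degC.
#' @param floorMethod floor statistic passed to [estimateFloor()].
#' @param minArea,openingRadius particle filter settings
#'   (see [filterSmallParticles()]).
#' @return list with \code{template} (a \linkS4class{HenTemplate}) and
#'   \code{stats}, a data.frame with one row per geometric feature:
#'   \code{shape}, \code{feature}, \code{n}, \code{mean}, \code{se},
#'   \code{ciLow}, \code{ciHigh} (95%, Student t), \code{pValue}
#'   (one-sample t-test of the mean).
#' @export
calibrateTemplate <- function(frames, shift = 1, floorMethod = "mode",
                              minArea = 30, openingRadius = 1) {
  measurements <- lapply(frames, function(fr) {
    bg <- estimateFloor(fr, floorMethod)
    bct <- computeBCT(bg, shift, calibration(fr))
    mask <- filterSmallParticles(binarize(fr, bct), minArea, openingRadius)
    parts <- labelParticles(mask)
    if (nrow(parts) == 0L) {
      warning("no particle found in frame '", frameId(fr),
              "': frame skipped")
      return(NULL)
    }
    parts[which.max(parts$pixelCount), ]
  })
  measurements <- do.call(rbind, measurements)
  if (is.null(measurements) || nrow(measurements) < 2L)
    stop("calibration requires at least 2 frames with a measurable particle")
  if (shift == 1) {
    shape <- "ellipse"
    feats <- list(`major axis` = measurements$ellipseMajor,
                  `minor axis` = measurements$ellipseMinor)
  } else {
    shape <- "triangle"
    feats <- list(base = measurements$rectLong,
                  height = measurements$rectShort)
  }
  stats <- do.call(rbind, lapply(names(feats), function(fn) {
    x <- feats[[fn]]
    n <- length(x)
    m <- mean(x)
    s <- stats::sd(x)
    se <- s / sqrt(n)
    if (se > 0) {
      tt <- stats::t.test(x)
      ci <- as.numeric(tt$conf.int)
      p <- tt$p.value
    } else {
      ci <- c(m, m)
      p <- NA_real_
    }
    data.frame(shape = shape, feature = fn, n = n, mean = m, se = se,
               ciLow = ci[1L], ciHigh = ci[2L], pValue = p)
  }))
  dims <- roundHalfUp(vapply(feats, mean, numeric(1)))
  template <- if (shape == "ellipse") {
    makeEllipseTemplate(max(dims), min(dims), shift = shift)
  } else {
    makeTriangleTemplate(dims[[1L]], dims[[2L]], shift = shift)
  }
  list(template = template, stats = stats)
}

#' Write a template calibration report
#'
#' Tab-separated report of the calibration statistics: one row per feature
#' with mean, standard error, 95% confidence interval and significance.
#'
#' @param calibrationResult value of [calibrateTemplate()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCalibrationReport <- function(calibrationResult, path) {
  s <- calibrationResult$stats
  out <- data.frame(shape = s$shape, feature = s$feature, n = s$n,
                    mean_se = sprintf("%.1f ± %.1f", s$mean, s$se),
                    ci95 = sprintf("%.1f-%.1f", s$ciLow, s$ciHigh),
                    significance = ifelse(is.na(s$pValue), "n.a.",
                                          ifelse(s$pValue < 0.01, "p < 0.01",
                                                 sprintf("p = %.3f", s$pValue))))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a template
#'
#' The mask is persisted as a PNG image and the shape metadata as a JSON
#' sidecar (\code{<path>.json}).
#'
#' @param template a \linkS4class{HenTemplate}.
#' @param path PNG path for the mask.
#' @return \code{writeTemplate} returns \code{path} invisibly;
#'   \code{readTemplate} returns the \linkS4class{HenTemplate}.
#' @export
writeTemplate <- function(template, path) {
  png::writePNG(template@mask + 0.0, path)
  meta <- sprintf(
    '{"shape": "%s", "dims": [%g, %g], "shiftAssociation": %g}',
    template@shape, template@dims[1L], template@dims[2L],
    template@shiftAssociation)
  writeLines(meta, paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeTemplate
#' @param calibrationIgnored unused; kept for signature symmetry.
#' @export
readTemplate <- function(path, calibrationIgnored = NULL) {
  img <- png::readPNG(path)
  mask <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  meta <- paste(readLines(paste0(path, ".json")), collapse = "")
  shape <- sub('.*"shape": "([a-z]+)".*', "\\1", meta)
  dims <- as.numeric(strsplit(
    sub('.*"dims": \\[([^]]+)\\].*', "\\1", meta), ",")[[1L]])
  shiftA <- as.numeric(sub('.*"shiftAssociation": ([0-9.]+).*', "\\1", meta))
  new("HenTemplate", mask = mask, shape = shape, dims = dims,
      shiftAssociation = shiftA)
}
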