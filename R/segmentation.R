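## Image pre-processing chain: histogram -> floor estimate -> Background
## Color Threshold -> binarization -> small-particle filter -> colored-pixel
## count -> particle measurement.

#' Intensity histogram of a frame
#'
#' Exact frequency distribution of grey levels 0..255.
#'
#' @param frame a \linkS4class{ThermalFrame} or grey-level matrix.
#' @return integer vector of length 256 (names \code{"0"}..\code{"255"});
#'   \code{sum(counts)} equals the pixel count.
#' @export
computeHistogram <- function(frame) {
  px <- if (is(frame, "ThermalFrame")) frame@pixels else frame
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

#' Estimate the floor (background) temperature of a frame
#'
#' The intensity histogram of a frame of the empty floor is unimodal and
#' centred on the background intensity, so a location statistic of the
#' histogram estimates the floor temperature. \code{"mode"} takes the grey
#' level with the highest count (ties broken toward the lowest level);
#' \code{"trimmed-mean"} takes the count-weighted mean of the levels inside
#' the central 80% of the histogram mass. The mode equals the mean for a
#' symmetric unimodal background and stays robust when hens occupy a large
#' image fraction.
#'
#' @param frame a \linkS4class{ThermalFrame}.
#' @param method \code{"mode"} (default) or \code{"trimmed-mean"}.
#' @return list with \code{floorTemperature} (degC), \code{floorIntensity}
#'   (grey level), and \code{method}.
#' @export
estimateFloor <- function(frame, method = c("mode", "trimmed-mean")) {
  method <- match.arg(method)
  counts <- computeHistogram(frame)
  cal <- calibration(frame)
  if (method == "mode") {
    level <- unname(which.max(counts)) - 1L   # lowest level on ties
  } else {
    cum <- cumsum(counts) / sum(counts)
    lo <- which(cum > 0.10)[1L] - 1L
    hi <- which(cum >= 0.90)[1L] - 1L
    keep <- (lo:hi) + 1L
    level <- sum((lo:hi) * counts[keep]) / sum(counts[keep])
  }
  temp <- temperatureOf(level, cal)
  list(floorTemperature = temp,
       floorIntensity = as.integer(intensityOf(temp, cal)),
       method = method)
}

#' Background Color Threshold
#'
#' Adds a fixed temperature shift to the estimated floor temperature and
#' converts the result to a grey level: the adaptive threshold that
#' separates warm (hen) pixels from the floor. A shift that saturates at
#' level 255 makes detection impossible; the result then carries
#' \code{attr(, "saturated") == TRUE} and a warning is emitted so a
#' monitoring run can continue.
#'
#' @param bg floor estimate from [estimateFloor()].
#' @param shift temperature shift in degC, > 0 (1, 2 and 3 degC are the
#'   calibrated operating points; 1 degC is the default set-up).
#' @param cal a \linkS4class{ThermalCalibration}.
#' @return integer grey level with attribute \code{saturated}.
#' @export
computeBCT <- function(bg, shift, cal = thermalCalibration()) {
  if (length(shift) != 1L || shift <= 0)
    stop("'shift' must be a single positive temperature in degC")
  level <- intensityOf(bg$floorTemperature + shift, cal)
  if (any(attr(level, "saturated")))
    warning("BCT saturated at grey level 255: no pixel can exceed it")
  level
}

#' Binarize a frame against a threshold
#'
#' Pixels strictly above the Background Color Threshold become foreground.
#'
#' @param frame a \linkS4class{ThermalFrame} or grey-level matrix.
#' @param bct grey level in [0, 255].
#' @return integer 0/1 matrix with the frame's raster.
#' @export
binarize <- function(frame, bct) {
  px <- if (is(frame, "ThermalFrame")) frame@pixels else frame
  if (bct < 0 || bct > 255) stop("'bct' must lie in [0, 255]")
  mask <- matrix(0L, nrow(px), ncol(px))
  mask[px > bct] <- 1L
  mask
}

#' Remove small particles from a binary mask
#'
#' Morphological opening with a disc structuring element followed by removal
#' of 8-connected components below an area cut. Suppresses noise speckle and
#' small residual-heat artifacts (foot imprints, small warm patches) before
#' pixel counting and pattern recognition. Idempotent; never adds foreground.
#'
#' @param mask integer 0/1 matrix.
#' @param minArea components with fewer pixels are dropped (default 30).
#' @param openingRadius disc radius in pixels for the opening (default 1;
#'   0 skips the opening).
#' @return filtered 0/1 matrix.
#' @export
filterSmallParticles <- function(mask, minArea = 30, openingRadius = 1) {
  mask <- asBinaryMask(mask)
  if (minArea < 0 || openingRadius < 0)
    stop("'minArea' and 'openingRadius' must be >= 0")
  if (openingRadius > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(openingRadius) + 1L, "disc")
    mask <- matrix(as.integer(EBImage::opening(mask, kern) > 0),
                   nrow(mask), ncol(mask))
  }
  if (minArea > 0 && any(mask == 1L)) {
    lab <- cpp_label8(mask)
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L])
      drop <- which(areas < minArea)
      if (length(drop)) mask[lab %in% drop] <- 0L
    }
  }
  mask
}

#' Count foreground ("colored") pixels
#'
#' @param mask integer 0/1 matrix.
#' @return the exact number of 1-pixels (CP).
#' @export
countColoredPixels <- function(mask) {
  sum(asBinaryMask(mask) == 1L)
}

#' Measure connected particles
#'
#' Labels 8-connected foreground components and measures each: pixel area,
#' centroid, equivalent ellipse (the ellipse with the same normalized second
#' central moments as the component; axis length = 4 sqrt(eigenvalue), with
#' a 1/12 unit-pixel variance correction so single-pixel-wide shapes keep a
#' positive minor axis), and the oriented bounding rectangle aligned with
#' the principal axes.
#'
#' @param mask integer 0/1 matrix.
#' @return data.frame with one row per particle: \code{particle},
#'   \code{pixelCount}, \code{centroidRow}, \code{centroidCol},
#'   \code{ellipseMajor}, \code{ellipseMinor}, \code{rectLong},
#'   \code{rectShort}, \code{orientation} (degrees of the major axis from
#'   the column direction, in [0, 180)).
#' @export
labelParticles <- function(mask) {
  mask <- asBinaryMask(mask)
  lab <- cpp_label8(mask)
  n <- max(lab)
  out <- data.frame(particle = integer(0), pixelCount = integer(0),
                    centroidRow = numeric(0), centroidCol = numeric(0),
                    ellipseMajor = numeric(0), ellipseMinor = numeric(0),
                    rectLong = numeric(0), rectShort = numeric(0),
                    orientation = numeric(0))
  if (n == 0L) return(out)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  labs <- lab[idx]
  for (k in seq_len(n)) {
    sel <- labs == k
    r <- rows[sel]; c <- cols[sel]
    a <- length(r)
    mr <- mean(r); mc <- mean(c)
    ## central second moments with the unit-square pixel correction
    srr <- sum((r - mr)^2) / a + 1 / 12
    scc <- sum((c - mc)^2) / a + 1 / 12
    src <- sum((r - mr) * (c - mc)) / a
    cov <- matrix(c(srr, src, src, scc), 2L)
    e <- eigen(cov, symmetric = TRUE)
    major <- 4 * sqrt(max(e$values[1L], 0))
    minor <- 4 * sqrt(max(e$values[2L], 0))
    v <- e$vectors[, 1L]  # (row, col) components of the major axis
    ang <- atan2(v[1L], v[2L]) * 180 / pi
    ang <- ang %% 180
    ## oriented rectangle: extent of the component along the principal axes
    along <- (r - mr) * v[1L] + (c - mc) * v[2L]
    across <- (r - mr) * v[2L] - (c - mc) * v[1L]
    out[k, ] <- list(k, a, mr, mc, major, minor,
                     diff(range(along)) + 1, diff(range(across)) + 1, ang)
  }
  out
}
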