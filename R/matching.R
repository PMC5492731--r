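## Template matching: raw cross-correlation and normalized cross-correlation
## (NCC) with a rotation search. Matching operates on the filtered binary
## mask, whose 0/1 values are treated as real intensities.

#' Raw cross-correlation surface
#'
#' \code{C(i, j) = sum_{x, y} t(x, y) p(x + i, y + j)}, evaluated at every
#' placement where the template lies fully inside the image ("valid" mode).
#' Sensitive to absolute intensities; kept as the elementary correlation
#' primitive and as a reference for the normalized matcher.
#'
#' @param image numeric matrix (rows x cols).
#' @param template numeric matrix, no larger than \code{image} in either
#'   dimension.
#' @return numeric matrix of size
#'   \code{(nrow(image)-nrow(template)+1) x (ncol(image)-ncol(template)+1)};
#'   entry \code{[i, j]} scores the placement with the template's top-left
#'   pixel over \code{image[i, j]}.
#' @seealso [normalizedCrossCorrelation()]
#' @export
crossCorrelation <- function(image, template) {
  image <- as.matrix(image); template <- as.matrix(template)
  if (nrow(template) > nrow(image) || ncol(template) > ncol(image))
    stop("template dimensions exceed image dimensions")
  cpp_cross_correlation(matrix(as.double(image), nrow(image)),
                        matrix(as.double(template), nrow(template)))
}

## Valid-mode cross-correlation of `image` with kernel `t0` via the circular
## cross-correlation theorem (template zero-padded to the image raster).
validCorrFFT <- function(image, t0) {
  H <- nrow(image); W <- ncol(image)
  h <- nrow(t0); w <- ncol(t0)
  tp <- matrix(0, H, W)
  tp[1:h, 1:w] <- t0
  full <- Re(fft(fft(image) * Conj(fft(tp)), inverse = TRUE)) / (H * W)
  full[1:(H - h + 1), 1:(W - w + 1), drop = FALSE]
}

#' Normalized cross-correlation surface
#'
#' For each valid placement, both the template and the overlapped image
#' window are mean-subtracted and the correlation is divided by the product
#' of their root sums of squares, giving a score \code{R} in [-1, 1] that is
#' invariant to affine changes of image intensity (gain and offset). Windows
#' with constant image content have an undefined score and return 0 by
#' convention, so blank regions never match.
#'
#' The cross term is computed by FFT and the window statistics by integral
#' images, so the cost is a few FFTs of the image raster per call.
#'
#' @inheritParams crossCorrelation
#' @return numeric score surface, same layout as [crossCorrelation()].
#' @export
normalizedCrossCorrelation <- function(image, template) {
  image <- as.matrix(image) * 1.0; template <- as.matrix(template) * 1.0
  if (nrow(template) > nrow(image) || ncol(template) > ncol(image))
    stop("template dimensions exceed image dimensions")
  t0 <- template - mean(template)
  st2 <- sum(t0^2)
  if (st2 <= 0) stop("constant template: normalized correlation undefined")
  h <- nrow(template); w <- ncol(template)
  n <- h * w
  cross <- validCorrFFT(image, t0)
  s1 <- boxSum(image, h, w)
  s2 <- boxSum(image^2, h, w)
  varp <- pmax(s2 - s1^2 / n, 0)
  denom <- sqrt(st2 * varp)
  ## threshold scaled to the window magnitude: constant windows -> R = 0
  eps <- sqrt(st2) * sqrt(n) * 1e-9
  R <- matrix(0, nrow(cross), ncol(cross))
  ok <- denom > eps
  R[ok] <- cross[ok] / denom[ok]
  R
}

## Precompute the rotated variants of a template for a fixed image raster:
## rotated cropped masks, their zero-mean kernels and sums of squares.
prepareRotations <- function(template, angles, rasterDim) {
  mask <- if (is(template, "HenTemplate")) template@mask else template
  lapply(angles, function(a) {
    rot <- rotateMask(mask, a)
    if (nrow(rot) > rasterDim[1L] || ncol(rot) > rasterDim[2L])
      stop(sprintf("rotated template (%d x %d) exceeds the %d x %d raster",
                   nrow(rot), ncol(rot), rasterDim[1L], rasterDim[2L]))
    list(angle = a, mask = rot)
  })
}

#' Match a template in a binary mask over a rotation grid
#'
#' Evaluates the normalized cross-correlation of the (rotated) template at
#' every valid placement and every requested angle and keeps the global
#' maximum. Ties are broken by the lowest angle, then the lowest (row, col)
#' placement, so results are deterministic.
#'
#' @param mask integer 0/1 matrix (the filtered binary frame).
#' @param template a \linkS4class{HenTemplate} or 0/1 matrix.
#' @param threshold acceptance score in (0, 1]; the match is declared found
#'   when the best score reaches it.
#' @param angles rotation grid in degrees. Defaults to 0-165 in steps of 15
#'   for elliptical templates (180 degree symmetry) and 0-345 for triangles.
#' @return list with \code{found} (logical), \code{score} (best R),
#'   \code{location} (row, col of the best top-left placement), and
#'   \code{angle} (degrees).
#' @export
matchTemplate <- function(mask, template, threshold = 0.5, angles = NULL) {
  mask <- asBinaryMask(mask)
  if (is.null(angles)) angles <- defaultAngles(template)
  if (length(angles) == 0L) stop("'angles' must be non-empty")
  if (threshold <= 0 || threshold > 1) stop("'threshold' must lie in (0, 1]")
  rots <- prepareRotations(template, angles, dim(mask))
  best <- list(found = FALSE, score = -Inf,
               location = c(NA_integer_, NA_integer_), angle = NA_real_)
  for (rot in rots) {
    R <- normalizedCrossCorrelation(mask, rot$mask)
    mx <- max(R)
    if (mx > best$score + 1e-12) {
      cand <- which(R == mx, arr.ind = TRUE)
      hit <- cand[order(cand[, 1L], cand[, 2L])[1L], ]  # lowest (row, col)
      best$score <- mx
      best$location <- as.integer(hit)
      best$angle <- rot$angle
    }
  }
  if (!is.finite(best$score)) best$score <- 0
  best$found <- best$score >= threshold
  best
}

defaultAngles <- function(template) {
  shape <- if (is(template, "HenTemplate")) template@shape else "ellipse"
  if (shape == "triangle") seq(0, 345, by = 15) else seq(0, 165, by = 15)
}
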