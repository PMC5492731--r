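## Internal numeric helpers shared across modules.

## Round half away from zero (the convention used for reported percentages;
## base round() rounds half to even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Sliding-window sums of all h x w windows of x (valid placements only),
## via zero-padded 2D cumulative sums. Output (nrow(x)-h+1) x (ncol(x)-w+1).
boxSum <- function(x, h, w) {
  cs <- matrix(0, nrow(x) + 1L, ncol(x) + 1L)
  cc <- apply(x, 2L, cumsum)
  if (nrow(x) == 1L) cc <- matrix(cc, nrow = 1L)
  rc <- apply(cc, 1L, cumsum)
  if (ncol(x) == 1L) rc <- matrix(rc, nrow = 1L)
  cs[-1L, -1L] <- t(rc)
  nr <- nrow(x) - h + 1L
  nc <- ncol(x) - w + 1L
  cs[(1L + h):(nr + h), (1L + w):(nc + w), drop = FALSE] -
    cs[(1L + h):(nr + h), 1L:nc, drop = FALSE] -
    cs[1L:nr, (1L + w):(nc + w), drop = FALSE] +
    cs[1L:nr, 1L:nc, drop = FALSE]
}

## Rotate a binary mask by `angle` degrees and crop to the tight bounding box
## of its foreground. Convention: at angle a, a shape axis originally along
## the column direction points along the unit vector (sin a, cos a) in
## (row, col) coordinates. Nearest-neighbour inverse mapping.
rotateMask <- function(mask, angle) {
  a <- angle * pi / 180
  if (abs(a) < 1e-12) return(cropMask(mask))
  h <- nrow(mask); w <- ncol(mask)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  ## output canvas large enough for any rotation of the h x w box
  H <- ceiling(abs((h - 1) * cos(a)) + abs((w - 1) * sin(a))) + 1L
  W <- ceiling(abs((h - 1) * sin(a)) + abs((w - 1) * cos(a))) + 1L
  CR <- (H + 1) / 2; CC <- (W + 1) / 2
  dr <- matrix(seq_len(H) - CR, H, W)
  dc <- matrix(seq_len(W) - CC, H, W, byrow = TRUE)
  ## inverse rotation of target offsets back into source coordinates
  sr <- round(dr * cos(a) - dc * sin(a) + cr)
  sc <- round(dr * sin(a) + dc * cos(a) + cc)
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  out <- matrix(0L, H, W)
  out[ok] <- mask[cbind(sr[ok], sc[ok])]
  cropMask(out)
}

## Crop a binary mask to the tight bounding box of its 1-pixels.
cropMask <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) return(mask)
  mask[rows[1L]:rows[length(rows)], cols[1L]:cols[length(cols)], drop = FALSE]
}

## Coerce a 0/1 matrix, validating values.
asBinaryMask <- function(mask) {
  if (is(mask, "HenTemplate")) mask <- mask@mask
  if (!is.matrix(mask)) stop("binary mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("binary mask must contain only 0 and 1")
  storage.mode(mask) <- "integer"
  mask
}

## Derive a 32-bit-safe child seed from a base seed and a stream index.
childSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}
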