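## Shared fixtures and independent brute-force oracles used across tests.

defaultCal <- thermalCalibration(0, 0.1)

## Frame with a flat floor at `level` plus arbitrary painted regions.
flatFrame <- function(level = 80L, nrow = 24L, ncol = 32L,
                      cal = defaultCal, id = "fixture") {
  thermalFrame(matrix(as.integer(level), nrow, ncol), cal, frameId = id)
}

## Quadruple-loop raw cross-correlation (valid placements), the direct
## transcription of the summation definition.
ccOracle <- function(image, template) {
  h <- nrow(template); w <- ncol(template)
  out <- matrix(0, nrow(image) - h + 1L, ncol(image) - w + 1L)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    acc <- 0
    for (x in seq_len(h)) for (y in seq_len(w))
      acc <- acc + template[x, y] * image[i + x - 1L, j + y - 1L]
    out[i, j] <- acc
  }
  out
}

## Direct per-window normalized cross-correlation.
nccOracle <- function(image, template) {
  h <- nrow(template); w <- ncol(template)
  t0 <- template - mean(template)
  st <- sqrt(sum(t0^2))
  out <- matrix(0, nrow(image) - h + 1L, ncol(image) - w + 1L)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    p <- image[i:(i + h - 1L), j:(j + w - 1L)]
    p0 <- p - mean(p)
    sp <- sqrt(sum(p0^2))
    out[i, j] <- if (sp > 1e-12) sum(t0 * p0) / (st * sp) else 0
  }
  out
}

## Queue-based 8-connected flood fill; returns per-component pixel counts.
floodFillAreas <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextLab <- 0L
  areas <- integer(0)
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] == 0L || lab[i, j] != 0L) next
    nextLab <- nextLab + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nextLab
    count <- 0L
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      count <- count + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- cur[1L] + di; nj <- cur[2L] + dj
        if (ni >= 1L && ni <= nrow(mask) && nj >= 1L && nj <= ncol(mask) &&
            mask[ni, nj] == 1L && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nextLab
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
    areas <- c(areas, count)
  }
  areas
}

## Brute-force binary morphological opening with a (2r+1)-square-inscribed
## disc: erosion (brush must fit entirely in the foreground) then dilation.
openingOracle <- function(mask, radius) {
  brush <- EBImage::makeBrush(2L * radius + 1L, "disc")
  offs <- which(brush == 1, arr.ind = TRUE) - radius - 1L
  h <- nrow(mask); w <- ncol(mask)
  fits <- function(i, j) {
    for (k in seq_len(nrow(offs))) {
      ni <- i + offs[k, 1L]; nj <- j + offs[k, 2L]
      if (ni < 1L || ni > h || nj < 1L || nj > w || mask[ni, nj] == 0L)
        return(FALSE)
    }
    TRUE
  }
  eroded <- matrix(0L, h, w)
  for (j in seq_len(w)) for (i in seq_len(h))
    if (mask[i, j] == 1L && fits(i, j)) eroded[i, j] <- 1L
  dilated <- matrix(0L, h, w)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (eroded[i, j] == 1L) {
      for (k in seq_len(nrow(offs))) {
        ni <- i + offs[k, 1L]; nj <- j + offs[k, 2L]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w) dilated[ni, nj] <- 1L
      }
    }
  }
  dilated
}
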