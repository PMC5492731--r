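test_that("histogram counts every pixel exactly", {
  fr <- flatFrame(7L, 2L, 2L)
  h <- computeHistogram(fr)
  expect_identical(h[["7"]], 4L)
  expect_identical(sum(h), 4L)
  h2 <- computeHistogram(matrix(c(0L, 0L, 255L, 255L), 2))
  expect_identical(h2[["0"]], 2L)
  expect_identical(h2[["255"]], 2L)
  set.seed(11)
  px <- matrix(sample(0:255, 240 * 320, replace = TRUE), 240, 320)
  h3 <- computeHistogram(px)
  tally <- vapply(0:255, function(L) sum(px == L), integer(1))
  expect_identical(unname(h3), tally)
  expect_identical(sum(h3), length(px))
})

test_that("floor estimate recovers constant backgrounds across the ambient range", {
  for (t in seq(5, 13, by = 1)) {
    fr <- flatFrame(as.integer(intensityOf(t, defaultCal)))
    for (m in c("mode", "trimmed-mean")) {
      bg <- estimateFloor(fr, m)
      expect_equal(bg$floorTemperature, t, tolerance = 1e-9)
      expect_identical(bg$floorIntensity,
                       as.integer(intensityOf(bg$floorTemperature,
                                              defaultCal)))
    }
  }
})

test_that("floor estimate is robust to a hot blob on a noisy floor", {
  scene <- sceneConfig(seed = 21,
                       artifactRates = c(footprint = 0, egg = 0,
                                         hotpatch = 0))
  errs <- vapply(0:99, function(i) {
    fr <- renderFrame(scene, i, henCount = 1L)$frame
    abs(estimateFloor(fr, "mode")$floorTemperature - 8.0)
  }, numeric(1))
  expect_lte(max(errs), 0.2)
})

test_that("the background color threshold applies the shift through the calibration", {
  bg <- list(floorTemperature = 8.0, floorIntensity = 80L, method = "mode")
  expect_identical(as.integer(computeBCT(bg, 1.0, defaultCal)), 90L)
  expect_identical(as.integer(computeBCT(bg, 3.0, defaultCal)), 110L)
  expect_error(computeBCT(bg, 0), "positive")
  hot <- list(floorTemperature = 25.4, floorIntensity = 254L,
              method = "mode")
  expect_warning(lvl <- computeBCT(hot, 2.0, defaultCal), "saturated")
  expect_identical(as.integer(lvl), 255L)
  expect_true(attr(lvl, "saturated"))
})

test_that("binarization is a strict threshold", {
  fr <- matrix(c(89L, 91L, 90L, 120L), 2)
  expect_identical(binarize(fr, 90), matrix(c(0L, 1L, 0L, 1L), 2))
  expect_identical(binarize(fr, 255), matrix(0L, 2, 2))
  expect_identical(binarize(fr, 0), matrix(1L, 2, 2))
  ## equivalence with a naive double loop, and CP monotone in the threshold
  set.seed(5)
  for (rep in 1:20) {
    px <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    bct <- sample(0:255, 1)
    naive <- matrix(0L, 32, 32)
    for (i in 1:32) for (j in 1:32) if (px[i, j] > bct) naive[i, j] <- 1L
    expect_identical(binarize(px, bct), naive)
  }
  px <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  cps <- vapply(0:255, function(b) countColoredPixels(binarize(px, b)),
                integer(1))
  expect_true(all(diff(cps) <= 0))
})

test_that("particle filter removes small blobs, keeps large ones, and is idempotent", {
  mask <- matrix(0L, 40, 40)
  mask[5:6, 5] <- 1L; mask[6, 6] <- 1L      # 3-pixel blob
  expect_identical(sum(filterSmallParticles(mask, minArea = 30)), 0L)
  mask2 <- matrix(0L, 80, 80)
  mask2[3:7, 3:4] <- 1L                      # area 10
  mask2[20:69, 20:59] <- 1L                  # area 2000
  filtered <- filterSmallParticles(mask2, minArea = 30, openingRadius = 1)
  expect_identical(sum(filtered[3:7, 3:4]), 0L)
  expect_gte(sum(filtered), 48 * 38)
  ## idempotence on random blobby masks
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(rbinom(60 * 60, 1, 0.4), 60, 60)
    once <- filterSmallParticles(m, minArea = 20, openingRadius = 1)
    twice <- filterSmallParticles(once, minArea = 20, openingRadius = 1)
    expect_identical(twice, once)
    expect_lte(sum(once), sum(m))
  }
})

test_that("opening matches a brute-force erosion-dilation oracle", {
  mask <- matrix(0L, 60, 44)
  mask[6:55, 8:37] <- 1L                     # solid 50 x 30 rectangle
  opened <- filterSmallParticles(mask, minArea = 0, openingRadius = 1)
  expect_identical(opened, openingOracle(mask, 1L))
  expect_gte(sum(opened), 48 * 28)
  set.seed(13)
  m <- matrix(0L, 30, 30)
  m[cbind(sample(3:28, 40, TRUE), sample(3:28, 40, TRUE))] <- 1L
  m[10:20, 10:20] <- 1L
  expect_identical(filterSmallParticles(m, minArea = 0, openingRadius = 1),
                   openingOracle(m, 1L))
})

test_that("colored pixel count is exact", {
  expect_identical(countColoredPixels(matrix(0L, 10, 10)), 0L)
  tpl <- makeEllipseTemplate(135, 63)
  expect_identical(countColoredPixels(templateMask(tpl)),
                   sum(templateMask(tpl) == 1L))
})

test_that("particle measurement recovers planted geometry", {
  ## axis-aligned rectangle: oriented bounding sides within a pixel
  mask <- matrix(0L, 160, 160)
  mask[31:70, 21:120] <- 1L                  # 40 rows x 100 cols
  p <- labelParticles(mask)
  expect_identical(nrow(p), 1L)
  expect_identical(p$pixelCount, 4000L)
  expect_lt(abs(p$rectLong - 100), 1.01)
  expect_lt(abs(p$rectShort - 40), 1.01)
  ## filled ellipse: equivalent-ellipse axes near the analytic axes
  em <- templateMask(makeEllipseTemplate(135, 63))
  canvas <- matrix(0L, 240, 320)
  canvas[51:(50 + nrow(em)), 81:(80 + ncol(em))] <- em
  pe <- labelParticles(canvas)
  expect_lt(abs(pe$ellipseMajor - 135), 3)
  expect_lt(abs(pe$ellipseMinor - 63), 2)
  ## two disjoint blobs: per-component areas match a flood-fill oracle
  two <- matrix(0L, 50, 50)
  two[5:10, 5:10] <- 1L
  two[30:45, 20:40] <- 1L
  pt <- labelParticles(two)
  expect_identical(nrow(pt), 2L)
  expect_setequal(pt$pixelCount, floodFillAreas(two))
})

test_that("equivalent ellipse axes stay within 5% under arbitrary rotation", {
  set.seed(17)
  for (rep in 1:8) {
    major <- runif(1, 40, 150)
    minor <- runif(1, 10, major * 0.9)
    ang <- runif(1, 0, 180)
    em <- templateMask(makeEllipseTemplate(round(major), round(minor)))
    rot <- hentherm:::rotateMask(em, ang)
    canvas <- matrix(0L, 260, 260)
    canvas[40 + seq_len(nrow(rot)) - 1, 40 + seq_len(ncol(rot)) - 1] <- rot
    p <- labelParticles(canvas)
    p <- p[which.max(p$pixelCount), ]
    expect_lt(abs(p$ellipseMajor - round(major)) / round(major), 0.05)
    expect_lt(abs(p$ellipseMinor - round(minor)) / round(minor), 0.05)
  }
})
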