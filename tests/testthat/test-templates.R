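test_that("ellipse templates rasterize to the analytic area and box", {
  tpl <- makeEllipseTemplate(135, 63)
  m <- templateMask(tpl)
  expect_identical(dim(m), c(64L, 136L))
  expect_lt(abs(sum(m) - pi * 67.5 * 31.5) / (pi * 67.5 * 31.5), 0.02)
  ## circle: 4-fold symmetry
  circ <- templateMask(makeEllipseTemplate(11, 11))
  expect_identical(circ, circ[nrow(circ):1, ])
  expect_identical(circ, circ[, ncol(circ):1])
  expect_identical(circ, t(circ))
  ## smallest legal template is non-empty
  expect_gte(sum(templateMask(makeEllipseTemplate(3, 3))), 1)
  expect_error(makeEllipseTemplate(5, 2), "major >= minor >= 3")
})

test_that("triangle templates are isosceles with the analytic area", {
  tpl <- makeTriangleTemplate(35, 16)
  m <- templateMask(tpl)
  expect_lt(abs(sum(m) - 35 * 16 / 2) / (35 * 16 / 2), 0.10)
  expect_identical(dim(templateMask(makeTriangleTemplate(18, 12))),
                   c(12L, 18L))
  ## mirror symmetry about the vertical centerline
  expect_identical(m, m[, ncol(m):1])
  ## base at the bottom is the widest row
  expect_identical(which.max(rowSums(m)), nrow(m))
  expect_error(makeTriangleTemplate(2, 10), "base >= 3")
})

test_that("rasterized areas converge to the analytic area at scale", {
  for (dims in list(c(60, 30), c(100, 50), c(150, 70))) {
    a <- sum(templateMask(makeEllipseTemplate(dims[1], dims[2])))
    expect_lt(abs(a - pi * dims[1] * dims[2] / 4) / (pi * dims[1] * dims[2] / 4),
              0.02)
  }
  for (dims in list(c(60, 40), c(120, 60))) {
    a <- sum(templateMask(makeTriangleTemplate(dims[1], dims[2])))
    expect_lt(abs(a - dims[1] * dims[2] / 2) / (dims[1] * dims[2] / 2), 0.05)
  }
})

test_that("template calibration recovers planted hen geometry", {
  scene <- sceneConfig(seed = 2026,
                       artifactRates = c(footprint = 0, egg = 0,
                                         hotpatch = 0))
  frames <- lapply(0:29, function(i)
    renderFrame(scene, i, henCount = 1L, henDeltaT = 2.5)$frame)
  res <- calibrateTemplate(frames, shift = 1)
  dims <- templateDims(res$template)
  expect_identical(templateShape(res$template), "ellipse")
  expect_lte(abs(dims[1] - 135), 3)
  expect_lte(abs(dims[2] - 63), 3)
  st <- res$stats
  expect_identical(st$feature, c("major axis", "minor axis"))
  expect_true(all(st$ciLow < st$mean & st$mean < st$ciHigh))
  expect_true(all(st$se > 0))
  expect_true(all(st$n == 30))
  ## the interval tracks the axes actually planted in these frames
  planted <- do.call(rbind, lapply(0:29, function(i)
    renderFrame(scene, i, henCount = 1L, henDeltaT = 2.5)$truth$hens))
  expect_true(st$ciLow[1] < mean(planted$major) &&
                mean(planted$major) < st$ciHigh[1])
  expect_true(st$ciLow[2] < mean(planted$minor) &&
                mean(planted$minor) < st$ciHigh[2])
})

test_that("larger shifts calibrate a head-scale triangular template", {
  scene <- sceneConfig(seed = 99,
                       artifactRates = c(footprint = 0, egg = 0,
                                         hotpatch = 0))
  frames <- lapply(0:19, function(i)
    renderFrame(scene, i, henCount = 1L, henDeltaT = 2.5)$frame)
  res <- calibrateTemplate(frames, shift = 3)
  expect_identical(templateShape(res$template), "triangle")
  ## head disc of radius 12: sides near its diameter
  expect_lte(abs(templateDims(res$template)[1] - 24), 5)
  expect_lte(abs(templateDims(res$template)[2] - 24), 5)
})

test_that("degenerate calibrations are handled explicitly", {
  scene <- sceneConfig(seed = 4,
                       artifactRates = c(footprint = 0, egg = 0,
                                         hotpatch = 0))
  one <- renderFrame(scene, 0, henCount = 1L)$frame
  ## identical frames: zero variance, dims equal the single measurement
  res <- calibrateTemplate(list(one, one, one), shift = 1)
  expect_true(all(res$stats$se == 0))
  expect_true(all(is.na(res$stats$pValue)))
  single <- labelParticles(filterSmallParticles(binarize(
    one, computeBCT(estimateFloor(one), 1, defaultCal))))
  biggest <- single[which.max(single$pixelCount), ]
  expect_identical(templateDims(res$template),
                   unname(c(round(biggest$ellipseMajor),
                            round(biggest$ellipseMinor))))
  ## frames with no particle are skipped with a warning; too few -> error
  empty <- renderFrame(scene, 1, henCount = 0L)$frame
  expect_warning(
    res2 <- calibrateTemplate(list(one, one, empty), shift = 1),
    "no particle")
  expect_error(suppressWarnings(calibrateTemplate(list(empty, empty), 1)),
               "at least 2 frames")
})

test_that("calibration reports and template files round-trip", {
  scene <- sceneConfig(seed = 12,
                       artifactRates = c(footprint = 0, egg = 0,
                                         hotpatch = 0))
  frames <- lapply(0:4, function(i)
    renderFrame(scene, i, henCount = 1L)$frame)
  res <- calibrateTemplate(frames, shift = 1)
  report <- withr::local_tempfile(fileext = ".tsv")
  writeCalibrationReport(res, report)
  tab <- read.delim(report)
  expect_identical(names(tab), c("shape", "feature", "n", "mean_se",
                                 "ci95", "significance"))
  expect_identical(nrow(tab), 2L)
  tplPath <- withr::local_tempfile(fileext = ".png")
  writeTemplate(res$template, tplPath)
  back <- readTemplate(tplPath)
  expect_identical(templateMask(back), templateMask(res$template))
  expect_identical(templateShape(back), "ellipse")
  expect_identical(templateDims(back), unname(templateDims(res$template)))
})
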