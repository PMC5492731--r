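test_that("the HD decision rule matches its truth table", {
  ## detection = pattern match OR colored pixels strictly above the CPT
  expect_identical(hentherm:::hdFlag(TRUE,  2000, 1736), 1L)
  expect_identical(hentherm:::hdFlag(TRUE,  0,    1736), 1L)
  expect_identical(hentherm:::hdFlag(FALSE, 2089, 1736), 1L)
  expect_identical(hentherm:::hdFlag(FALSE, 1525, 1736), 0L)
  expect_identical(hentherm:::hdFlag(FALSE, 1736, 1736), 0L)  # strict
  for (matched in c(TRUE, FALSE)) for (above in c(TRUE, FALSE)) {
    cp <- if (above) 1737L else 1736L
    expect_identical(hentherm:::hdFlag(matched, cp, 1736),
                     as.integer(matched || cp > 1736))
  }
})

test_that("detection results satisfy the decision invariant end to end", {
  cal <- defaultCal
  cfg <- detectorConfig(openingRadius = 0)
  mkframe <- function(paint) {
    px <- matrix(80L, 240, 320)
    thermalFrame(paint(px), cal, frameId = "constructed")
  }
  ## long thin bar, 11 x 190 minus one corner pixel: 2089 warm pixels,
  ## nothing ellipse-shaped -> fallback fires
  bar <- mkframe(function(px) {
    px[100:110, 60:249] <- 105L; px[100, 60] <- 80L; px
  })
  rbar <- detectFrame(bar, cfg)
  expect_false(rbar$matched)
  expect_identical(rbar$cp, 2089L)
  expect_identical(rbar$hd, 1L)
  ## thin 5 x 305 bar: 1525 warm pixels, below the CPT -> negative
  thin <- mkframe(function(px) { px[118:122, 10:314] <- 105L; px })
  rthin <- detectFrame(thin, cfg)
  expect_false(rthin$matched)
  expect_identical(rthin$cp, 1525L)
  expect_identical(rthin$hd, 0L)
  ## a hen-shaped blob matches regardless of its pixel count
  em <- templateMask(makeEllipseTemplate(135, 63))
  hen <- mkframe(function(px) {
    px[61:(60 + nrow(em)), 101:(100 + ncol(em))][em == 1L] <- 105L; px
  })
  rhen <- detectFrame(hen, cfg)
  expect_true(rhen$matched)
  expect_identical(rhen$hd, 1L)
  for (r in list(rbar, rthin, rhen))
    expect_identical(r$hd, as.integer(r$matched || r$cp > cfg@cpt))
})

test_that("detection is a pure function of frame and config", {
  fr <- renderFrame(sceneConfig(seed = 6), 0, henCount = 1L)$frame
  cfg <- detectorConfig()
  a <- detectFrame(fr, cfg)
  b <- detectFrame(fr, cfg)
  expect_identical(a, b)
})

test_that("a saturated threshold warns but still classifies", {
  hot <- thermalFrame(matrix(250L, 60, 60), defaultCal, frameId = "hot")
  cfg <- detectorConfig(template = makeEllipseTemplate(11, 7), shift = 2)
  res <- detectFrame(hot, cfg)
  expect_gte(length(res$warnings), 1L)
  expect_match(res$warnings[1], "saturated")
  expect_identical(res$hd, 0L)
})

test_that("monitoring groups frames into slots and logs one record each", {
  scene <- sceneConfig(seed = 14)
  occ <- rep(c(0L, 1L), each = 5)
  seqr <- renderSequence(scene, 10, occupancy = occ)
  log <- withr::local_tempfile(fileext = ".tsv")
  recs <- runMonitoring(seqr$frames, detectorConfig(), logPath = log)
  expect_identical(nrow(recs), 10L)
  expect_identical(names(recs),
                   c("slot_start", "slot_end", "hd", "cp", "bct", "shift_c",
                     "template_id", "ncc_score", "warnings"))
  ## log round-trip reproduces every field
  back <- readMonitoringLog(log)
  back$warnings[is.na(back$warnings)] <- ""
  expect_equal(back, recs, tolerance = 1e-6)
  ## slot duration is the configured two seconds
  starts <- as.POSIXct(recs$slot_start, format = "%Y-%m-%dT%H:%M:%OS",
                       tz = "UTC")
  ends <- as.POSIXct(recs$slot_end, format = "%Y-%m-%dT%H:%M:%OS",
                     tz = "UTC")
  expect_true(all(abs(as.numeric(ends - starts, units = "secs") - 2) < 1e-6))
})

test_that("multi-frame slots aggregate with any-frame-positive logic", {
  scene <- sceneConfig(seed = 15, artifactRates = c(footprint = 0, egg = 0,
                                                    hotpatch = 0))
  empty <- renderFrame(scene, 0, 0L)$frame
  hen <- renderFrame(scene, 1, 1L)$frame
  t0 <- as.POSIXct("2026-01-01", tz = "UTC")
  setTs <- function(fr, secs) {
    fr@timestamp <- t0 + secs
    fr
  }
  frames <- list(setTs(empty, 0), setTs(hen, 1),    # slot 1: hen in frame 2
                 setTs(empty, 2), setTs(empty, 3))  # slot 2: empty
  recs <- runMonitoring(frames, detectorConfig())
  expect_identical(recs$hd, c(1L, 0L))
  expect_identical(nrow(recs), 2L)
})

test_that("an empty frame source yields a valid header-only log", {
  log <- withr::local_tempfile(fileext = ".tsv")
  recs <- runMonitoring(list(), detectorConfig(), logPath = log)
  expect_identical(nrow(recs), 0L)
  expect_identical(readLines(log), paste(
    c("slot_start", "slot_end", "hd", "cp", "bct", "shift_c",
      "template_id", "ncc_score", "warnings"), collapse = "\t"))
  expect_identical(nrow(readMonitoringLog(log)), 0L)
})

test_that("monitoring reads frames back from a directory", {
  dir <- withr::local_tempdir()
  scene <- sceneConfig(seed = 16)
  seqr <- renderSequence(scene, 4, occupancy = c(1L, 0L, 1L, 0L), dir = dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 4L)
  recs <- runMonitoring(dir, detectorConfig())
  expect_identical(nrow(recs), 4L)
  inMem <- renderSequence(scene, 4, occupancy = c(1L, 0L, 1L, 0L))
  recs2 <- runMonitoring(inMem$frames, detectorConfig())
  expect_identical(recs$hd, recs2$hd)
  expect_identical(recs$cp, recs2$cp)
})
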