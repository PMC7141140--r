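test_that("all generators emit on-screen, validation-clean sequences", {
  scr <- testScreen()
  for (gs in generatorGallery(scr)) {
    expect_true(all(gazeValid(gs)))
    expect_equal(length(validateGaze(gs, scr, "drop")), length(gs))
  }
})

test_that("generators are bitwise deterministic under a fixed seed", {
  scr <- testScreen()
  a <- generatorGallery(scr, seed = 5)
  b <- generatorGallery(scr, seed = 5)
  for (k in names(a)) expect_identical(as.data.frame(a[[k]]),
                                       as.data.frame(b[[k]]))
  m1 <- genMovieWithText(scr, rate = 50, nTexts = 2, seed = 9)
  m2 <- genMovieWithText(scr, rate = 50, nTexts = 2, seed = 9)
  expect_identical(as.data.frame(m1$gaze), as.data.frame(m2$gaze))
  expect_identical(m1$textIntervals, m2$textIntervals)
})

test_that("fixation generator honors durations, dispersion and rate", {
  scr <- testScreen()
  # dispersion 0: every sample sits exactly on the center
  lay0 <- FixationLayout(cbind(500, 300), durations = 1, dispersion = 0)
  gs0 <- genFixationSaccade(lay0, scr, rate = 100, seed = 1)
  expect_length(gs0, 100L)
  expect_true(all(gazeX(gs0) == 500 & gazeY(gs0) == 300))
  # total sample count is the sum of per-fixation counts
  lay <- FixationLayout(rbind(c(100, 100), c(600, 400), c(1000, 600)),
                        durations = c(0.25, 0.5, 0.3), dispersion = 5)
  gs <- genFixationSaccade(lay, scr, rate = 60, seed = 2)
  expect_length(gs, sum(round(c(0.25, 0.5, 0.3) * 60)))
  expect_error(
    genFixationSaccade(FixationLayout(cbind(-10, 50), 1), scr, seed = 1),
    "off screen")
})

test_that("off-diagonal fixation blocks reflect the center distance", {
  scr <- ScreenGeometry(1000, 1000)
  sep <- function(d) rbind(c(300, 500), c(300 + d, 500))
  offBlockMean <- function(d, seed) {
    lay <- FixationLayout(sep(d), durations = 0.3, dispersion = 8)
    gs <- genFixationSaccade(lay, scr, rate = 100, seed = seed)
    m <- gsspValues(computeGSSP(gs, scr))
    mean(m[1:30, 31:60])
  }
  N <- normalizationFactor(scr)
  for (d in c(100, 500)) {
    vals <- vapply(1:20, function(s) offBlockMean(d, s), numeric(1))
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - d / N), 3 * se + 1e-3)
  }
})

test_that("smooth pursuit moves at constant speed and recurs across repeats", {
  scr <- testScreen()
  straight <- rbind(c(100, 100), c(1100, 100))
  gs <- genSmoothPursuit(straight, scr, speed = 500, rate = 100, noise = 0,
                         seed = 3)
  step <- sqrt(diff(gazeX(gs))^2 + diff(gazeY(gs))^2)
  expect_equal(step, rep(5, length(step)), tolerance = 1e-9) # speed / rate
  # along a row, distance grows monotonically with |i - j|
  m <- gsspValues(computeGSSP(gs, scr))
  expect_true(all(diff(m[1, ]) > 0))
  # two traversals: gssp(i, i + P) = 0
  rep2 <- genSmoothPursuit(straight, scr, speed = 500, rate = 100, noise = 0,
                           repeats = 2, seed = 3)
  P <- length(rep2) / 2
  m2 <- gsspValues(computeGSSP(rep2, scr))
  expect_true(all(abs(m2[cbind(1:P, 1:P + P)]) < 1e-12))
  expect_error(genSmoothPursuit(rbind(c(1, 1), c(1, 1)), scr), "zero-length")
})

test_that("reading is downward-only vertically with one sweep per line break", {
  scr <- testScreen()
  lay <- ReadingLayout(seq(0.2, 0.8, length.out = 5) * yMax(scr),
                       xStart = 0.1 * xMax(scr), xEnd = 0.9 * xMax(scr),
                       jitter = 0)
  gs <- genReading(lay, scr, rate = 100, seed = 4)
  vh <- gsspValues(computeGSSPVH(gs, scr))
  expect_true(all(vh[lower.tri(vh)] >= 0))  # vertical only downwards
  width <- 0.8 * xMax(scr)
  sweeps <- sum(diff(gazeX(gs)) < -width / 2)
  expect_equal(sweeps, 4L)                  # line_count - 1
})

test_that("backward reading mirrors the forward horizontal profile", {
  scr <- testScreen()
  fwd <- ReadingLayout(c(300, 400), xStart = 200, xEnd = 1000, jitter = 0)
  bwd <- ReadingLayout(c(300, 400), xStart = 200, xEnd = 1000, jitter = 0,
                       direction = "backward")
  vf <- gsspValues(computeGSSPVH(genReading(fwd, scr, seed = 1), scr))
  vb <- gsspValues(computeGSSPVH(genReading(bwd, scr, seed = 1), scr))
  up <- upper.tri(vf)
  # mirrored layout: horizontal directed distances negate, vertical unchanged
  expect_equal(vb[up], -vf[up], tolerance = 1e-9)
  expect_equal(vb[lower.tri(vb)], vf[lower.tri(vf)], tolerance = 1e-9)
})

test_that("outlier injection brightens the injected row of the plot", {
  scr <- ScreenGeometry(1000, 1000)
  lay <- FixationLayout(cbind(500, 500), durations = 1, dispersion = 5)
  tight <- genFixationSaccade(lay, scr, rate = 100, seed = 6)
  # count = 0 leaves the sequence untouched
  expect_identical(as.data.frame(injectOutliers(tight, scr, count = 0)),
                   as.data.frame(tight))
  out <- injectOutliers(tight, scr, count = 1, minOffset = 400, seed = 7)
  idx <- gazeMetadata(out)$outlierIndices
  expect_length(idx, 1L)
  m <- gsspValues(computeGSSP(out, scr))
  expect_gt(mean(m[idx, ]), mean(m))       # the bright cross
  expect_error(injectOutliers(tight, scr, count = 1, minOffset = 1e6),
               "unreachable")
})

test_that("movie simulation returns a plausible schedule", {
  scr <- testScreen()
  mv <- genMovieWithText(scr, rate = 50, nTexts = 3, seed = 11)
  iv <- mv$textIntervals
  expect_equal(nrow(iv), 3L)
  expect_true(all(iv$t_end - iv$t_start >= 7 - 0.1 &
                  iv$t_end - iv$t_start <= 9 + 0.1))
  expect_true(all(diff(as.vector(rbind(iv$t_start, iv$t_end))) > 0))
  dur <- max(gazeTimes(mv$gaze))
  expect_gt(dur, max(iv$t_end))            # closing pursuit break exists
  expect_true(all(gazeValid(mv$gaze)))
})
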