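# Independent brute-force oracles and fixture builders. These deliberately
# use naive double loops so they stay independent of the vectorized
# implementation they check.

# Naive pairwise Euclidean distance matrix, normalized by the screen diagonal.
naiveGSSP <- function(x, y, xmax, ymax) {
  n <- length(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) /
        sqrt(xmax^2 + ymax^2)
    }
  }
  out
}

# Naive co-occurrence counter over a level matrix: walks every cell, checks
# domain membership of both the cell and its offset partner explicitly.
naiveCooccurrence <- function(lv, K, dx, dy, part) {
  n <- nrow(lv)
  inDomain <- function(r, c) {
    if (r < 1 || r > n || c < 1 || c > n) return(FALSE)
    switch(part, full = TRUE, H = r < c, V = r > c)
  }
  freq <- matrix(0, K + 1, K + 1)
  npair <- 0
  for (r in seq_len(n)) {
    for (c in seq_len(n)) {
      if (!inDomain(r, c)) next
      r2 <- r + dx; c2 <- c + dy
      if (!inDomain(r2, c2)) next
      a <- lv[r, c]; b <- lv[r2, c2]
      freq[a + 1, b + 1] <- freq[a + 1, b + 1] + 1
      npair <- npair + 1
    }
  }
  if (npair > 0) freq <- freq / npair
  list(freq = freq, pairCount = npair)
}

# Random on-screen gaze sequence.
randomGaze <- function(n, screen, seed) {
  withr::with_seed(seed, GazeSequence(
    x = stats::runif(n, 0, xMax(screen)),
    y = stats::runif(n, 0, yMax(screen)),
    rate = 100))
}

# One instance of every synthetic generator archetype, used by roundtrip and
# validation-cleanliness properties.
generatorGallery <- function(screen, seed = 42) {
  lay <- FixationLayout(rbind(c(200, 150), c(900, 600), c(250, 160)),
                        durations = c(0.3, 0.4, 0.3), dispersion = 12)
  rlay <- ReadingLayout(seq(0.25, 0.75, length.out = 4) * yMax(screen),
                        xStart = 0.15 * xMax(screen),
                        xEnd = 0.85 * xMax(screen), dwell = 0.1)
  blay <- ReadingLayout(rlay@lineY, rlay@xStart, rlay@xEnd, dwell = 0.1,
                        direction = "backward")
  wp <- rbind(c(100, 100), c(1000, 200), c(600, 600))
  list(
    fixations = genFixationSaccade(lay, screen, rate = 100, seed = seed),
    pursuit = genSmoothPursuit(wp, screen, speed = 600, rate = 100,
                               noise = 2, repeats = 2, seed = seed),
    reading = genReading(rlay, screen, rate = 100, seed = seed),
    readingBackward = genReading(blay, screen, rate = 100, seed = seed),
    outliers = injectOutliers(
      genFixationSaccade(lay, screen, rate = 100, seed = seed),
      screen, count = 3, minOffset = 300, seed = seed + 1))
}

testScreen <- function() ScreenGeometry(1280, 720)
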