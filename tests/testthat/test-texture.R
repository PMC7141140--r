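test_that("discretization floors onto 0..K with 1 mapping to K", {
  scr <- ScreenGeometry(100, 100)
  m <- computeGSSP(GazeSequence(x = c(0, 100), y = c(0, 100)), scr)
  d <- discretizeGSSP(m, K = 10)
  expect_equal(levelValues(d), matrix(c(0L, 10L, 10L, 0L), 2, 2))
  # floor semantics on an intermediate value
  m2 <- computeGSSP(GazeSequence(x = c(0, 34.9), y = c(0, 0)),
                    ScreenGeometry(80, 60))  # dist 34.9 / N=100 -> 0.349
  expect_equal(levelValues(discretizeGSSP(m2, K = 10))[1, 2], 3L)
  expect_error(discretizeGSSP(m, K = 0), "positive integer")
})

test_that("directed discretization uses magnitude by default, signed on demand", {
  scr <- ScreenGeometry(100, 100)
  vh <- computeGSSPVH(GazeSequence(x = c(60, 10), y = c(10, 60)), scr)
  # dx = -0.5 (leftward), dy = +0.5 (downward)
  d <- discretizeGSSP(vh, K = 10)
  expect_equal(levelValues(d)[1, 2], 5L)   # |-0.5| * 10
  expect_equal(levelValues(d)[2, 1], 5L)
  ds <- discretizeGSSP(vh, K = 10, signed = TRUE)
  expect_equal(levelValues(ds)[1, 2], 2L)  # floor((-0.5 + 1) / 2 * 10)
  expect_equal(levelValues(ds)[2, 1], 7L)  # floor((0.5 + 1) / 2 * 10)
  expect_equal(levelValues(ds)[1, 1], 5L)  # zero maps mid-scale
})

test_that("co-occurrence counts match hand enumeration", {
  mk <- function(lv, K) new("DiscretizedMatrix", levels = lv, K = as.integer(K),
                            signed = FALSE, directed = FALSE)
  # constant matrix: all mass at (0,0)
  cm <- cooccurrence(mk(matrix(0L, 3, 3), 10), c(0, 1), "full")
  expect_equal(cmFreq(cm)[1, 1], 1)
  expect_equal(sum(cmFreq(cm)), 1)
  # 2x2 with distinct levels, offset (0,1): pairs (0,1) and (2,3)
  lv <- matrix(c(0L, 2L, 1L, 3L), 2, 2)  # rows: [0 1; 2 3]
  cm2 <- cooccurrence(mk(lv, 3), c(0, 1), "full")
  expect_equal(pairCount(cm2), 2)
  expect_equal(cmFreq(cm2)[1, 2], 0.5)   # a=0,b=1
  expect_equal(cmFreq(cm2)[3, 4], 0.5)   # a=2,b=3
  expect_equal(sum(cmFreq(cm2)), 1)
  # strict-upper-triangle domain: only the pair fully inside the triangle
  lv3 <- matrix(0L, 3, 3)
  lv3[1, 2] <- 1L; lv3[1, 3] <- 2L; lv3[2, 3] <- 3L
  cm3 <- cooccurrence(mk(lv3, 3), c(0, 1), "H")
  expect_equal(pairCount(cm3), 1)        # (1,2)->(1,3) only
  expect_equal(cmFreq(cm3)[2, 3], 1)     # levels 1 -> 2
  expect_error(cooccurrence(mk(lv3, 3), c(0, 0)), "offset")
  # degenerate domain flagged, not crashed
  cm4 <- cooccurrence(mk(matrix(0L, 1, 1), 3), c(0, 1), "H")
  expect_equal(pairCount(cm4), 0)
})

test_that("co-occurrence equals the naive counter on random matrices", {
  for (seed in 1:8) {
    lvK <- withr::with_seed(seed, {
      n <- sample(2:30, 1)
      K <- sample(1:10, 1)
      list(lv = matrix(sample(0:K, n * n, replace = TRUE), n, n), K = K)
    })
    d <- new("DiscretizedMatrix", levels = lvK$lv, K = as.integer(lvK$K),
             signed = FALSE, directed = FALSE)
    for (part in c("full", "H", "V")) {
      for (off in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 2))) {
        got <- cooccurrence(d, off, part)
        want <- naiveCooccurrence(lvK$lv, lvK$K, off[1], off[2], part)
        expect_equal(pairCount(got), want$pairCount)
        expect_equal(cmFreq(got), want$freq, tolerance = 1e-12)
        if (want$pairCount > 0)
          expect_equal(sum(cmFreq(got)), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("texture metrics match closed-form hand evaluations", {
  mkcm <- function(freq, K, np = 1) new("CooccurrenceMatrix",
    freq = freq, offset = c(0L, 1L), part = "full",
    pairCount = np, K = as.integer(K))
  # constant image
  f0 <- matrix(0, 11, 11); f0[1, 1] <- 1
  expect_equal(homogeneity(mkcm(f0, 10)), 1)
  expect_equal(contrast(mkcm(f0, 10)), 0)
  expect_equal(uniformity(mkcm(f0, 10)), 1)
  # all mass at (0, 10)
  f1 <- matrix(0, 11, 11); f1[1, 11] <- 1
  expect_equal(homogeneity(mkcm(f1, 10)), 1 / 11)
  expect_equal(contrast(mkcm(f1, 10)), 100)
  # K=1, uniform mass on all four cells
  f2 <- matrix(0.25, 2, 2)
  expect_equal(homogeneity(mkcm(f2, 1)), 0.75)
  expect_equal(contrast(mkcm(f2, 1)), 0.5)
  expect_equal(uniformity(mkcm(f2, 1)), 0.25)
  # mass 0.5 on two cells
  f3 <- matrix(0, 2, 2); f3[1, 1] <- 0.5; f3[2, 2] <- 0.5
  expect_equal(uniformity(mkcm(f3, 1)), 0.5)
  # degenerate matrix refuses metrics
  degen <- new("CooccurrenceMatrix", freq = matrix(0, 2, 2),
               offset = c(0L, 1L), part = "H", pairCount = 0, K = 1L)
  expect_error(homogeneity(degen), "degenerate")
})

test_that("metric ranges hold and homogeneity/contrast anti-correlate", {
  scr <- testScreen()
  K <- 10
  hs <- cs <- us <- numeric(0)
  for (seed in 1:15) {
    gs <- randomGaze(withr::with_seed(seed, sample(5:40, 1)), scr, seed + 100)
    cm <- cooccurrence(discretizeGSSP(computeGSSP(gs, scr), K), c(0, 1), "full")
    h <- homogeneity(cm); cc <- contrast(cm); u <- uniformity(cm)
    expect_gte(h, 0); expect_lte(h, 1)
    expect_gte(cc, 0); expect_lte(cc, K^2)
    expect_gte(u, 0); expect_lte(u, 1)
    hs <- c(hs, h); cs <- c(cs, cc); us <- c(us, u)
  }
  expect_lt(stats::cor(hs, cs, method = "spearman"), 0)
})

test_that("feature extraction yields one value per direction/offset/metric", {
  scr <- testScreen()
  gs <- randomGaze(30, scr, seed = 1)
  fv <- featureVector(computeGSSPVH(gs, scr))
  expect_length(fv, 18L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_setequal(
    names(fv),
    as.vector(outer(c("H01", "H10", "H11", "V01", "V10", "V11"),
                    c("contrast", "homogeneity", "uniformity"), paste)))
  # constant gaze: every homogeneity/uniformity 1, every contrast 0
  const <- featureVector(computeGSSPVH(
    GazeSequence(x = rep(100, 10), y = rep(100, 10)), scr))
  expect_true(all(const[grep("homogeneity", names(const))] == 1))
  expect_true(all(const[grep("uniformity", names(const))] == 1))
  expect_true(all(const[grep("contrast", names(const))] == 0))
  # restricting offsets restricts the vector
  fv6 <- featureVector(computeGSSPVH(gs, scr), offsets = list(c(1, 1)))
  expect_length(fv6, 6L)
})

test_that("correlation pruning reports collinear features and drops 18 to 14", {
  scr <- testScreen()
  feats <- t(sapply(1:8, function(s)
    featureVector(computeGSSPVH(randomGaze(40, scr, s), scr))))
  pruned <- pruneCorrelated(feats, threshold = 0.9)
  expect_length(pruned$keep, 14L)
  expect_setequal(pruned$dropped,
                  c("H01 uniformity", "H10 uniformity",
                    "V01 uniformity", "V10 uniformity"))
  # a duplicated column is reported with r = 1
  dup <- feats
  dup[, "H10 contrast"] <- dup[, "H01 contrast"]
  rep <- pruneCorrelated(dup, threshold = 0.9)$report
  row <- rep[rep$key1 == "H01 contrast" & rep$key2 == "H10 contrast", ]
  expect_equal(row$r, 1)
  expect_true(row$flagged)
  # zero-variance column reported as NA, not an error
  zv <- feats
  zv[, "V11 uniformity"] <- 0.5
  repz <- pruneCorrelated(zv, threshold = 0.9)$report
  expect_true(any(is.na(repz$r[repz$key1 == "V01 uniformity" &
                               repz$key2 == "V11 uniformity"])))
  # independent random columns are not flagged
  ind <- withr::with_seed(1, matrix(rnorm(80 * 2), 80, 2,
    dimnames = list(NULL, c("H01 contrast", "H10 contrast"))))
  expect_false(any(pruneCorrelated(ind, threshold = 0.9)$report$flagged))
})

test_that("feature tables export to CSV and JSON", {
  scr <- testScreen()
  fv <- featureVector(computeGSSPVH(randomGaze(20, scr, 3), scr))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  fjson <- withr::local_tempfile(fileext = ".json")
  writeFeatures(t(as.matrix(fv)), fcsv)
  writeFeatures(t(as.matrix(fv)), fjson)
  back <- as.matrix(data.table::fread(fcsv))
  expect_equal(unname(back[1, ]), unname(fv), tolerance = 1e-9)
  expect_equal(names(jsonlite::read_json(fjson)[[1]]), names(fv))
})
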