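test_that("syntheticConfig validates its distributions", {
  expect_s3_class(syntheticConfig(), "SyntheticConfig")
  expect_error(syntheticConfig(ryMix = c(0.5, 0.5)), "5 entries")
  expect_error(syntheticConfig(ryMix = c(0.5, 0.5, 0.5, 0, 0)), "summing")
  expect_error(syntheticConfig(wwMix = c(GC = 1)), "wwMix")
  expect_error(syntheticConfig(spacerMix = c("20" = 1)), "spacer")
  expect_error(syntheticConfig(mismatchRate = 1.5), "mismatchRate")
})

test_that("generators are pure functions of their config and seed", {
  cfg <- syntheticConfig(seed = 7, nRes = 100)
  a <- generateRESet(cfg)
  b <- generateRESet(cfg)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  txA <- generateTransactivation(a$truth, cfg)
  txB <- generateTransactivation(b$truth, cfg)
  expect_identical(txA$truth$ratio, txB$truth$ratio)
  expect_identical(txA$records, txB$records)
  cvA <- generateBindingCurve(230, 1.9, seed = 7)
  cvB <- generateBindingCurve(230, 1.9, seed = 7)
  expect_identical(cvA, cvB)
  # different seed, different draw
  cfg2 <- syntheticConfig(seed = 8, nRes = 100)
  expect_false(identical(as.character(generateRESet(cfg2)$sequences),
                         as.character(a$sequences)))
  # generators restore the global RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generateRESet(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated REs re-score exactly to their recorded truth", {
  cfg <- syntheticConfig(seed = 3, nRes = 200, mismatchRate = 0.3)
  re <- generateRESet(cfg)
  prof <- ryProfile(re$truth$re20)
  expect_identical(prof$ryCount, re$truth$ryCount)
  expect_identical(prof$ww1, re$truth$ww1)
  expect_identical(prof$ww2, re$truth$ww2)
  expect_identical(cbind(prof$ry1, prof$ry2, prof$ry3, prof$ry4),
                   cbind(re$truth$ry1, re$truth$ry2, re$truth$ry3,
                         re$truth$ry4))
  # emitted sequence = re20 with the spacer inserted between half-sites
  expect_identical(unname(as.character(re$sequences))[re$truth$spacer == 0],
                   re$truth$re20[re$truth$spacer == 0])
})

test_that("spacer sampling inserts spacers in sequences but not re20", {
  cfg <- syntheticConfig(seed = 5, nRes = 50,
                         spacerMix = c("0" = 0.5, "2" = 0.3, "13" = 0.2))
  re <- generateRESet(cfg)
  expect_setequal(unique(re$truth$spacer), c(0L, 2L, 13L))
  expect_identical(unname(nchar(as.character(re$sequences))),
                   20L + re$truth$spacer)
  expect_true(all(nchar(re$truth$re20) == 20L))
  withSp <- which(re$truth$spacer > 0)[1]
  s <- as.character(re$sequences)[withSp]
  expect_identical(paste0(substr(s, 1, 10),
                          substr(s, nchar(s) - 9, nchar(s))),
                   re$truth$re20[withSp])
})

test_that("point-mass mixes force the intended signature composition", {
  cfg <- syntheticConfig(seed = 9, nRes = 30,
                         ryMix = c(0, 0, 0, 0, 1),
                         wwMix = c(TT = 1))
  re <- generateRESet(cfg)
  expect_true(all(re$truth$ryCount == 4L))
  expect_true(all(re$truth$ww1 == "TT" & re$truth$ww2 == "TT"))
  pred <- s139fPredict(ryProfile(re$truth$re20))
  expect_true(all(pred$score == 4.5))
  expect_true(all(pred$predictedClass == "enhanced"))
})

test_that("noise-free ratios compose the stated effect model exactly", {
  mkTruth <- function(ry, ww) S4Vectors::DataFrame(
    name = "x", re20 = "GAACATGTTCGAACATGTTC", spacer = 0L,
    ryCount = as.integer(ry), ry1 = FALSE, ry2 = FALSE, ry3 = FALSE,
    ry4 = FALSE, ww1 = ww, ww2 = "AT")
  cfg <- syntheticConfig(seed = 1, nRes = 1, noiseSD = 0, replicateCV = 0)
  ratio <- function(ry, ww)
    generateTransactivation(mkTruth(ry, ww), cfg)$truth$ratio
  expect_equal(ratio(0, "AT"), 0.5)
  expect_equal(ratio(2, "AT"), 0.5 * 1.6^2)  # 1.28, similar
  expect_equal(ratio(3, "AT"), 0.5 * 1.6^3)  # 2.048, enhanced
  expect_equal(ratio(0, "TT"), 0.5 * 1.3)
  cl <- classifyRatio(c(0.5, 1.28, 2.048), 1)$class
  expect_identical(as.character(cl), c("reduced", "similar", "enhanced"))
})

test_that("replicate records reproduce the generated folds when noiseless", {
  cfg <- syntheticConfig(seed = 17, nRes = 20, replicateCV = 0)
  re <- generateRESet(cfg)
  tx <- generateTransactivation(re$truth, cfg)
  cl <- classifyActivities(tx$records)
  m <- match(cl$re_name, tx$truth$name)
  expect_equal(cl$wtFold, tx$truth$wtFold[m], tolerance = 1e-9)
  expect_equal(cl$ratio, tx$truth$ratio[m], tolerance = 1e-9)
  expect_identical(as.character(cl$class), as.character(tx$truth$class[m]))
})

test_that("generateBindingCurve is exact at zero noise", {
  grid <- defaultTitrationGrid()
  expect_length(grid, 18L)
  expect_equal(range(grid), c(0, 20000))
  cv <- generateBindingCurve(230, 1.9, noiseSD = 0, replicates = 2, seed = 2)
  expect_equal(cv$response, rep(hillFraction(grid, 230, 1.9), 2))
})
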