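test_that("fractionBound interpolates linearly and clips", {
  expect_equal(as.numeric(fractionBound(100, 100, 200)), 0)
  expect_equal(as.numeric(fractionBound(200, 100, 200)), 1)
  expect_equal(as.numeric(fractionBound(150, 100, 200)), 0.5)
  f <- fractionBound(c(90, 210), 100, 200)
  expect_equal(as.numeric(f), c(0, 1))
  expect_identical(attr(f, "clipped"), c(TRUE, TRUE))
  expect_error(fractionBound(1, 5, 5), "differ")
})

test_that("hillFraction satisfies the midpoint and limit identities", {
  expect_equal(hillFraction(230, 230, 1.9), 0.5)
  expect_equal(hillFraction(230, 230, 1.9, f0 = 0.1, fmax = 0.9), 0.5)
  expect_equal(hillFraction(9 * 50, 50, 1), 0.9)
  expect_equal(hillFraction(0, 100, 2, f0 = 0.07), 0.07)
  expect_error(hillFraction(-1, 100, 1), "non-negative")
  expect_error(hillFraction(1, 0, 1), "ec50")
  expect_error(hillFraction(1, 10, 0), "hill")
})

test_that("hillFraction is increasing in conc and log-symmetric about ec50", {
  set.seed(51)
  for (i in 1:10) {
    ec <- 10^runif(1, 1, 4)
    h <- runif(1, 0.5, 3)
    conc <- sort(10^runif(20, -1, 5))
    y <- hillFraction(conc, ec, h)
    expect_true(all(diff(y) > 0))
    # f(ec*k) + f(ec/k) = 1 for f0=0, fmax=1
    k <- 10^runif(5, 0.1, 2)
    expect_equal(hillFraction(ec * k, ec, h) + hillFraction(ec / k, ec, h),
                 rep(1, 5))
  }
})

test_that("fitHill recovers noiseless parameters across a seeded grid", {
  conc <- defaultTitrationGrid()
  for (ec in c(10, 230, 4480)) for (h in c(0.5, 1.9, 3)) {
    fit <- fitHill(conc, hillFraction(conc, ec, h, 0.02, 0.95))
    expect_false(isCensored(fit))
    expect_lt(abs(ec50(fit) - ec) / ec, 1e-4)
    expect_lt(abs(hillCoefficient(fit) - h) / h, 1e-4)
    expect_lt(abs(fit@estimates[["f0"]] - 0.02), 1e-4)
    expect_lt(abs(fit@estimates[["fmax"]] - 0.95), 1e-4)
  }
})

test_that("the Hill model nests the hyperbola", {
  conc <- defaultTitrationGrid()
  fit <- fitHill(conc, hillFraction(conc, 500, 1))
  expect_lt(abs(hillCoefficient(fit) - 1), 1e-6)
})

test_that("unsaturated curves are censored with a Kd lower bound", {
  conc <- defaultTitrationGrid()
  fit <- fitHill(conc, hillFraction(conc, 5 * max(conc), 1.5))
  expect_true(isCensored(fit))
  expect_equal(kdLowerBound(fit), max(conc))
  expect_error(fitHill(c(0, 1, 10), c(0, 0.1, 0.4)), "5 distinct")
})

test_that("fitted rss never exceeds the grid-search oracle", {
  for (s in 1:5) {
    cv <- generateBindingCurve(ec50 = c(50, 230, 1540, 4480, 15000)[s],
                               hill = c(1, 1.5, 1.9, 2.5, 0.7)[s],
                               noiseSD = 0.03, replicates = 2, seed = s)
    fit <- fitHill(cv$concentration_nM, cv$response)
    oracle <- oracleHillGridRSS(cv$concentration_nM, cv$response)
    expect_lte(fitRSS(fit), oracle * (1 + 1e-8))
  }
})

test_that("noisy recovery stays within the expected error band", {
  relerr <- vapply(1:40, function(s) {
    cv <- generateBindingCurve(230, 1.9, noiseSD = 0.02, replicates = 3,
                               seed = 400 + s)
    abs(ec50(fitHill(cv$concentration_nM, cv$response)) - 230) / 230
  }, numeric(1))
  expect_lt(median(relerr), 0.15)
})

test_that("affinityRatio reports point ratios and censored bounds", {
  conc <- defaultTitrationGrid()
  fitG <- fitHill(conc, hillFraction(conc, 230, 1.9))
  fitA <- fitHill(conc, hillFraction(conc, 4480, 1.7))
  r <- affinityRatio(fitG, fitA)
  expect_equal(r$ratio, 4480 / 230, tolerance = 1e-3)
  expect_identical(r$qualifier, "none")
  expect_equal(affinityRatio(fitG, fitG)$ratio, 1, tolerance = 1e-9)

  cens <- fitHill(conc, hillFraction(conc, 5 * max(conc), 1.5))
  rb <- affinityRatio(fitG, cens)
  expect_identical(rb$qualifier, ">=")
  expect_equal(rb$ratio, max(conc) / 230, tolerance = 1e-3)
  expect_identical(affinityRatio(cens, fitG)$qualifier, "<=")
  expect_error(affinityRatio(cens, cens), "undefined")
})

test_that("HillFit show method prints the censoring convention", {
  conc <- defaultTitrationGrid()
  out <- capture.output(show(fitHill(conc, hillFraction(conc, 230, 1.9))))
  expect_match(out[2], "Kd")
  cens <- fitHill(conc, hillFraction(conc, 5 * max(conc), 1.5))
  expect_match(capture.output(show(cens))[2], ">")
})

test_that("the depletion model recovers Kd from quadratic-binding data", {
  conc <- defaultTitrationGrid()
  y <- depletionFraction(conc, kd = 100, dnaConc = 50)
  fit <- fitHill(conc, y, depletion = TRUE, dnaConc = 50)
  expect_lt(abs(ec50(fit) - 100) / 100, 1e-4)
  expect_identical(hillCoefficient(fit), 1)
  # at dnaConc << Kd the depletion model reduces to the hyperbola
  expect_equal(depletionFraction(conc, 5000, dnaConc = 1e-4),
               hillFraction(conc, 5000, 1), tolerance = 1e-4)
  expect_error(depletionFraction(conc, -1), "kd")
})
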