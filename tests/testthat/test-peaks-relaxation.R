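test_that("nine-point averaging is the plain 3x3 mean", {
  expect_equal(ninePointAverage(matrix(5, 3, 3), c(2, 2)), 5)
  g <- matrix(1, 3, 3); g[2, 2] <- 10
  expect_equal(ninePointAverage(g, c(2, 2)), 2)
  set.seed(42)
  big <- matrix(rnorm(49), 7, 7)
  for (ctr in list(c(2, 2), c(4, 5), c(6, 6))) {
    brute <- 0
    for (di in -1:1) for (dj in -1:1)
      brute <- brute + big[ctr[1] + di, ctr[2] + dj]
    expect_equal(ninePointAverage(big, ctr), brute / 9, tolerance = 1e-12)
  }
  expect_error(ninePointAverage(big, c(1, 4)), "inside the grid")
  expect_error(ninePointAverage(big, c(4, 7)), "inside the grid")
})

test_that("noiseless decay series are fitted exactly", {
  d <- defaultDelaySchedules()
  series <- synthesizeDecaySeries(rateTable(1, 10), d$r2, i0 = 1000,
                                  noiseSd = 0)
  fit <- fitExponentialRate(series, noiseRmsd = 0, nMc = 0)
  expect_equal(fit$value, 10, tolerance = 1e-4)
  const <- synthesizeDecaySeries(rateTable(2, 0), d$r2, i0 = 500,
                                 noiseSd = 0)
  fit0 <- fitExponentialRate(const, noiseRmsd = 0, nMc = 0)
  expect_equal(fit0$value, 0, tolerance = 1e-6)
})

test_that("rate fitting is scale invariant and uses duplicate delays", {
  d <- defaultDelaySchedules()$r1
  series <- synthesizeDecaySeries(rateTable(7, 1.8), d, i0 = 1000,
                                  noiseSd = 5, seed = 3)
  f1 <- fitExponentialRate(series, noiseRmsd = 0, nMc = 0)
  series2 <- series
  series2$intensity <- series2$intensity * 37.5
  f2 <- fitExponentialRate(series2, noiseRmsd = 0, nMc = 0)
  expect_equal(f1$value, f2$value, tolerance = 1e-7)
  expect_equal(f1$nPoints, length(d))  # duplicates kept as observations
})

test_that("degenerate series are flagged rather than fitted", {
  bad <- data.frame(residue = 1, delay_s = c(0, 0.1, 0.2),
                    intensity = c(-5, -1, -3))
  fit <- fitExponentialRate(bad, noiseRmsd = 0, nMc = 0)
  expect_true(fit$masked)
  expect_true(is.na(fit$value))
})

test_that("Monte-Carlo rate errors track the empirical spread", {
  d <- defaultDelaySchedules()$r2
  rTrue <- 10
  nRep <- 200
  fits <- numeric(nRep)
  mcSd <- numeric(nRep)
  for (i in seq_len(nRep)) {
    series <- synthesizeDecaySeries(rateTable(1, rTrue), d, i0 = 1000,
                                    noiseSd = 10, seed = 1000 + i)
    fit <- fitExponentialRate(series, noiseRmsd = 10, nMc = 500,
                              seed = 2000 + i)
    fits[i] <- fit$value
    mcSd[i] <- fit$sd
  }
  empirical <- sd(fits)
  expect_lt(mean(mcSd) / empirical, 1.5)
  expect_gt(mean(mcSd) / empirical, 1 / 1.5)
  # parameter recovery at the default noise level
  expect_lt(median(abs(fits - rTrue) / rTrue), 0.02)
})

test_that("hNOE values and first-order errors behave as specified", {
  out <- computeHnoe(1:3, sat = c(800, 800, 250), ref = c(800, 1000, 1000),
                     noiseRmsd = 10)
  expect_equal(out$value[1], 1)
  expect_equal(out$value[3], 0.25)
  weak <- computeHnoe(1, sat = 5, ref = 25, noiseRmsd = 10)
  expect_true(weak$masked)
  expect_true(is.na(weak$value))
})

test_that("propagated hNOE errors match a large Monte-Carlo draw", {
  sat <- 800; ref <- 1000; sigma <- 10
  out <- computeHnoe(1, sat, ref, sigma)
  set.seed(99)
  draws <- (sat + rnorm(10000, 0, sigma)) / (ref + rnorm(10000, 0, sigma))
  expect_equal(out$sd, sd(draws), tolerance = 0.05)
})

test_that("R2/R1 ratios propagate errors and flag exchange", {
  r2 <- rateTable(1:4, c(8, 2, 4, 20), sd = 0.1)
  r1 <- rateTable(1:4, c(2, 2, 2, 2), sd = 0.1)
  out <- r2OverR1(r2, r1)
  expect_equal(out$value, c(4, 1, 2, 10))
  expect_equal(out$sd,
               out$value * sqrt((0.1 / r2$value)^2 + (0.1 / 2)^2),
               tolerance = 1e-10)
  # ratio profile {2,2,2,10} has mean 4: only the last lies above it
  out2 <- r2OverR1(rateTable(1:4, c(4, 4, 4, 20), sd = 0),
                   rateTable(1:4, rep(2, 4), sd = 0))
  expect_equal(out2$value, c(2, 2, 2, 10))
  expect_equal(out2$aboveMean, c(FALSE, FALSE, FALSE, TRUE))
  r1bad <- rateTable(1, -1, sd = 0.1)
  r2one <- rateTable(1, 8, sd = 0.1)
  expect_true(r2OverR1(r2one, r1bad)$masked)
})
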