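test_that("Gamma2 is the paramagnetic excess with quadrature errors", {
  para <- rateTable(1:3, c(25, 10, 12), sd = 1)
  dia <- rateTable(1:3, c(10, 10, 14), sd = 1)
  out <- computeGamma2(para, dia)
  expect_equal(out$value, c(15, 0, -2))
  expect_equal(out$sd, rep(sqrt(2), 3), tolerance = 1e-9)
  expect_equal(out$negative, c(FALSE, FALSE, TRUE))  # retained, flagged
})

test_that("residues present in only one dataset are masked", {
  out <- computeGamma2(rateTable(1:2, c(25, 30), sd = 1),
                       rateTable(2:3, c(10, 10), sd = 1))
  expect_true(out$masked[out$residue == 1])
  expect_true(out$masked[out$residue == 3])
  expect_false(out$masked[out$residue == 2])
})

test_that("the PRI rate is the dual-label excess over the single sum", {
  both <- rateTable(1:2, c(40, 25), sd = 1)
  a <- rateTable(1:2, c(15, 15), sd = 1)
  b <- rateTable(1:2, c(10, 10), sd = 1)
  out <- computePri(both, a, b)
  expect_equal(out$value, c(15, 0))   # additive case gives zero
  expect_equal(out$sd, rep(sqrt(3), 2), tolerance = 1e-9)
})

test_that("computePri is symmetric and responds to shifts as -s", {
  both <- rateTable(1:5, c(40, 25, 33, 18, 50), sd = 1)
  a <- rateTable(1:5, c(15, 15, 9, 4, 20), sd = 2)
  b <- rateTable(1:5, c(10, 10, 17, 2, 21), sd = 0.5)
  expect_equal(computePri(both, a, b)$value, computePri(both, b, a)$value)
  s <- 7.3
  shift <- function(tb) { tb$value <- tb$value + s; tb }
  shifted <- computePri(shift(both), shift(a), shift(b))
  expect_equal(shifted$value, computePri(both, a, b)$value - s,
               tolerance = 1e-12)
})

test_that("masked inputs propagate into masked PRI", {
  both <- rateTable(1:2, c(40, 40), sd = 1, masked = c(TRUE, FALSE))
  a <- rateTable(1:2, c(15, 15), sd = 1)
  b <- rateTable(1:2, c(10, 10), sd = 1)
  out <- computePri(both, a, b)
  expect_true(out$masked[1])
  expect_false(out$masked[2])
})

test_that("projection-angle regimes follow the sign of the PRI rate", {
  expect_equal(classifyProjectionAngle(15, 2), "aligned")
  expect_equal(classifyProjectionAngle(-19, 2), "orthogonal")
  expect_equal(classifyProjectionAngle(0.5, 2), "magic/indeterminate")
  expect_equal(classifyProjectionAngle(0, 0), "magic/indeterminate")
  expect_equal(classifyProjectionAngle(c(15, -19, 0.5), c(2, 2, 2), z = 2),
               c("aligned", "orthogonal", "magic/indeterminate"))
})

test_that("a compact state at 90 degrees gives a negative measured PRI", {
  v <- computePriRates(angleEnsemble(c(90, 90), rA = 12, rB = 12),
                       226L, 227L)$value[1]
  expect_lt(v, 0)
})

test_that("identical PRI sets show no significant differences", {
  wt <- rateTable(1:20, rnorm(20), sd = 1)
  out <- priDifference(wt, wt, z = 2)
  expect_false(any(out$significant))
  expect_true(all(out$diff[!out$masked] == 0))
})

test_that("clear differences are flagged with a direction", {
  wt <- rateTable(1:2, c(0, 5), sd = 1)
  mut <- rateTable(1:2, c(10, -6), sd = 1)
  out <- priDifference(wt, mut, z = 2)
  expect_true(all(out$significant))
  expect_equal(out$direction, c("increased", "decreased"))
})

test_that("null data keep the false-positive rate near the z = 2 level", {
  set.seed(31)
  nRes <- 60
  mu <- rnorm(nRes, 0, 5)
  rate <- replicate(100, {
    wt <- rateTable(seq_len(nRes), mu + rnorm(nRes), sd = 1)
    mut <- rateTable(seq_len(nRes), mu + rnorm(nRes), sd = 1)
    mean(priDifference(wt, mut, z = 2)$significant)
  })
  expect_lte(mean(rate), 0.05)
})
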