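test_that("Larmor frequencies match the gyromagnetic ratio", {
  w <- larmorFrequencies(700.3)
  expect_equal(round(unname(w["wN"]), 1), 71.0)
  expect_equal(unname(w["wh"]), 0.87 * 700.3, tolerance = 1e-12)
  expect_equal(unname(larmorFrequencies(0)), c(0, 0))
  expect_equal(round(unname(larmorFrequencies(600.13)["wN"]), 2), 60.83)
  expect_error(larmorFrequencies(-1), ">= 0")
})

test_that("a flat spectral density maps onto itself", {
  jStar <- 3e-10
  field <- fieldParameters()
  fw <- forwardRelaxationRates(jStar, jStar, jStar, field)
  out <- reducedSpectralDensities(
    rateTable(1, fw$r1, sd = 0.01), rateTable(1, fw$r2, sd = 0.01),
    rateTable(1, fw$noe, sd = 0.01), field)
  expect_equal(out$j0, jStar, tolerance = 1e-12)
  expect_equal(out$jN, jStar, tolerance = 1e-12)
  expect_equal(out$jh, jStar, tolerance = 1e-12)
})

test_that("the reduced mapping is the exact inverse of the forward model", {
  field <- fieldParameters()
  set.seed(8)
  for (i in 1:25) {
    j0 <- runif(1, 1e-10, 5e-9)
    jN <- runif(1, 1e-11, j0)
    jh <- runif(1, 1e-12, jN)
    fw <- forwardRelaxationRates(j0, jN, jh, field)
    out <- reducedSpectralDensities(
      rateTable(1, fw$r1, sd = 0), rateTable(1, fw$r2, sd = 0),
      rateTable(1, fw$noe, sd = 0), field)
    expect_equal(out$j0, j0, tolerance = 1e-10)
    expect_equal(out$jN, jN, tolerance = 1e-10)
    expect_equal(out$jh, jh, tolerance = 1e-10)
  }
})

test_that("a 4 ns Lorentzian round-trips through the high-field approximation", {
  field <- fieldParameters()
  tau <- 4e-9
  fw <- relaxationFromTauc(tau, field)   # exact five-frequency forward
  out <- reducedSpectralDensities(
    rateTable(1, fw$r1, sd = 0), rateTable(1, fw$r2, sd = 0),
    rateTable(1, fw$noe, sd = 0), field)
  expect_equal(out$j0, 0.4 * tau, tolerance = 0.1)
})

test_that("only J_eff(0) carries transverse-specific contributions", {
  field <- fieldParameters()
  fw <- relaxationFromTauc(1e-9, field)
  base <- reducedSpectralDensities(
    rateTable(1, fw$r1, sd = 0), rateTable(1, fw$r2, sd = 0),
    rateTable(1, fw$noe, sd = 0), field)
  # doubling R2 (or equivalently adding exchange) at fixed R1 and NOE
  more <- reducedSpectralDensities(
    rateTable(1, fw$r1, sd = 0), rateTable(1, 2 * fw$r2, sd = 0),
    rateTable(1, fw$noe, sd = 0), field)
  expect_gt(more$j0, base$j0)
  expect_equal(more$jN, base$jN, tolerance = 1e-14)
  expect_equal(more$jh, base$jh, tolerance = 1e-14)
})

test_that("unphysical NOE values are masked, negative J0 flagged", {
  field <- fieldParameters()
  fw <- relaxationFromTauc(1e-9, field)
  out <- reducedSpectralDensities(
    rateTable(1, fw$r1, sd = 0.01), rateTable(1, fw$r2, sd = 0.01),
    rateTable(1, 1.5, sd = 0.05), field)
  expect_true(out$masked)
  # implausibly small R2 drives J_eff(0) negative: reported, not clipped
  neg <- reducedSpectralDensities(
    rateTable(1, fw$r1, sd = 0), rateTable(1, 0.05 * fw$r2, sd = 0),
    rateTable(1, fw$noe, sd = 0), field)
  expect_true(neg$j0Negative)
  expect_lt(neg$j0, 0)
})

test_that("spectral-density uncertainties follow first-order propagation", {
  field <- fieldParameters()
  fw <- relaxationFromTauc(1.2e-9, field)
  sds <- c(r1 = 0.02, r2 = 0.05, noe = 0.01)
  out <- reducedSpectralDensities(
    rateTable(1, fw$r1, sd = sds["r1"]), rateTable(1, fw$r2, sd = sds["r2"]),
    rateTable(1, fw$noe, sd = sds["noe"]), field)
  set.seed(21)
  nmc <- 20000
  mc <- reducedSpectralDensities(
    rateTable(seq_len(nmc), fw$r1 + rnorm(nmc, 0, sds["r1"]), sd = 0),
    rateTable(seq_len(nmc), fw$r2 + rnorm(nmc, 0, sds["r2"]), sd = 0),
    rateTable(seq_len(nmc), fw$noe + rnorm(nmc, 0, sds["noe"]), sd = 0),
    field)
  expect_equal(out$j0Sd, sd(mc$j0), tolerance = 0.05)
  expect_equal(out$jhSd, sd(mc$jh), tolerance = 0.05)
})
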