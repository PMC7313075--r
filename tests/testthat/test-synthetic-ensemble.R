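test_that("identical config and seed give bitwise-identical ensembles", {
  cfg <- ensembleConfig(nConformers = 60L, seed = 1L)
  e1 <- sampleEnsemble(cfg)
  e2 <- sampleEnsemble(cfg)
  expect_identical(e1@coords, e2@coords)
  expect_identical(e1@labelCoords, e2@labelCoords)
  expect_identical(e1@stateTag, e2@stateTag)
  e3 <- sampleEnsemble(ensembleConfig(nConformers = 60L, seed = 2L))
  expect_false(identical(e1@coords, e3@coords))
})

test_that("chain geometry and weights satisfy the ensemble invariants", {
  ens <- sampleEnsemble(ensembleConfig(nConformers = 40L, seed = 3L))
  for (k in c(1L, 20L, 40L)) {
    xyz <- conformerCoords(ens, k)
    d <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_true(all(abs(d - 3.8) < 1e-6))
  }
  expect_equal(sum(conformerWeights(ens)), 1, tolerance = 1e-12)
  expect_true(all(conformerWeights(ens) >= 0))
})

test_that("zero compact population yields no compact conformers", {
  ens <- sampleEnsemble(ensembleConfig(nConformers = 200L, seed = 4L,
                                       compactPopulation = 0))
  expect_true(all(stateTags(ens) == "major"))
})

test_that("the compact fraction stays within binomial sampling error", {
  nc <- 2000L
  ens <- sampleEnsemble(ensembleConfig(nConformers = nc, seed = 5L,
                                       compactPopulation = 0.05))
  nCompact <- sum(stateTags(ens) == "compact")
  expect_lt(abs(nCompact - 0.05 * nc), 4 * sqrt(nc * 0.05 * 0.95))
})

test_that("fully coupled hinges draw identical bend angles", {
  seg <- cbind(start = c(230L, 240L, 250L), end = c(236L, 246L, 256L))
  n <- 40L
  cfg <- ensembleConfig(nResidues = n, firstResidue = 225L, sequence = "",
                        segments = seg, labelSites = 233L,
                        hingeCoupling = matrix(1, 2, 2),
                        compactPopulation = 0,
                        compactFolds = list(list(bends = numeric(n - 2),
                                                 torsions = numeric(n - 2))),
                        nConformers = 5000L, seed = 6L)
  ens <- sampleEnsemble(cfg)
  a <- hingeAngles(ens)
  expect_gt(cor(a[1, ], a[2, ]), 0.95)
})

test_that("invalid configurations are rejected", {
  overlapping <- cbind(start = c(230L, 234L), end = c(236L, 240L))
  expect_error(ensembleConfig(segments = overlapping), "overlap")
  expect_error(ensembleConfig(nConformers = 1L), "nConformers")
  badCoupling <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  seg <- cbind(start = c(230L, 240L, 250L), end = c(236L, 246L, 256L))
  expect_error(ensembleConfig(segments = seg, hingeCoupling = badCoupling),
               "coupling")
})

test_that("PRE rates follow the Solomon-Bloembergen closed form", {
  params <- forwardParams()
  ens20 <- distanceEnsemble(c(20, 20))
  v20 <- computePreRates(ens20, 225L, params)$value[4]
  expect_equal(v20, 3.08, tolerance = 0.01)
  ens15 <- distanceEnsemble(c(15, 15))
  v15 <- computePreRates(ens15, 225L, params)$value[4]
  expect_equal(v15, 17.3, tolerance = 0.01)
  # the ratio removes the prefactor: exactly (20/15)^6
  expect_equal(v15 / v20, (20 / 15)^6, tolerance = 1e-10)
})

test_that("the ensemble average of r^-6 is linear in conformer weights", {
  params <- forwardParams()
  mixed <- computePreRates(distanceEnsemble(c(15, 20)), 225L, params)$value[4]
  v15 <- computePreRates(distanceEnsemble(c(15, 15)), 225L, params)$value[4]
  v20 <- computePreRates(distanceEnsemble(c(20, 20)), 225L, params)$value[4]
  expect_equal(mixed, (v15 + v20) / 2, tolerance = 1e-12)
})

test_that("prolines and the labelled residue emit no PRE observable", {
  cfg <- ensembleConfig(nConformers = 50L, seed = 7L)
  ens <- sampleEnsemble(cfg)
  pre <- computePreRates(ens, 262L)
  expect_true(pre$masked[pre$residue == 262])
  expect_true(all(pre$masked[pre$residue %in% c(232, 233, 301, 312)]))
  expect_true(all(is.na(pre$value[pre$masked])))
  expect_true(all(pre$value[!pre$masked] >= 0))
})

test_that("PRI obeys the angular contract of the interference term", {
  params <- forwardParams()
  magic <- acos(sqrt(1 / 3)) * 180 / pi
  vMagic <- computePriRates(angleEnsemble(c(magic, magic)), 226L, 227L,
                            params)$value[1]
  v0 <- computePriRates(angleEnsemble(c(0, 0)), 226L, 227L, params)$value[1]
  v90 <- computePriRates(angleEnsemble(c(90, 90)), 226L, 227L,
                         params)$value[1]
  expect_lt(abs(vMagic), 1e-9 * abs(v0))
  expect_gt(v0, 0)
  expect_lt(v90, 0)
  expect_equal(v0 / v90, -2, tolerance = 1e-10)
  # mixed ensemble: 0.3 x (+2) + 0.7 x (-1) = -0.1 of the theta = 0 scale
  vMix <- computePriRates(angleEnsemble(c(0, 90), weights = c(0.3, 0.7)),
                          226L, 227L, params)$value[1]
  expect_equal(vMix, -0.1 * v0 / 2, tolerance = 1e-10)
})

test_that("conformers beyond the interference cutoff contribute zero", {
  params <- forwardParams(priDistanceCutoff = 50)
  near <- angleEnsemble(c(0, 0), rA = 15, rB = 15)
  # antiparallel labels 60 A apart: outside the cutoff, although the
  # angular factor alone would contribute positively
  far <- angleEnsemble(c(180, 180), rA = 30, rB = 30)
  both <- angleEnsemble(c(0, 0), rA = 15, rB = 15)
  both@labelCoords[, , 2] <- far@labelCoords[, , 2]
  vNear <- computePriRates(near, 226L, 227L, params)$value[1]
  vBoth <- computePriRates(both, 226L, 227L, params)$value[1]
  expect_equal(vBoth, vNear / 2, tolerance = 1e-12)
})

test_that("identical labels are rejected for PRI", {
  expect_error(computePriRates(angleEnsemble(c(0, 0)), 226L, 226L),
               "differ")
})

test_that("PRI locality: no compact state and distant labels give zero", {
  params <- forwardParams(priDistanceCutoff = 50)
  far <- angleEnsemble(c(180, 170), rA = 30, rB = 30)
  v <- computePriRates(far, 226L, 227L, params)$value
  expect_true(all(v[!is.na(v)] == 0))
})

test_that("decay series reproduce exact exponentials without noise", {
  tab <- rateTable(1:2, c(10, 0))
  out <- synthesizeDecaySeries(tab, delays = 0.1, i0 = 1000, noiseSd = 0)
  expect_equal(out$intensity[out$residue == 1], 1000 * exp(-1),
               tolerance = 1e-9)
  expect_equal(out$intensity[out$residue == 2], 1000, tolerance = 1e-12)
})

test_that("duplicate delays get distinct replicate numbers", {
  out <- synthesizeDecaySeries(rateTable(1, 5), delays = c(0, 0.032, 0.032),
                               noiseSd = 0)
  expect_equal(out$replicate[out$delay_s == 0.032], c(1L, 2L))
  expect_error(synthesizeDecaySeries(rateTable(1, 5), delays = numeric()),
               "empty")
})

test_that("PRE decays monotonically along a freely jointed control chain", {
  n <- 60L
  cfg <- ensembleConfig(nResidues = n, firstResidue = 1L, sequence = "",
                        segments = matrix(integer(), 0, 2),
                        labelSites = 1L,
                        hingeCoupling = matrix(numeric(), 0, 0),
                        compactPopulation = 0,
                        compactFolds = list(list(bends = numeric(n - 2),
                                                 torsions = numeric(n - 2))),
                        linkerBendSd = 10, linkerTorsionSd = 10,
                        nConformers = 3000L, seed = 11L)
  ens <- sampleEnsemble(cfg)
  d <- prePRI:::labelDistances(ens, 1L)
  r6med <- apply(pmax(d, 5)^-6, 1, median)
  sep <- abs(seq_len(n) - 1L)
  keep <- sep >= 3
  # non-increasing up to the finite-sample wiggle of the median
  x <- r6med[keep]
  expect_true(all(diff(x) <= 0.05 * head(x, -1)))
})
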