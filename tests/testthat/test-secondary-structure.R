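test_that("secondary shifts subtract the packaged random-coil reference", {
  rc <- randomCoilShifts()
  refA <- rc$CA[rc$residueType == "A"]
  expect_equal(secondaryShift(refA, "A", "CA"), 0)
  expect_equal(secondaryShift(51.5, "A", "CA"), 51.5 - refA)
  # glycine carbonyl uses its own reference row, no generic fallback
  refGC <- rc$C[rc$residueType == "G"]
  expect_equal(secondaryShift(refGC, "G", "C"), 0)
  expect_true(is.na(secondaryShift(60, "X", "CA")))
})

test_that("the averaged CaC' index is the exact 3:4 weighted mean", {
  expect_equal(averagedSecondaryShift(7, 7), 7)
  expect_equal(averagedSecondaryShift(0, 0), 0)
  expect_equal(averagedSecondaryShift(-0.7, 0.35), -0.1, tolerance = 1e-12)
  # exact linearity
  expect_equal(averagedSecondaryShift(3 * -0.7, 3 * 0.35), 3 * -0.1,
               tolerance = 1e-12)
  expect_true(is.na(averagedSecondaryShift(NA, 0.5)))
})

test_that("profiles recompute the averaged index from both nuclei", {
  shifts <- syntheticShiftTable("wt", noiseSd = 0, seed = 1)
  prof <- secondaryShiftProfile(shifts)
  expect_equal(prof$dAv, (3 * prof$dCa + 4 * prof$dCp) / 7,
               tolerance = 1e-12)
  dup <- rbind(shifts, shifts[1, ])
  expect_error(secondaryShiftProfile(dup), "one observed shift")
})

test_that("sign runs are classified into beta and turn regions", {
  prof <- data.frame(residue = 1:12, residueType = "A",
                     dCa = c(rep(-1, 6), rep(0.3, 6)) * c(1, 1, 1, 1, 1, 1,
                                                          1, 1, 1, -1, 1, -1),
                     dCp = 0)
  prof$dCa <- c(rep(-1, 6), 0.3, -0.3, 0.3, -0.3, 0.3, -0.3)
  prof$dAv <- (3 * prof$dCa) / 7
  out <- classifyPropensity(prof, minRunBeta = 4, minRunTurn = 3)
  expect_equal(nrow(out$regions), 1)
  expect_equal(out$regions$type, "beta")
  expect_equal(c(out$regions$start, out$regions$end), c(1, 6))
  # alternating signs never form a region
  alt <- data.frame(residue = 1:10, residueType = "A",
                    dCa = rep(c(-1, 1), 5), dCp = rep(c(-1, 1), 5))
  alt$dAv <- (3 * alt$dCa + 4 * alt$dCp) / 7
  expect_equal(nrow(classifyPropensity(alt)$regions), 0)
})

test_that("the planted wild-type profile yields 3 beta and 2 turn regions", {
  prof <- secondaryShiftProfile(syntheticShiftTable("wt", seed = 2))
  out <- classifyPropensity(prof, minRunBeta = 3, minRunTurn = 3)
  beta <- out$regions[out$regions$type == "beta", ]
  turn <- out$regions[out$regions$type == "turn", ]
  expect_equal(nrow(beta), 3)
  expect_equal(beta$start, c(275, 296, 306))
  expect_equal(beta$end, c(280, 298, 311))
  expect_equal(nrow(turn), 2)
  expect_equal(turn$start, c(270, 301))
  # at the published "more than three residues" cut the 3-residue run
  # corresponding to beta3 drops out
  strict <- classifyPropensity(prof, minRunBeta = 4, minRunTurn = 3)
  expect_equal(sum(strict$regions$type == "beta"), 2)
})

test_that("shrinking a planted region removes its call and no other", {
  wt <- classifyPropensity(
    secondaryShiftProfile(syntheticShiftTable("wt", seed = 3)),
    minRunBeta = 3)
  mut <- classifyPropensity(
    secondaryShiftProfile(syntheticShiftTable("p301l", seed = 3)),
    minRunBeta = 3)
  wtBeta <- wt$regions[wt$regions$type == "beta", ]
  mutBeta <- mut$regions[mut$regions$type == "beta", ]
  wt296 <- wtBeta[wtBeta$start == 296, ]
  mut296 <- mutBeta[mutBeta$start >= 295 & mutBeta$start <= 299, ]
  # the beta3-like call weakens: smaller |mean| or gone entirely
  expect_true(nrow(mut296) == 0 || abs(mut296$meanDav) < abs(wt296$meanDav))
  # the amyloid-motif regions survive untouched
  expect_true(all(c(275, 306) %in% mutBeta$start))
})

test_that("the NMR-STAR reader extracts CA and carbonyl rows", {
  path <- system.file("extdata", "synthetic_shifts.str", package = "prePRI")
  tab <- readNmrStar(path)
  expect_equal(nrow(tab), 8)          # CB and N rows are dropped
  expect_setequal(unique(tab$atom), c("CA", "C"))
  expect_equal(tab$shift[tab$residue == 275 & tab$atom == "CA"], 61.1)
  expect_equal(tab$residueType[tab$residue == 276][1], "Q")
  prof <- secondaryShiftProfile(tab)
  expect_equal(nrow(prof), 4)
})
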