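test_that("rate-matrix assembly honours the observability threshold", {
  sets <- list(
    a = rateTable(1:3, c(1, 2, 3)),
    b = rateTable(1:3, c(2, 3, 4)),
    c = rateTable(1:3, c(3, 4, 5)),
    d = rateTable(1:3, c(4, 5, 6), masked = c(FALSE, TRUE, FALSE))
  )
  strict <- assembleRateMatrix(sets, minDatasets = 4)
  expect_equal(residueNumbers(strict), c(1L, 3L))
  loose <- assembleRateMatrix(sets, minDatasets = 2)
  expect_equal(residueNumbers(loose), 1:3)
  expect_error(assembleRateMatrix(sets[1]), "at least two")
})

test_that("correlation values reproduce hand-computed Pearson cases", {
  m <- rbind(`1` = c(1, 2, 3, 4), `2` = c(2, 4, 6, 8),
             `3` = c(8, 6, 4, 2), `4` = c(1, 3, 2, 4))
  rm <- new("RateMatrix", values = m, sds = m * 0,
            observed = matrix(TRUE, 4, 4, dimnames = dimnames(m)))
  map <- correlationMap(rm)
  cc <- corrMatrix(map)
  expect_equal(cc["1", "2"], 1, tolerance = 1e-12)
  expect_equal(cc["1", "3"], -1, tolerance = 1e-12)
  expect_equal(cc["1", "4"], 0.8, tolerance = 1e-12)
  expect_true(all(diag(cc) == 1))
})

test_that("the map agrees with a naive double-loop oracle to 1e-12", {
  set.seed(13)
  for (rep in 1:3) {
    m <- matrix(rnorm(80), 20, 4, dimnames = list(1:20, letters[1:4]))
    rm <- new("RateMatrix", values = m, sds = m * 0,
              observed = matrix(TRUE, 20, 4, dimnames = dimnames(m)))
    cc <- corrMatrix(correlationMap(rm))
    for (i in 1:20) for (j in 1:20) {
      xi <- m[i, ]; xj <- m[j, ]
      cv <- mean((xi - mean(xi)) * (xj - mean(xj)))   # 1/N as printed
      si <- sqrt(mean((xi - mean(xi))^2))
      sj <- sqrt(mean((xj - mean(xj))^2))
      expect_lt(abs(cc[i, j] - cv / (si * sj)), 1e-12)
    }
  }
})

test_that("reordering datasets leaves the map unchanged", {
  set.seed(14)
  m <- matrix(rnorm(48), 12, 4, dimnames = list(1:12, letters[1:4]))
  rm1 <- new("RateMatrix", values = m, sds = m * 0,
             observed = matrix(TRUE, 12, 4, dimnames = dimnames(m)))
  m2 <- m[, c(3, 1, 4, 2)]
  rm2 <- new("RateMatrix", values = m2, sds = m2 * 0,
             observed = matrix(TRUE, 12, 4, dimnames = dimnames(m2)))
  expect_equal(corrMatrix(correlationMap(rm1)),
               corrMatrix(correlationMap(rm2)))
})

test_that("zero-variance residues and sparse pairs are masked quietly", {
  m <- rbind(`1` = c(1, 2, 3, 4), `2` = c(5, 5, 5, 5))
  o <- matrix(TRUE, 2, 4, dimnames = dimnames(m))
  map <- correlationMap(new("RateMatrix", values = m, sds = m * 0,
                            observed = o))
  expect_false(validMask(map)["1", "2"])
  # a pair sharing fewer than two datasets is masked, not an error
  m2 <- rbind(`1` = c(1, 2, NA, NA), `2` = c(NA, 5, 6, 7))
  o2 <- !is.na(m2)
  map2 <- correlationMap(new("RateMatrix", values = m2, sds = m2 * 0,
                             observed = o2))
  expect_false(validMask(map2)["1", "2"])
})

test_that("block-diagonal maps yield one segment per block", {
  m <- matrix(0, 25, 25)
  m[1:10, 1:10] <- 1
  m[16:25, 16:25] <- 1
  diag(m) <- 1
  seg <- detectSegments(mapFromMatrix(m), corrThreshold = 0.5,
                        minLength = 4, bridgeGaps = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$start, c(1, 16))
  expect_equal(seg$end, c(10, 25))
  empty <- detectSegments(mapFromMatrix(diag(25)))
  expect_equal(nrow(empty), 0)
})

test_that("single missing residues are bridged inside a segment", {
  m <- matrix(1, 10, 10)
  keep <- setdiff(1:10, 5)   # residue 5 unobservable
  map <- mapFromMatrix(m[keep, keep], residues = keep)
  seg <- detectSegments(map, bridgeGaps = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(1, 10))
  split <- detectSegments(map, bridgeGaps = FALSE)
  expect_equal(nrow(split), 2)
})

test_that("map comparison reports differences and sign flips", {
  m <- matrix(0.1, 20, 20)
  m[1:8, 1:8] <- 0.9
  m[13:20, 13:20] <- 0.9
  m[1:8, 13:20] <- 0.6
  m[13:20, 1:8] <- 0.6
  diag(m) <- 1
  m2 <- m
  m2[1:8, 13:20] <- -0.4
  m2[13:20, 1:8] <- -0.4
  a <- mapFromMatrix(m)
  b <- mapFromMatrix(m2)
  same <- compareMaps(a, a)
  expect_true(all(same$difference == 0, na.rm = TRUE))
  expect_false(any(same$blocks$signFlip))
  segs <- data.frame(start = c(1, 13), end = c(8, 20))
  cmp <- compareMaps(a, b, segments = segs)
  flip <- cmp$blocks[cmp$blocks$segA == 1 & cmp$blocks$segB == 2, ]
  expect_true(flip$signFlip)
  expect_equal(flip$meanA, 0.6, tolerance = 1e-12)
  expect_equal(flip$meanB, -0.4, tolerance = 1e-12)
  disjoint <- mapFromMatrix(diag(3), residues = 101:103)
  expect_error(compareMaps(a, disjoint), "share no residues")
})
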