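#' Assemble PRE/PRI rate tables into a residues-by-datasets matrix
#'
#' Stacks per-dataset rate tables (one per spin-label or label pair)
#' and keeps residues observable in at least \code{minDatasets}
#' datasets.  The default keeps only residues observable in every
#' dataset; correlation maps in the style of the published figures use
#' \code{minDatasets = 2}.
#'
#' @param rateSets named list of rate tables (columns \code{residue},
#'   \code{value}, \code{sd}, \code{masked}).
#' @param minDatasets minimal number of unmasked datasets per residue
#'   (default: all datasets).
#' @return a \linkS4class{RateMatrix}.
#' @export
assembleRateMatrix <- function(rateSets, minDatasets = length(rateSets)) {
  if (length(rateSets) < 2) stop("at least two rate sets are required")
  if (is.null(names(rateSets)))
    names(rateSets) <- paste0("dataset", seq_along(rateSets))
  resAll <- sort(unique(unlist(lapply(rateSets, `[[`, "residue"))))
  nd <- length(rateSets)
  V <- S <- matrix(NA_real_, length(resAll), nd,
                   dimnames = list(resAll, names(rateSets)))
  O <- matrix(FALSE, length(resAll), nd,
              dimnames = list(resAll, names(rateSets)))
  for (k in seq_len(nd)) {
    tb <- rateSets[[k]]
    idx <- match(tb$residue, resAll)
    V[idx, k] <- tb$value
    S[idx, k] <- tb$sd
    O[idx, k] <- !tb$masked & is.finite(tb$value)
  }
  V[!O] <- NA_real_
  keep <- rowSums(O) >= minDatasets
  new("RateMatrix", values = V[keep, , drop = FALSE],
      sds = S[keep, , drop = FALSE], observed = O[keep, , drop = FALSE])
}

#' Inter-residue correlation map across spin-label datasets
#'
#' For residues \eqn{i, j} with rates \eqn{R_{ik}} over datasets
#' \eqn{k = 1..N}:
#' \deqn{cov_{i,j} = \frac{1}{N}\sum_k (R_{ik}-R_{i0})(R_{jk}-R_{j0}),
#'   \qquad corr_{i,j} = cov_{i,j}/(\sigma_i\sigma_j)}
#' with means \eqn{R_{i0}} and population (1/N) standard deviations
#' \eqn{\sigma_i}.  For residues not observed in every dataset, the
#' statistics run over the datasets the pair has in common; pairs
#' sharing fewer than two datasets, and residues with zero variance,
#' are masked rather than raising an error.  The diagonal is 1
#' wherever defined.
#'
#' @param rateMatrix a \linkS4class{RateMatrix}.
#' @return a \linkS4class{CorrelationMap}.
#' @export
correlationMap <- function(rateMatrix) {
  V <- rateMatrix@values
  O <- rateMatrix@observed
  n <- nrow(V)
  res <- rownames(V)
  cc <- matrix(NA_real_, n, n, dimnames = list(res, res))
  ok <- matrix(FALSE, n, n, dimnames = list(res, res))
  complete <- all(O)
  if (complete) {
    mu <- rowMeans(V)
    Vc <- V - mu
    sig <- sqrt(rowMeans(Vc^2))
    good <- sig > 0
    covm <- tcrossprod(Vc) / ncol(V)
    cc <- covm / tcrossprod(sig)
    cc[!good, ] <- NA_real_
    cc[, !good] <- NA_real_
    ok <- outer(good, good, `&`)
  } else {
    for (i in seq_len(n)) {
      for (j in i:n) {
        common <- O[i, ] & O[j, ]
        if (sum(common) < 2) next
        xi <- V[i, common]; xj <- V[j, common]
        si <- sqrt(mean((xi - mean(xi))^2))
        sj <- sqrt(mean((xj - mean(xj))^2))
        if (si == 0 || sj == 0) next
        cv <- mean((xi - mean(xi)) * (xj - mean(xj)))
        cc[i, j] <- cc[j, i] <- cv / (si * sj)
        ok[i, j] <- ok[j, i] <- TRUE
      }
    }
  }
  cc[ok] <- pmin(pmax(cc[ok], -1), 1)   # guard rounding at +-1
  diag(cc)[diag(ok)] <- 1
  new("CorrelationMap", corr = cc, valid = ok)
}

## mean pairwise correlation over the valid pairs among `idx`
meanPairCorr <- function(map, idx) {
  if (length(idx) < 2) return(NA_real_)
  sub <- map@corr[idx, idx, drop = FALSE]
  subOk <- map@valid[idx, idx, drop = FALSE]
  up <- upper.tri(sub)
  vals <- sub[up & subOk]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Detect locally correlated segments on a correlation map
#'
#' Greedy scan for maximal runs of consecutive residues whose mean
#' pairwise correlation stays at or above \code{corrThreshold}.
#' Residues absent from the map (prolines, label sites, overlapped
#' peaks) can be bridged when the gap does not exceed
#' \code{bridgeGaps} residues, mirroring how segment boxes are drawn
#' across unobservable positions.  Runs shorter than \code{minLength}
#' observed residues are discarded.
#'
#' @param map a \linkS4class{CorrelationMap}.
#' @param corrThreshold minimal mean intra-run correlation
#'   (default 0.5).
#' @param minLength minimal number of observed residues per segment
#'   (default 4).
#' @param bridgeGaps maximal number of consecutive missing residues to
#'   bridge (default 2, enough for the adjacent prolines of the
#'   proline-rich region; \code{TRUE} is taken as 1, \code{FALSE} as
#'   0).
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{nResidues}, \code{meanCorr}; zero rows when nothing is
#'   found.
#' @export
detectSegments <- function(map, corrThreshold = 0.5, minLength = 4,
                           bridgeGaps = 2L) {
  if (is.logical(bridgeGaps)) bridgeGaps <- if (bridgeGaps) 1L else 0L
  res <- residueNumbers(map)
  res <- res[order(res)]
  usable <- res[vapply(as.character(res),
                       function(r) map@valid[r, r], logical(1))]
  segs <- list()
  i <- 1L
  while (i <= length(usable)) {
    run <- usable[i]
    j <- i
    while (j < length(usable)) {
      nxt <- usable[j + 1L]
      if (nxt - usable[j] > bridgeGaps + 1L) break
      # a residue joins when it correlates with the run members on
      # average and is not anti-correlated with any of them: segments
      # are coherent blocks, whereas smoothly rotating profiles (e.g.
      # along a flexible linker) lose correlation with the far end of
      # a run and are cut off
      cc <- map@corr[as.character(run), as.character(nxt)]
      ok <- map@valid[as.character(run), as.character(nxt)]
      toRun <- if (any(ok)) mean(cc[ok]) else NA_real_
      minTo <- if (any(ok)) min(cc[ok]) else NA_real_
      if (!is.na(toRun) && toRun >= corrThreshold &&
          minTo >= corrThreshold / 2) {
        run <- c(run, nxt)
        j <- j + 1L
      } else break
    }
    if (length(run) >= minLength &&
        meanPairCorr(map, as.character(run)) >= corrThreshold) {
      segs[[length(segs) + 1L]] <- data.frame(
        start = min(run), end = max(run), nResidues = length(run),
        meanCorr = meanPairCorr(map, as.character(run)))
    }
    i <- j + 1L
  }
  if (!length(segs))
    return(data.frame(start = integer(), end = integer(),
                      nResidues = integer(), meanCorr = numeric()))
  do.call(rbind, segs)
}

#' Compare two correlation maps (e.g. wild-type versus mutant)
#'
#' Elementwise difference \code{b - a} over commonly valid pairs, plus
#' a block summary of mean correlations per segment pair in both maps
#' with sign-flip flags (blocks whose mean correlation changes sign
#' with magnitude at least \code{minBlockCorr} on both sides).
#'
#' @param a,b \linkS4class{CorrelationMap}s sharing residues (the
#'   intersection is used; disjoint sets raise an error).
#' @param segments segment table (\code{start}, \code{end}) defining
#'   the blocks; default: \code{\link{detectSegments}} on \code{a}.
#' @param minBlockCorr magnitude a block mean must reach on both maps
#'   to count as sign-flipped (default 0.2).
#' @return list with \code{difference} (matrix), \code{residues},
#'   and \code{blocks} (data.frame \code{segA}, \code{segB},
#'   \code{meanA}, \code{meanB}, \code{signFlip}).
#' @export
compareMaps <- function(a, b, segments = NULL, minBlockCorr = 0.2) {
  common <- intersect(residueNumbers(a), residueNumbers(b))
  if (!length(common)) stop("the two maps share no residues")
  ca <- as.character(common)
  A <- a@corr[ca, ca]; B <- b@corr[ca, ca]
  okBoth <- a@valid[ca, ca] & b@valid[ca, ca]
  D <- B - A
  D[!okBoth] <- NA_real_
  if (is.null(segments)) segments <- detectSegments(a)
  blocks <- NULL
  ns <- nrow(segments)
  if (ns > 0) {
    rows <- list()
    for (p in seq_len(ns)) for (q in p:ns) {
      ip <- ca[common >= segments$start[p] & common <= segments$end[p]]
      iq <- ca[common >= segments$start[q] & common <= segments$end[q]]
      if (!length(ip) || !length(iq)) next
      okblk <- okBoth[ip, iq, drop = FALSE]
      if (!any(okblk)) next
      ma <- mean(A[ip, iq, drop = FALSE][okblk])
      mb <- mean(B[ip, iq, drop = FALSE][okblk])
      rows[[length(rows) + 1L]] <- data.frame(
        segA = p, segB = q, meanA = ma, meanB = mb,
        signFlip = sign(ma) != sign(mb) & abs(ma) >= minBlockCorr &
          abs(mb) >= minBlockCorr)
    }
    blocks <- do.call(rbind, rows)
  }
  list(difference = D, residues = common, blocks = blocks)
}

#' Score detected segments against a planted architecture
#'
#' @param detected segment table from \code{\link{detectSegments}}.
#' @param planted matrix or data.frame with \code{start}, \code{end}.
#' @param tol boundary tolerance in residues (default 1).
#' @return list with \code{nDetected}, \code{nPlanted} and
#'   \code{nMatched} (planted segments whose start and end are both
#'   reproduced within \code{tol}).
#' @export
segmentRecovery <- function(detected, planted, tol = 1) {
  planted <- as.data.frame(planted)
  names(planted)[1:2] <- c("start", "end")
  matched <- 0L
  for (s in seq_len(nrow(planted))) {
    hit <- any(abs(detected$start - planted$start[s]) <= tol &
                 abs(detected$end - planted$end[s]) <= tol)
    matched <- matched + hit
  }
  list(nDetected = nrow(detected), nPlanted = nrow(planted),
       nMatched = matched)
}
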