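#' Nine-point peak-intensity averaging
#'
#' Arithmetic mean of the 3 x 3 spectral-grid neighbourhood centred at
#' the peak maximum, the standard way to reduce the influence of
#' background noise on a peak-height readout.
#'
#' @param grid 2-D numeric intensity array.
#' @param center integer pair (row, column) of the peak maximum.
#' @return the averaged intensity (scalar).
#' @examples
#' g <- matrix(1, 3, 3); g[2, 2] <- 10
#' ninePointAverage(g, c(2, 2))  # 2
#' @export
ninePointAverage <- function(grid, center) {
  stopifnot(is.matrix(grid), length(center) == 2)
  i <- center[1]; j <- center[2]
  if (i < 2 || j < 2 || i > nrow(grid) - 1 || j > ncol(grid) - 1)
    stop("the 3x3 neighbourhood of the centre must lie inside the grid")
  mean(grid[(i - 1):(i + 1), (j - 1):(j + 1)])
}

## Profiled least squares for I(t) = I0 * exp(-R t):
## for fixed R the optimal I0 is sum(I e)/sum(e^2); minimise over R.
decaySse <- function(R, t, I) {
  e <- exp(-R * t)
  denom <- sum(e * e)
  if (denom <= 0 || !is.finite(denom)) return(Inf)
  i0 <- sum(I * e) / denom
  sum((I - i0 * e)^2)
}

## Point fit of the decay rate: coarse grid bracket + Brent refine.
fitDecayRate <- function(t, I, lower = -50, upper = 2000) {
  grid <- c(seq(lower, 0, length.out = 6),
            exp(seq(log(0.05), log(upper), length.out = 60)))
  sse <- vapply(grid, decaySse, numeric(1), t = t, I = I)
  i <- which.min(sse)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (lo == hi) return(grid[i])
  optimize(decaySse, c(lo, hi), t = t, I = I, tol = 1e-9)$minimum
}

## Vectorised golden-section fit over many perturbed series at once.
## P: length(t) x nDraws matrix of intensities; returns nDraws rates.
fitDecayRateMany <- function(t, P, lower = -50, upper = 2000, iter = 70L) {
  nd <- ncol(P)
  sseAt <- function(R) {
    E <- exp(-outer(t, R))
    i0 <- colSums(P * E) / colSums(E * E)
    colSums((P - sweep(E, 2, i0, "*"))^2)
  }
  # per-column coarse bracket
  grid <- c(seq(lower, 0, length.out = 6),
            exp(seq(log(0.05), log(upper), length.out = 40)))
  S <- vapply(grid, function(g) sseAt(rep(g, nd)), numeric(nd))
  S <- matrix(S, nrow = nd)
  best <- max.col(-S)
  a <- grid[pmax(best - 1L, 1L)]
  b <- grid[pmin(best + 1L, length(grid))]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- sseAt(x1)
  f2 <- sseAt(x2)
  for (it in seq_len(iter)) {
    left <- f1 < f2            # minimum is in [a, x2]
    b <- ifelse(left, x2, b)
    a <- ifelse(left, a, x1)
    x2new <- ifelse(left, x1, a + gr * (b - a))
    x1new <- ifelse(left, b - gr * (b - a), x2)
    fEval <- sseAt(ifelse(left, x1new, x2new))
    f2new <- ifelse(left, f1, fEval)
    f1new <- ifelse(left, fEval, f2)
    x1 <- x1new; x2 <- x2new; f1 <- f1new; f2 <- f2new
  }
  (a + b) / 2
}

#' Fit mono-exponential decay rates with Monte-Carlo uncertainties
#'
#' Least-squares fit of \eqn{I(t) = I_0 e^{-Rt}} per residue (both
#' parameters free, \eqn{I_0} profiled out analytically).  Duplicated
#' delays enter as independent observations.  The uncertainty is the
#' standard deviation of the rate over \code{nMc} refits in which every
#' intensity is perturbed by \eqn{N(0, \mathrm{noiseRmsd})}, seeded
#' deterministically.
#'
#' Residues whose intensities are all non-positive, or whose fitted
#' rate runs into the search bound (signals broadened beyond
#' observability), are flagged \code{masked}.
#'
#' @param series peak-intensity table with columns \code{residue},
#'   \code{delay_s}, \code{intensity}.
#' @param noiseRmsd spectral noise level (intensity units) used for the
#'   Monte-Carlo perturbations.
#' @param nMc number of Monte-Carlo refits.
#' @param seed integer seed.
#' @param upper upper bound of the rate search (1/s).
#' @return rate table: data.frame with columns \code{residue},
#'   \code{value}, \code{sd}, \code{masked}, \code{nPoints}.
#' @export
fitExponentialRate <- function(series, noiseRmsd = 0, nMc = 500L,
                               seed = 1L, upper = 2000) {
  stopifnot(all(c("residue", "delay_s", "intensity") %in% names(series)))
  set.seed(seed)
  resIds <- sort(unique(series$residue))
  out <- data.frame(residue = resIds, value = NA_real_, sd = NA_real_,
                    masked = FALSE, nPoints = 0L)
  for (i in seq_along(resIds)) {
    sel <- series$residue == resIds[i]
    t <- series$delay_s[sel]
    I <- series$intensity[sel]
    out$nPoints[i] <- length(t)
    if (length(unique(t)) < 2 || all(I <= 0)) {
      out$masked[i] <- TRUE
      next
    }
    R <- fitDecayRate(t, I, upper = upper)
    if (R >= 0.98 * upper) {
      out$masked[i] <- TRUE
      next
    }
    out$value[i] <- R
    if (noiseRmsd > 0 && nMc > 0) {
      P <- I + matrix(rnorm(length(I) * nMc, 0, noiseRmsd), nrow = length(I))
      Rmc <- fitDecayRateMany(t, P, upper = upper)
      keep <- Rmc < 0.98 * upper
      out$sd[i] <- stats::sd(Rmc[keep])
    } else {
      out$sd[i] <- 0
    }
  }
  out
}

#' Heteronuclear NOE from saturated/reference intensity pairs
#'
#' \eqn{\mathrm{hNOE} = I_\mathrm{sat} / I_\mathrm{ref}} with the
#' uncertainty propagated to first order from the spectral noise RMSD
#' on both intensities.  Residues whose reference intensity is weaker
#' than three times the noise are masked as unreliable.
#'
#' @param residue residue numbers.
#' @param sat,ref peak intensities with and without proton saturation.
#' @param noiseRmsd noise RMSD measured on a signal-free spectral
#'   region.
#' @return rate table (dimensionless \code{value}) with columns
#'   \code{residue}, \code{value}, \code{sd}, \code{masked}.
#' @export
computeHnoe <- function(residue, sat, ref, noiseRmsd) {
  stopifnot(length(sat) == length(ref), length(residue) == length(ref),
            noiseRmsd >= 0)
  masked <- abs(ref) < 3 * noiseRmsd
  val <- sat / ref
  sdv <- sqrt((noiseRmsd / ref)^2 + (sat * noiseRmsd / ref^2)^2)
  val[masked] <- NA_real_
  sdv[masked] <- NA_real_
  data.frame(residue = residue, value = val, sd = sdv, masked = masked)
}

#' R2/R1 ratio profile with exchange flags
#'
#' Ratio of transverse to longitudinal 15N relaxation rates per
#' residue, with first-order error propagation, plus a flag marking
#' residues whose ratio exceeds the profile average -- the signature of
#' additional ms-timescale exchange broadening.
#'
#' @param r2,r1 rate tables (columns \code{residue}, \code{value},
#'   \code{sd}, \code{masked}) on a common residue set.
#' @return data.frame with columns \code{residue}, \code{value},
#'   \code{sd}, \code{masked}, \code{aboveMean}.
#' @export
r2OverR1 <- function(r2, r1) {
  m <- merge(r2, r1, by = "residue", suffixes = c(".r2", ".r1"))
  masked <- m$masked.r2 | m$masked.r1 | !is.finite(m$value.r1) |
    m$value.r1 <= 0
  val <- ifelse(masked, NA_real_, m$value.r2 / m$value.r1)
  sdv <- abs(val) * sqrt((m$sd.r2 / m$value.r2)^2 + (m$sd.r1 / m$value.r1)^2)
  sdv[masked] <- NA_real_
  avg <- mean(val[!masked])
  data.frame(residue = m$residue, value = val, sd = sdv, masked = masked,
             aboveMean = !masked & val > avg)
}
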