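#' PRE rate from paramagnetic and diamagnetic 1HN R2
#'
#' \eqn{\Gamma_2 = R_2^{para} - R_2^{dia}} per residue, uncertainties
#' added in quadrature.  Negative values (possible through noise) are
#' retained and flagged rather than clipped, so that downstream
#' correlation maps are not biased.
#'
#' @param paraR2,diaR2 rate tables (columns \code{residue},
#'   \code{value}, \code{sd}, \code{masked}); residues present in only
#'   one table are masked.
#' @return rate table with additional logical column \code{negative}.
#' @export
computeGamma2 <- function(paraR2, diaR2) {
  m <- merge(paraR2[, c("residue", "value", "sd", "masked")],
             diaR2[, c("residue", "value", "sd", "masked")],
             by = "residue", all = TRUE, suffixes = c(".p", ".d"))
  masked <- is.na(m$masked.p) | is.na(m$masked.d) | m$masked.p | m$masked.d
  val <- m$value.p - m$value.d
  sdv <- sqrt(m$sd.p^2 + m$sd.d^2)
  val[masked] <- NA_real_
  sdv[masked] <- NA_real_
  data.frame(residue = m$residue, value = val, sd = sdv, masked = masked,
             negative = !masked & val < 0)
}

#' PRI rate from dual- and single-label PRE rates
#'
#' The interference rate is the excess of the doubly labelled PRE over
#' the sum of the two singly labelled PREs:
#' \deqn{\Delta\Gamma_2 = \Gamma_2[X_1{+}X_2] - (\Gamma_2[X_1] +
#'   \Gamma_2[X_2])}
#' with the uncertainty from quadrature over the three terms.  A
#' positive rate indicates compact conformers in which the two
#' label-amide vectors are nearly (anti)parallel; a negative rate,
#' nearly orthogonal.
#'
#' @param g2Both rate table of the doubly labelled sample.
#' @param g2A,g2B rate tables of the two singly labelled samples.
#' @return rate table (columns \code{residue}, \code{value}, \code{sd},
#'   \code{masked}).
#' @export
computePri <- function(g2Both, g2A, g2B) {
  m <- merge(merge(g2Both[, c("residue", "value", "sd", "masked")],
                   g2A[, c("residue", "value", "sd", "masked")],
                   by = "residue", all = TRUE, suffixes = c(".ab", ".a")),
             g2B[, c("residue", "value", "sd", "masked")],
             by = "residue", all = TRUE)
  masked <- is.na(m$masked.ab) | is.na(m$masked.a) | is.na(m$masked) |
    m$masked.ab | m$masked.a | m$masked
  val <- m$value.ab - m$value.a - m$value
  sdv <- sqrt(m$sd.ab^2 + m$sd.a^2 + m$sd^2)
  val[masked] <- NA_real_
  sdv[masked] <- NA_real_
  data.frame(residue = m$residue, value = val, sd = sdv, masked = masked)
}

#' Classify the average projection angle regime from a PRI rate
#'
#' A PRI rate significantly positive implies the average angle between
#' the two label-amide vectors approaches 0 or 180 degrees
#' (\code{"aligned"}); significantly negative implies close to 90
#' degrees (\code{"orthogonal"}); otherwise the angle is near the magic
#' angle or the data are uninformative
#' (\code{"magic/indeterminate"}).
#'
#' @param value PRI rate(s) (1/s).
#' @param sd uncertainties.
#' @param z significance multiple (default 2).
#' @return character vector of regimes.
#' @export
classifyProjectionAngle <- function(value, sd, z = 2) {
  stopifnot(length(value) == length(sd), all(is.finite(sd)))
  out <- rep("magic/indeterminate", length(value))
  out[value > z * sd] <- "aligned"
  out[value < -z * sd] <- "orthogonal"
  out[!is.finite(value)] <- "magic/indeterminate"
  out
}

#' Wild-type versus mutant PRI-rate differences
#'
#' Per-residue difference (mutant minus wild-type) of PRI rates for a
#' common label pair, flagged significant when the difference exceeds
#' \code{z} combined standard deviations, with a direction tag
#' (\code{"increased"}/\code{"decreased"}).
#'
#' @param wt,mut PRI rate tables (columns \code{residue},
#'   \code{value}, \code{sd}, \code{masked}).
#' @param z significance multiple (default 2).
#' @return data.frame with columns \code{residue}, \code{diff},
#'   \code{sd}, \code{masked}, \code{significant}, \code{direction}.
#' @export
priDifference <- function(wt, mut, z = 2) {
  m <- merge(wt[, c("residue", "value", "sd", "masked")],
             mut[, c("residue", "value", "sd", "masked")],
             by = "residue", all = TRUE, suffixes = c(".wt", ".mut"))
  masked <- is.na(m$masked.wt) | is.na(m$masked.mut) | m$masked.wt |
    m$masked.mut
  d <- m$value.mut - m$value.wt
  sdv <- sqrt(m$sd.wt^2 + m$sd.mut^2)
  d[masked] <- NA_real_
  sdv[masked] <- NA_real_
  sig <- !masked & abs(d) > z * sdv
  dir <- rep(NA_character_, length(d))
  dir[sig & d > 0] <- "increased"
  dir[sig & d < 0] <- "decreased"
  data.frame(residue = m$residue, diff = d, sd = sdv, masked = masked,
             significant = sig, direction = dir)
}
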