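## gyromagnetic-ratio magnitude ratio |gammaN/gammaH| for 15N/1H
GAMMA_RATIO_N_H <- 0.1013676

#' Larmor frequencies used in reduced spectral density mapping
#'
#' @param protonLarmorMHz proton Larmor frequency (MHz).
#' @return named numeric vector with \code{wN} (15N Larmor,
#'   \code{protonLarmorMHz * |gammaN/gammaH|}) and \code{wh}
#'   (effective high-frequency point, \code{0.87 * protonLarmorMHz}),
#'   both in MHz.
#' @examples
#' larmorFrequencies(700.3)  # wN about 71.0 MHz
#' @export
larmorFrequencies <- function(protonLarmorMHz) {
  if (protonLarmorMHz < 0) stop("proton Larmor frequency must be >= 0")
  c(wN = protonLarmorMHz * GAMMA_RATIO_N_H, wh = 0.87 * protonLarmorMHz)
}

#' Field and interaction constants for 15N relaxation analysis
#'
#' Derives the dipolar and CSA interaction constants entering the
#' reduced spectral density mapping from the field strength, the N-H
#' bond length and the 15N chemical shift anisotropy.
#'
#' @param protonLarmorMHz proton Larmor frequency (MHz; default 700.3).
#' @param rNH N-H bond length (Angstrom; default 1.02).
#' @param csaPpm 15N CSA (ppm; default -172).
#' @return list with angular frequencies \code{wH}, \code{wN},
#'   \code{wh} (rad/s), \code{d2} (squared dipolar constant, rad^2/s^2),
#'   \code{c2} (squared CSA constant) and \code{gammaRatio} (signed
#'   gammaN/gammaH).
#' @export
fieldParameters <- function(protonLarmorMHz = 700.3, rNH = 1.02,
                            csaPpm = -172) {
  stopifnot(protonLarmorMHz > 0, rNH > 0)
  mu0_4pi <- 1e-7
  hbar <- 1.054571817e-34
  gammaH <- 2.6752218744e8
  gammaN <- -gammaH * GAMMA_RATIO_N_H
  r <- rNH * 1e-10
  d <- mu0_4pi * hbar * gammaH * abs(gammaN) / r^3
  wH <- 2 * pi * protonLarmorMHz * 1e6
  wN <- wH * GAMMA_RATIO_N_H
  c2 <- (wN * csaPpm * 1e-6)^2 / 3
  list(wH = wH, wN = wN, wh = 0.87 * wH, d2 = d^2, c2 = c2,
       gammaRatio = -GAMMA_RATIO_N_H)
}

#' Lorentzian spectral density
#'
#' \eqn{J(\omega) = (2/5)\,\tau_c / (1 + \omega^2\tau_c^2)} for
#' isotropic tumbling with a single correlation time.
#'
#' @param omega angular frequency (rad/s); vectorised.
#' @param tauC correlation time (s).
#' @return spectral density (s/rad).
#' @export
lorentzianJ <- function(omega, tauC) {
  0.4 * tauC / (1 + (omega * tauC)^2)
}

#' Forward 15N relaxation rates from three spectral density values
#'
#' The reduced (three-point) forward expressions, the exact inverse of
#' \code{\link{reducedSpectralDensities}}:
#' \deqn{R_1 = (d^2/4)[3J(\omega_N) + 7J(\omega_h)] + c^2 J(\omega_N)}
#' \deqn{R_2 = (d^2/8)[4J(0) + 3J(\omega_N) + 13J(\omega_h)] +
#'   (c^2/6)[4J(0) + 3J(\omega_N)] + R_{ex}}
#' \deqn{\mathrm{NOE} = 1 + (\gamma_H/\gamma_N)(d^2/4)\,
#'   5J(\omega_h)/R_1}
#'
#' @param j0,jN,jh spectral densities at 0, \eqn{\omega_N} and
#'   \eqn{0.87\,\omega_H} (s/rad); vectorised.
#' @param field a \code{\link{fieldParameters}} list.
#' @param rex optional exchange contribution to R2 (1/s).
#' @return data.frame with columns \code{r1}, \code{r2}, \code{noe}.
#' @export
forwardRelaxationRates <- function(j0, jN, jh, field = fieldParameters(),
                                   rex = 0) {
  D <- field$d2 / 4
  C <- field$c2
  r1 <- D * (3 * jN + 7 * jh) + C * jN
  r2 <- (D / 2) * (4 * j0 + 3 * jN + 13 * jh) +
    (C / 6) * (4 * j0 + 3 * jN) + rex
  sigma <- 5 * D * jh
  noe <- 1 + (1 / field$gammaRatio) * sigma / r1
  data.frame(r1 = r1, r2 = r2, noe = noe)
}

#' Exact 15N relaxation rates for single-correlation-time motion
#'
#' Full five-frequency expressions (no high-frequency approximation)
#' with a Lorentzian spectral density; used as an independent forward
#' oracle and by the synthetic data generator.
#'
#' @param tauC correlation time (s); vectorised.
#' @param field a \code{\link{fieldParameters}} list.
#' @param rex exchange contribution to R2 (1/s).
#' @return data.frame with columns \code{r1}, \code{r2}, \code{noe}.
#' @export
relaxationFromTauc <- function(tauC, field = fieldParameters(), rex = 0) {
  D <- field$d2 / 4
  C <- field$c2
  J <- function(w) lorentzianJ(w, tauC)
  jHmN <- J(field$wH - field$wN)
  jHpN <- J(field$wH + field$wN)
  jN <- J(field$wN)
  jH <- J(field$wH)
  j0 <- J(0)
  r1 <- D * (jHmN + 3 * jN + 6 * jHpN) + C * jN
  r2 <- (D / 2) * (4 * j0 + jHmN + 3 * jN + 6 * jH + 6 * jHpN) +
    (C / 6) * (4 * j0 + 3 * jN) + rex
  sigma <- D * (6 * jHpN - jHmN)
  noe <- 1 + (1 / field$gammaRatio) * sigma / r1
  data.frame(r1 = r1, r2 = r2, noe = noe)
}

#' Reduced spectral density mapping
#'
#' Inverts per-residue (R1, R2, hNOE) into the three spectral density
#' values \eqn{J_{eff}(0)}, \eqn{J(\omega_N)} and \eqn{J(\omega_h)}
#' (\eqn{\omega_h = 0.87\,\omega_H}):
#' \deqn{\sigma_{NH} = R_1(\mathrm{NOE}-1)\gamma_N/\gamma_H, \quad
#'   J(\omega_h) = 4\sigma_{NH}/(5d^2)}
#' \deqn{J(\omega_N) = [R_1 - (7d^2/4) J(\omega_h)]/(3d^2/4 + c^2)}
#' \deqn{J_{eff}(0) = [R_2 - (3d^2/8 + c^2/2) J(\omega_N) -
#'   (13d^2/16) J(\omega_h)] / (d^2/2 + 2c^2/3)}
#' Uncertainties follow by first-order propagation.  Exchange
#' broadening inflates only \eqn{J_{eff}(0)}, which is reported as is
#' (negative or inflated values are flagged, never clipped).
#'
#' @param r1,r2,hnoe rate tables (columns \code{residue},
#'   \code{value}, \code{sd}, \code{masked}) on a common residue set.
#' @param field a \code{\link{fieldParameters}} list.
#' @return data.frame with columns \code{residue}, \code{j0},
#'   \code{jN}, \code{jh}, \code{j0Sd}, \code{jNSd}, \code{jhSd},
#'   \code{masked}, \code{j0Negative}.
#' @export
reducedSpectralDensities <- function(r1, r2, hnoe,
                                     field = fieldParameters()) {
  m <- merge(merge(r1, r2, by = "residue", suffixes = c(".r1", ".r2")),
             hnoe, by = "residue")
  D <- field$d2 / 4
  C <- field$c2
  gr <- field$gammaRatio
  masked <- m$masked.r1 | m$masked.r2 | m$masked |
    !is.finite(m$value.r1) | m$value.r1 <= 0 |
    (is.finite(m$sd) & m$value > 1 + 5 * m$sd)
  R1 <- m$value.r1; R2 <- m$value.r2; NOE <- m$value
  sigma <- R1 * (NOE - 1) * gr
  jh <- sigma / (5 * D)
  jN <- (R1 - 7 * D * jh) / (3 * D + C)
  aJ <- 3 * D / 2 + C / 2
  bJ <- 13 * D / 2
  gJ <- 2 * D + 2 * C / 3
  j0 <- (R2 - aJ * jN - bJ * jh) / gJ
  # first-order propagation: partials of (jh, jN, j0) wrt (R1, R2, NOE)
  dSig_R1 <- (NOE - 1) * gr
  dSig_NOE <- R1 * gr
  jh_R1 <- dSig_R1 / (5 * D)
  jh_NOE <- dSig_NOE / (5 * D)
  jN_R1 <- (1 - 7 * D * jh_R1) / (3 * D + C)
  jN_NOE <- (-7 * D * jh_NOE) / (3 * D + C)
  j0_R1 <- (-aJ * jN_R1 - bJ * jh_R1) / gJ
  j0_NOE <- (-aJ * jN_NOE - bJ * jh_NOE) / gJ
  j0_R2 <- 1 / gJ
  v1 <- m$sd.r1^2; v2 <- m$sd.r2^2; vn <- m$sd^2
  jhSd <- sqrt(jh_R1^2 * v1 + jh_NOE^2 * vn)
  jNSd <- sqrt(jN_R1^2 * v1 + jN_NOE^2 * vn)
  j0Sd <- sqrt(j0_R1^2 * v1 + j0_R2^2 * v2 + j0_NOE^2 * vn)
  for (v in c("j0", "jN", "jh", "j0Sd", "jNSd", "jhSd"))
    assign(v, replace(get(v), masked, NA_real_))
  data.frame(residue = m$residue, j0 = j0, jN = jN, jh = jh,
             j0Sd = j0Sd, jNSd = jNSd, jhSd = jhSd, masked = masked,
             j0Negative = !masked & j0 < 0)
}
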