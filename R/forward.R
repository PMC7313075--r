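#' Forward-model parameters for PRE/PRI back-calculation
#'
#' @param tauC effective reorientation time of the electron-proton
#'   vector (s).  The default 4 ns puts back-calculated PRE rates in the
#'   tens-of-1/s regime typical of MTSL-labelled IDPs.
#' @param protonLarmor proton Larmor frequency (Hz).
#' @param kPre Solomon-Bloembergen prefactor (cm^6 s^-2).
#' @param kPri interference prefactor (cm^6 s^-2); only the sign, the
#'   magic-angle zero and the proximity cutoff of the PRI forward model
#'   are treated as physically normative, so the scale is configurable.
#' @param priDistanceCutoff label-label distance (Angstrom) beyond which
#'   conformers contribute no interference.
#' @param contactFloor minimal centre-to-centre distance (Angstrom) used
#'   when evaluating r^-6 / r^-3, a hard-sphere proxy for the excluded
#'   volume of the nitroxide side chain that keeps the phantom chain
#'   from producing unphysical contacts.
#' @param axialAnisotropy anisotropy coefficient \eqn{\kappa \in [0, 1]}
#'   of the local reorientation: the per-conformer PRE contribution is
#'   weighted by \eqn{1 + \kappa P_2(\cos\theta_{ax})}, where
#'   \eqn{\theta_{ax}} is the angle between the electron-proton vector
#'   and the local chain axis (a segment tumbles about its own axis, so
#'   interspin vectors along the axis relax more efficiently than
#'   perpendicular ones).  \eqn{\kappa = 0} (the default) recovers the
#'   isotropic Solomon-Bloembergen form.
#' @return a validated list of class \code{"ForwardParams"}.
#' @export
forwardParams <- function(tauC = 4e-9,
                          protonLarmor = 700.3e6,
                          kPre = 1.23e-32,
                          kPri = 1.23e-31,
                          priDistanceCutoff = 50,
                          contactFloor = 5,
                          axialAnisotropy = 0) {
  stopifnot(tauC > 0, protonLarmor > 0, kPre > 0, kPri > 0,
            priDistanceCutoff > 0, contactFloor >= 0,
            axialAnisotropy >= 0, axialAnisotropy <= 1)
  structure(list(tauC = tauC, protonLarmor = protonLarmor, kPre = kPre,
                 kPri = kPri, priDistanceCutoff = priDistanceCutoff,
                 contactFloor = contactFloor,
                 axialAnisotropy = axialAnisotropy),
            class = c("ForwardParams", "list"))
}

## Spectral factor 4*tau + 3*tau / (1 + wH^2 tau^2) of the
## Solomon-Bloembergen transverse PRE expression.
preSpectralFactor <- function(tauC, protonLarmor) {
  wH <- 2 * pi * protonLarmor
  4 * tauC + 3 * tauC / (1 + (wH * tauC)^2)
}

#' Evaluate the Solomon-Bloembergen PRE rate at a fixed distance
#'
#' \eqn{\Gamma_2 = K r^{-6} (4\tau_c + 3\tau_c/(1+\omega_H^2\tau_c^2))}
#' with \eqn{r} in Angstrom (converted to cm to match the prefactor).
#'
#' @param rAngstrom electron-proton distance (Angstrom); vectorised.
#' @param params a \code{\link{forwardParams}} list.
#' @return PRE rate (1/s).
#' @examples
#' gamma2FromDistance(20)  # about 3.1 1/s at the defaults
#' @export
gamma2FromDistance <- function(rAngstrom, params = forwardParams()) {
  rcm <- pmax(rAngstrom, params$contactFloor) * 1e-8
  params$kPre * rcm^-6 * preSpectralFactor(params$tauC, params$protonLarmor)
}

## residue-to-label distance matrix (nResidues x nConformers)
labelDistances <- function(ensemble, label) {
  track <- labelCoords(ensemble, label)   # nc x 3
  co <- ensemble@coords
  nc <- dim(co)[3]
  d <- matrix(NA_real_, nrow = dim(co)[1], ncol = nc)
  for (k in seq_len(nc)) {
    dv <- sweep(co[, , k], 2, track[k, ], "-")
    d[, k] <- sqrt(rowSums(dv^2))
  }
  d
}

#' Back-calculate per-residue PRE rates from an ensemble
#'
#' Ensemble-averaged Solomon-Bloembergen transverse PRE:
#' \eqn{\Gamma_{2,i} = K \langle r_i^{-6}\rangle (4\tau_c +
#' 3\tau_c/(1+\omega_H^2\tau_c^2))}, the average running over conformer
#' weights.
#'
#' In compact-state conformers the \eqn{r^{-6}} contribution of a
#' residue belonging to a semi-rigid segment is replaced by the mean
#' \eqn{r^{-6}} over that segment's residues in the same conformer
#' (registry averaging): a transient docking contact has no preferred
#' register along the rod, so all residues of a docked segment share
#' the segment's contact statistics -- the geometric embodiment of
#' concerted segmental motion.  Major-state conformers and linker
#' residues always use their own distances.
#'
#' The labelled residue itself and prolines emit no amide and are
#' returned masked.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param label residue number of the (single) spin label.
#' @param params a \code{\link{forwardParams}} list.
#' @return rate table: data.frame with columns \code{residue},
#'   \code{value}, \code{sd}, \code{masked}.
#' @export
computePreRates <- function(ensemble, label, params = forwardParams()) {
  cfg <- ensemble@config
  if (!label %in% cfg@labelSites) stop("label site ", label, " not in ensemble")
  res <- residueNumbers(ensemble)
  n <- length(res)
  kappa <- params$axialAnisotropy
  track <- labelCoords(ensemble, label)
  co <- ensemble@coords
  nc <- dim(co)[3]
  compact <- ensemble@stateTag == "compact"
  segSel <- lapply(seq_len(nrow(cfg@segments)), function(s)
    which(res >= cfg@segments[s, 1] & res <= cfg@segments[s, 2]))
  axSel <- if (kappa > 0) chainAxisSelectors(cfg) else NULL
  avg <- numeric(n)
  for (k in seq_len(nc)) {
    xyz <- co[, , k]
    dv <- sweep(xyz, 2, track[k, ], "-")
    r <- pmax(sqrt(rowSums(dv^2)), params$contactFloor)
    r6 <- (r * 1e-8)^-6
    if (kappa > 0) {
      ax <- xyz[axSel$to, ] - xyz[axSel$from, ]
      ax <- ax / sqrt(rowSums(ax^2))
      cosAx <- rowSums(dv * ax) / sqrt(rowSums(dv^2))
      r6 <- r6 * (1 + kappa * (3 * cosAx^2 - 1) / 2)
    }
    if (compact[k]) {
      for (sel in segSel) r6[sel] <- mean(r6[sel])
    }
    avg <- avg + ensemble@weights[k] * r6
  }
  val <- params$kPre * avg *
    preSpectralFactor(params$tauC, params$protonLarmor)
  masked <- res %in% unobservableResidues(cfg, labels = label)
  val[masked] <- NA_real_
  data.frame(residue = res, value = val, sd = 0, masked = masked)
}

## Per-residue local chain axis, defined by bead index pairs (from, to):
## segment residues use their segment's end-to-end axis (shared by the
## whole rod, so the axis jumps at hinges); linker residues use the
## local direction bead(i+1) - bead(i-1); chain termini use their only
## neighbouring bond.
chainAxisSelectors <- function(config) {
  n <- config@nResidues
  res <- residueNumbers(config)
  from <- pmax(seq_len(n) - 1L, 1L)
  to <- pmin(seq_len(n) + 1L, n)
  seg <- config@segments
  if (nrow(seg) > 0) {
    for (s in seq_len(nrow(seg))) {
      inSeg <- which(res >= seg[s, 1] & res <= seg[s, 2])
      from[inSeg] <- min(inSeg)
      to[inSeg] <- max(inSeg)
    }
  }
  list(from = from, to = to)
}

#' Back-calculate per-residue PRI rates from a dual-labelled ensemble
#'
#' Cross-correlated interference of the two electron-proton dipolar
#' couplings: \eqn{\Delta\Gamma_{2,i} = K' \langle (3\cos^2\theta_i - 1)
#' \, r_{A,i}^{-3} r_{B,i}^{-3} \rangle} over conformers in which the
#' two labels are closer than \code{priDistanceCutoff}; all other
#' conformers contribute zero.  \eqn{\theta_i} is the angle between the
#' two label-to-amide vectors, so conformations with \eqn{\theta} near
#' 0 or 180 degrees contribute positively, near 90 degrees negatively,
#' and the magic angle (54.7 degrees) contributes nothing.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param labelA,labelB residue numbers of the two label sites.
#' @param params a \code{\link{forwardParams}} list.
#' @return rate table as in \code{\link{computePreRates}}.
#' @export
computePriRates <- function(ensemble, labelA, labelB,
                            params = forwardParams()) {
  if (labelA == labelB) stop("labelA and labelB must differ")
  cfg <- ensemble@config
  res <- residueNumbers(ensemble)
  trackA <- labelCoords(ensemble, labelA)
  trackB <- labelCoords(ensemble, labelB)
  co <- ensemble@coords
  nc <- dim(co)[3]
  acc <- numeric(length(res))
  sf <- preSpectralFactor(params$tauC, params$protonLarmor)
  dAB <- sqrt(rowSums((trackA - trackB)^2))
  for (k in seq_len(nc)) {
    if (dAB[k] >= params$priDistanceCutoff) next
    vA <- sweep(co[, , k], 2, trackA[k, ], "-")
    vB <- sweep(co[, , k], 2, trackB[k, ], "-")
    rA <- pmax(sqrt(rowSums(vA^2)), params$contactFloor)
    rB <- pmax(sqrt(rowSums(vB^2)), params$contactFloor)
    cosT <- rowSums(vA * vB) / (rA * rB)
    ang <- 3 * cosT^2 - 1
    acc <- acc + ensemble@weights[k] * ang *
      (rA * 1e-8)^-3 * (rB * 1e-8)^-3
  }
  val <- params$kPri * sf * acc
  masked <- res %in% unobservableResidues(cfg, labels = c(labelA, labelB))
  val[masked] <- NA_real_
  data.frame(residue = res, value = val, sd = 0, masked = masked)
}

#' Standard relaxation-delay schedules
#'
#' The inversion-recovery, CPMG and amide-proton transverse relaxation
#' delay lists used throughout the package, including the duplicated
#' time points that serve to estimate experimental errors.
#'
#' @return named list of numeric delay vectors (seconds): \code{r1}
#'   (11 points, two duplicated), \code{r2} (7 points, two duplicated)
#'   and \code{hnR2} (4 points).
#' @export
defaultDelaySchedules <- function() {
  list(
    r1 = c(0.0103, 0.0103, 0.1537, 0.3074, 0.4612, 0.6149, 0.6149,
           0.7686, 0.9223, 1.1272, 1.5372),
    r2 = c(0, 0.032, 0.032, 0.080, 0.160, 0.160, 0.320),
    hnR2 = c(0, 0.014, 0.028, 0.042)
  )
}

#' Synthesize noisy exponential decay series from a rate table
#'
#' Emulates peak-intensity series \eqn{I(t) = I_0 e^{-Rt} +
#' \epsilon}, \eqn{\epsilon \sim N(0, \mathrm{noiseSd})}, one intensity
#' per (residue, delay).  Duplicated delays produce duplicate entries
#' with distinct replicate numbers.  Masked residues yield no entries.
#'
#' @param rateTable data.frame with columns \code{residue},
#'   \code{value}, \code{masked} (rates in 1/s).
#' @param delays non-negative delay times (s); may contain duplicates.
#' @param i0 reference intensity at zero delay.
#' @param noiseSd Gaussian spectral noise (intensity units).
#' @param seed integer seed.
#' @return peak-intensity table: data.frame with columns
#'   \code{residue}, \code{delay_s}, \code{intensity},
#'   \code{replicate}.
#' @export
synthesizeDecaySeries <- function(rateTable, delays, i0 = 1000,
                                  noiseSd = 0, seed = 1L) {
  if (length(delays) == 0) stop("delay list must not be empty")
  if (any(delays < 0)) stop("delays must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  set.seed(seed)
  keep <- rateTable[!rateTable$masked, , drop = FALSE]
  repId <- stats::ave(seq_along(delays), delays, FUN = seq_along)
  out <- do.call(rbind, lapply(seq_len(nrow(keep)), function(i) {
    mu <- i0 * exp(-keep$value[i] * delays)
    data.frame(residue = keep$residue[i], delay_s = delays,
               intensity = mu + rnorm(length(delays), 0, noiseSd),
               replicate = repId)
  }))
  rownames(out) <- NULL
  out
}
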