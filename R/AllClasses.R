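#' @import methods
#' @importFrom stats rnorm runif pnorm rbinom sd optimize median setNames
#'   quantile cor ave
#' @importFrom utils read.delim read.table write.table head tail
NULL

#' Configuration of a synthetic spin-labelled IDP ensemble
#'
#' Describes a coarse-grained chain of Calpha beads: semi-rigid segments
#' joined by flexible hinges whose bend angles are drawn from a correlated
#' multivariate normal, plus a sparsely populated compact state defined by
#' a fixed bend-angle template.  Residues are numbered
#' \code{firstResidue .. firstResidue + nResidues - 1}.
#'
#' @slot nResidues number of residues in the chain.
#' @slot firstResidue residue number of the first bead.
#' @slot sequence one-letter amino-acid sequence (length \code{nResidues}),
#'   or \code{""} for a generic chain with no prolines.
#' @slot segments integer matrix with columns \code{start}, \code{end}
#'   (residue numbers) of the semi-rigid segments, ordered and
#'   non-overlapping.
#' @slot labelSites residue numbers carrying a nitroxide spin label.
#' @slot hingeCoupling correlation matrix (one row/column per hinge, i.e.
#'   \code{nrow(segments) - 1}) of the latent hinge-angle variables.
#' @slot compactPopulation fraction of conformers drawn in the compact
#'   minor state.
#' @slot compactFolds list of compact-fold templates, each a list with
#'   numeric vectors \code{bends} and \code{torsions} (length
#'   nResidues - 2); compact conformers draw one template uniformly.
#' @slot compactOpenProb probability that a gap of a compact conformer
#'   is "open" (its docking turn relaxed), breaking the contacts that
#'   run across it; openings are correlated across gaps through
#'   \code{hingeCoupling}.
#' @slot compactBendSd Gaussian jitter (radians) applied to the
#'   compact-state bends and torsions.
#' @slot linkerBendSd Gaussian bend (radians) per linker bead in the
#'   major state.
#' @slot linkerTorsionSd Gaussian torsion (radians) per linker bead in
#'   the major state (hinge torsions are uniform).
#' @slot hingeBendMax maximal absolute hinge bend (radians); the latent
#'   normal hinge variable is mapped through a probit onto
#'   \code{(-hingeBendMax, hingeBendMax)}.
#' @slot labelOffset distance (Angstrom) of the nitroxide pseudo-atom
#'   from the labelled bead.
#' @slot bondLength virtual Calpha-Calpha bond length (Angstrom).
#' @slot nConformers number of conformers to draw.
#' @slot seed integer seed making the ensemble reproducible.
#' @export
setClass("EnsembleConfig",
  representation(
    nResidues = "integer",
    firstResidue = "integer",
    sequence = "character",
    segments = "matrix",
    labelSites = "integer",
    hingeCoupling = "matrix",
    compactPopulation = "numeric",
    compactFolds = "list",
    compactOpenProb = "numeric",
    compactBendSd = "numeric",
    linkerBendSd = "numeric",
    linkerTorsionSd = "numeric",
    hingeBendMax = "numeric",
    labelOffset = "numeric",
    bondLength = "numeric",
    nConformers = "integer",
    seed = "integer"
  )
)

setValidity("EnsembleConfig", function(object) {
  msg <- character()
  n <- object@nResidues
  if (length(n) != 1L || n < 2L) msg <- c(msg, "nResidues must be a single value >= 2")
  res <- residueNumbers(object)
  if (nzchar(object@sequence) && nchar(object@sequence) != n)
    msg <- c(msg, "sequence length must equal nResidues")
  seg <- object@segments
  if (nrow(seg) > 0) {
    if (ncol(seg) != 2L) msg <- c(msg, "segments must have two columns (start, end)")
    if (any(seg[, 1] > seg[, 2])) msg <- c(msg, "segment start must be <= end")
    if (any(seg < min(res)) || any(seg > max(res)))
      msg <- c(msg, "segments must lie within the chain")
    if (nrow(seg) > 1) {
      if (is.unsorted(seg[, 1], strictly = TRUE))
        msg <- c(msg, "segments must be ordered")
      if (any(seg[-1, 1] <= seg[-nrow(seg), 2]))
        msg <- c(msg, "segments must not overlap")
    }
  }
  nh <- max(nrow(seg) - 1L, 0L)
  hc <- object@hingeCoupling
  if (nh > 0) {
    if (!all(dim(hc) == nh))
      msg <- c(msg, sprintf("hingeCoupling must be %d x %d", nh, nh))
    else {
      if (any(abs(hc) > 1 + 1e-12)) msg <- c(msg, "|hinge coupling| must be <= 1")
      if (any(abs(hc - t(hc)) > 1e-9)) msg <- c(msg, "hingeCoupling must be symmetric")
      if (any(abs(diag(hc) - 1) > 1e-9)) msg <- c(msg, "hingeCoupling diagonal must be 1")
      ev <- eigen(hc, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) msg <- c(msg, "hingeCoupling must be positive semi-definite")
    }
  }
  if (object@compactPopulation < 0 || object@compactPopulation > 1)
    msg <- c(msg, "compactPopulation must be in [0, 1]")
  if (!length(object@compactFolds))
    msg <- c(msg, "at least one compact-fold template is required")
  for (f in object@compactFolds) {
    if (!is.list(f) || length(f$bends) != n - 2L ||
        length(f$torsions) != n - 2L) {
      msg <- c(msg, "each compact fold needs bends and torsions of length nResidues - 2")
      break
    }
  }
  if (object@compactOpenProb < 0 || object@compactOpenProb > 1)
    msg <- c(msg, "compactOpenProb must be in [0, 1]")
  if (any(!object@labelSites %in% res))
    msg <- c(msg, "labelSites must be residue numbers within the chain")
  if (object@bondLength <= 0) msg <- c(msg, "bondLength must be positive")
  if (object@labelOffset <= 0) msg <- c(msg, "labelOffset must be positive")
  if (object@nConformers < 2L) msg <- c(msg, "nConformers must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Weighted set of coarse-grained chain conformations
#'
#' Per-residue bead coordinates, per-label nitroxide pseudo-atom
#' coordinates and per-conformer weights, plus the latent hinge bend
#' angles actually drawn (useful for checking planted couplings).
#'
#' @slot coords numeric array \code{nResidues x 3 x nConformers}
#'   (Angstrom).
#' @slot labelCoords numeric array \code{nLabels x 3 x nConformers}.
#' @slot weights non-negative conformer weights summing to one.
#' @slot stateTag \code{"major"} or \code{"compact"} per conformer.
#' @slot hingeAngles matrix \code{nHinges x nConformers} of signed bend
#'   angles (radians).
#' @slot config the \linkS4class{EnsembleConfig} the ensemble was drawn
#'   from.
#' @export
setClass("ConformerEnsemble",
  representation(
    coords = "array",
    labelCoords = "array",
    weights = "numeric",
    stateTag = "character",
    hingeAngles = "matrix",
    config = "EnsembleConfig"
  )
)

setValidity("ConformerEnsemble", function(object) {
  msg <- character()
  d <- dim(object@coords)
  nc <- d[3]
  if (d[1] != object@config@nResidues) msg <- c(msg, "coords/residue mismatch")
  if (length(object@weights) != nc) msg <- c(msg, "weights/conformer mismatch")
  if (abs(sum(object@weights) - 1) > 1e-9) msg <- c(msg, "weights must sum to 1")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(object@stateTag) != nc) msg <- c(msg, "stateTag/conformer mismatch")
  if (!all(object@stateTag %in% c("major", "compact")))
    msg <- c(msg, "stateTag must be 'major' or 'compact'")
  b <- object@config@bondLength
  ncheck <- min(nc, 25L)
  for (k in seq_len(ncheck)) {
    xyz <- object@coords[, , k]
    dd <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
    if (any(abs(dd - b) > 1e-6)) {
      msg <- c(msg, "consecutive bead distances must equal the virtual bond length")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Residues-by-datasets table of PRE or PRI rates
#'
#' Rates \eqn{R_{ik}} for residue \eqn{i} in spin-label dataset \eqn{k},
#' with a logical mask of observed entries.  Row names are residue
#' numbers, column names dataset identifiers.
#'
#' @slot values numeric matrix of rates (1/s); unobserved entries NA.
#' @slot sds numeric matrix of rate uncertainties (1/s).
#' @slot observed logical matrix; TRUE where the rate is observable.
#' @export
setClass("RateMatrix",
  representation(values = "matrix", sds = "matrix", observed = "matrix")
)

setValidity("RateMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) < 2L) msg <- c(msg, "at least two datasets are required")
  if (!all(dim(object@values) == dim(object@observed)) ||
      !all(dim(object@values) == dim(object@sds)))
    msg <- c(msg, "values, sds and observed must have identical dimensions")
  if (is.null(rownames(object@values))) msg <- c(msg, "values must have residue rownames")
  if (length(msg)) msg else TRUE
})

#' Symmetric residue-by-residue correlation map
#'
#' Pearson correlations of per-residue rate profiles across spin-label
#' datasets, with a validity mask (pairs sharing fewer than two common
#' datasets, or residues with zero rate variance, are invalid).
#'
#' @slot corr symmetric numeric matrix in [-1, 1]; invalid entries NA.
#' @slot valid logical matrix marking usable entries.
#' @export
setClass("CorrelationMap",
  representation(corr = "matrix", valid = "matrix")
)

setValidity("CorrelationMap", function(object) {
  msg <- character()
  cc <- object@corr
  if (nrow(cc) != ncol(cc)) msg <- c(msg, "corr must be square")
  if (!all(dim(cc) == dim(object@valid))) msg <- c(msg, "corr/valid dimension mismatch")
  ok <- object@valid & !is.na(cc)
  if (any(abs(cc[ok]) > 1 + 1e-12)) msg <- c(msg, "|corr| must be <= 1")
  if (any(abs(cc[ok] - t(cc)[ok]) > 1e-12)) msg <- c(msg, "corr must be symmetric")
  if (length(msg)) msg else TRUE
})
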