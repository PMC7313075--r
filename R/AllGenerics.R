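#' Residue numbers of an object
#'
#' @param x an object carrying residue numbering.
#' @return integer vector of residue numbers.
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' Number of conformers in an ensemble
#'
#' @param x a \linkS4class{ConformerEnsemble} or
#'   \linkS4class{EnsembleConfig}.
#' @return integer count.
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' Conformer bead coordinates
#'
#' @param x a \linkS4class{ConformerEnsemble}.
#' @param i conformer index.
#' @return numeric matrix \code{nResidues x 3} (Angstrom).
#' @export
setGeneric("conformerCoords", function(x, i) standardGeneric("conformerCoords"))

#' Spin-label pseudo-atom coordinates
#'
#' @param x a \linkS4class{ConformerEnsemble}.
#' @param label residue number of the label site.
#' @return numeric matrix \code{nConformers x 3}.
#' @export
setGeneric("labelCoords", function(x, label) standardGeneric("labelCoords"))

#' Conformer weights
#'
#' @param x a \linkS4class{ConformerEnsemble}.
#' @return numeric vector summing to one.
#' @export
setGeneric("conformerWeights", function(x) standardGeneric("conformerWeights"))

#' State tag (major/compact) per conformer
#'
#' @param x a \linkS4class{ConformerEnsemble}.
#' @return character vector.
#' @export
setGeneric("stateTags", function(x) standardGeneric("stateTags"))

#' Hinge bend angles per conformer
#'
#' @param x a \linkS4class{ConformerEnsemble}.
#' @return matrix \code{nHinges x nConformers} (radians).
#' @export
setGeneric("hingeAngles", function(x) standardGeneric("hingeAngles"))

#' Rate values of a RateMatrix
#'
#' @param x a \linkS4class{RateMatrix}.
#' @return numeric matrix, residues by datasets.
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))

#' Observability mask of a RateMatrix
#'
#' @param x a \linkS4class{RateMatrix}.
#' @return logical matrix.
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' Correlation matrix of a CorrelationMap
#'
#' @param x a \linkS4class{CorrelationMap}.
#' @return symmetric numeric matrix with NA at invalid entries.
#' @export
setGeneric("corrMatrix", function(x) standardGeneric("corrMatrix"))

#' Validity mask of a CorrelationMap
#'
#' @param x a \linkS4class{CorrelationMap}.
#' @return logical matrix.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
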