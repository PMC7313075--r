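#' @describeIn EnsembleConfig residue numbers of the chain
#' @param x object
#' @export
setMethod("residueNumbers", "EnsembleConfig", function(x) {
  seq.int(x@firstResidue, length.out = x@nResidues)
})

#' @describeIn ConformerEnsemble residue numbers of the chain
#' @param x object
#' @export
setMethod("residueNumbers", "ConformerEnsemble", function(x) {
  residueNumbers(x@config)
})

#' @describeIn RateMatrix residue numbers (rownames as integers)
#' @export
setMethod("residueNumbers", "RateMatrix", function(x) {
  as.integer(rownames(x@values))
})

#' @describeIn CorrelationMap residue numbers (rownames as integers)
#' @export
setMethod("residueNumbers", "CorrelationMap", function(x) {
  as.integer(rownames(x@corr))
})

#' @describeIn EnsembleConfig number of conformers requested
#' @export
setMethod("nConformers", "EnsembleConfig", function(x) x@nConformers)

#' @describeIn ConformerEnsemble number of conformers drawn
#' @export
setMethod("nConformers", "ConformerEnsemble", function(x) dim(x@coords)[3])

#' @describeIn ConformerEnsemble coordinates of conformer \code{i}
#' @param i conformer index
#' @export
setMethod("conformerCoords", "ConformerEnsemble", function(x, i) {
  m <- x@coords[, , i]
  rownames(m) <- residueNumbers(x)
  m
})

#' @describeIn ConformerEnsemble label pseudo-atom track for one site
#' @param label residue number of the label site
#' @export
setMethod("labelCoords", "ConformerEnsemble", function(x, label) {
  idx <- match(as.character(label), dimnames(x@labelCoords)[[1]])
  if (is.na(idx)) stop("no such label site: ", label)
  t(x@labelCoords[idx, , ])
})

#' @describeIn ConformerEnsemble conformer weights
#' @export
setMethod("conformerWeights", "ConformerEnsemble", function(x) x@weights)

#' @describeIn ConformerEnsemble state tag per conformer
#' @export
setMethod("stateTags", "ConformerEnsemble", function(x) x@stateTag)

#' @describeIn ConformerEnsemble hinge bend angles per conformer
#' @export
setMethod("hingeAngles", "ConformerEnsemble", function(x) x@hingeAngles)

#' @describeIn RateMatrix rate values
#' @export
setMethod("rateValues", "RateMatrix", function(x) x@values)

#' @describeIn RateMatrix observability mask
#' @export
setMethod("observedMask", "RateMatrix", function(x) x@observed)

#' @describeIn CorrelationMap correlation matrix
#' @export
setMethod("corrMatrix", "CorrelationMap", function(x) x@corr)

#' @describeIn CorrelationMap validity mask
#' @export
setMethod("validMask", "CorrelationMap", function(x) x@valid)

setMethod("show", "EnsembleConfig", function(object) {
  cat("EnsembleConfig:", object@nResidues, "residues",
      sprintf("(%d-%d),", object@firstResidue,
              object@firstResidue + object@nResidues - 1L),
      nrow(object@segments), "segments,",
      length(object@labelSites), "label sites\n")
  cat("  label sites:", paste(object@labelSites, collapse = ", "), "\n")
  cat("  compact population:", object@compactPopulation,
      " conformers:", object@nConformers, " seed:", object@seed, "\n")
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat("ConformerEnsemble:", nConformers(object), "conformers,",
      object@config@nResidues, "residues,",
      sum(object@stateTag == "compact"), "compact\n")
})

setMethod("show", "RateMatrix", function(object) {
  cat("RateMatrix:", nrow(object@values), "residues x",
      ncol(object@values), "datasets (",
      sum(object@observed), "observed entries )\n")
})

setMethod("show", "CorrelationMap", function(object) {
  cat("CorrelationMap:", nrow(object@corr), "residues,",
      sum(object@valid[upper.tri(object@valid)]), "valid pairs\n")
})
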