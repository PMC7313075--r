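# Hand-built ensembles and tables used across the suite.

# minimal configuration: a short straight chain, no planted segments
miniConfig <- function(n = 4L, labelSites = 225L, nConformers = 2L,
                       sequence = "") {
  ensembleConfig(nResidues = n, firstResidue = 225L, sequence = sequence,
                 segments = matrix(integer(), 0, 2,
                                   dimnames = list(NULL, c("start", "end"))),
                 labelSites = labelSites,
                 hingeCoupling = matrix(numeric(), 0, 0),
                 compactPopulation = 0,
                 compactFolds = list(list(bends = numeric(n - 2),
                                          torsions = numeric(n - 2))),
                 nConformers = nConformers, seed = 1L)
}

# ensemble whose label pseudo-atom sits at given distances from the last
# bead, one conformer per distance (equal weights)
distanceEnsemble <- function(rList, labelSite = 225L, n = 4L) {
  nc <- max(length(rList), 2L)
  rList <- rep_len(rList, nc)
  cfg <- miniConfig(n = n, labelSites = labelSite, nConformers = nc)
  coords <- array(0, c(n, 3, nc))
  lab <- array(0, c(1, 3, nc), dimnames = list(as.character(labelSite),
                                               NULL, NULL))
  for (k in seq_len(nc)) {
    coords[, 1, k] <- 3.8 * (seq_len(n) - 1)
    # probe residue is the last bead; label offset along y
    lab[1, , k] <- c(3.8 * (n - 1), rList[k], 0)
  }
  new("ConformerEnsemble", coords = coords, labelCoords = lab,
      weights = rep(1 / nc, nc), stateTag = rep("major", nc),
      hingeAngles = matrix(numeric(), 0, nc), config = cfg)
}

# dual-label ensemble: at the probe residue (first bead) the two
# label-to-amide vectors subtend the given angles (degrees), at fixed
# distances rA and rB; one conformer per angle
angleEnsemble <- function(thetasDeg, weights = NULL, rA = 15, rB = 15,
                          labelA = 226L, labelB = 227L, n = 4L) {
  nc <- max(length(thetasDeg), 2L)
  thetasDeg <- rep_len(thetasDeg, nc)
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  cfg <- miniConfig(n = n, labelSites = c(labelA, labelB),
                    nConformers = nc)
  coords <- array(0, c(n, 3, nc))
  lab <- array(0, c(2, 3, nc),
               dimnames = list(as.character(c(labelA, labelB)), NULL, NULL))
  for (k in seq_len(nc)) {
    coords[, 3, k] <- 3.8 * (seq_len(n) - 1)   # chain along z
    th <- thetasDeg[k] * pi / 180
    lab[1, , k] <- c(rA, 0, 0)
    lab[2, , k] <- c(rB * cos(th), rB * sin(th), 0)
  }
  new("ConformerEnsemble", coords = coords, labelCoords = lab,
      weights = weights, stateTag = rep("major", nc),
      hingeAngles = matrix(numeric(), 0, nc), config = cfg)
}

rateTable <- function(residue, value, sd = 0, masked = FALSE) {
  data.frame(residue = residue, value = value, sd = sd,
             masked = rep_len(masked, length(residue)))
}

# correlation map built directly from a matrix
mapFromMatrix <- function(m, residues = seq_len(nrow(m))) {
  dimnames(m) <- list(residues, residues)
  new("CorrelationMap", corr = m,
      valid = matrix(TRUE, nrow(m), ncol(m), dimnames = dimnames(m)))
}
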