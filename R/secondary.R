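#' Random-coil 13Ca / 13C' reference shifts
#'
#' Random-coil chemical shift reference (ppm) in the style of the
#' Wishart random-coil tables, shipped as a plain-text data file.  The
#' reference set is configurable: any data.frame with columns
#' \code{residueType} (one-letter), \code{CA} and \code{C} can be used
#' in its place.
#'
#' @return data.frame with columns \code{residueType}, \code{CA},
#'   \code{C}.
#' @export
randomCoilShifts <- function() {
  path <- system.file("extdata", "random_coil_shifts.tsv",
                      package = "prePRI", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Secondary chemical shift of one nucleus
#'
#' \eqn{\Delta\delta = \delta_{obs} - \delta_{rc}} against the
#' random-coil reference for the residue type.  There is no generic
#' fallback: a residue type missing from the reference yields
#' \code{NA} (no-data).
#'
#' @param observed observed shift (ppm); vectorised.
#' @param residueType one-letter residue type(s).
#' @param atom \code{"CA"} or \code{"C"} (carbonyl); recycled.
#' @param rcTable reference table as from
#'   \code{\link{randomCoilShifts}}.
#' @return secondary shift (ppm), \code{NA} where no reference exists.
#' @export
secondaryShift <- function(observed, residueType, atom = "CA",
                           rcTable = randomCoilShifts()) {
  atom <- rep_len(match.arg(atom, c("CA", "C"), several.ok = TRUE),
                  length(observed))
  ref <- ifelse(atom == "CA",
                rcTable$CA[match(residueType, rcTable$residueType)],
                rcTable$C[match(residueType, rcTable$residueType)])
  observed - ref
}

#' Averaged CaC' secondary shift
#'
#' \eqn{\Delta\delta_{av} = [3\Delta\delta C_\alpha +
#' 4\Delta\delta C']/7}, the weighted index combining the two nuclei
#' into a single secondary-structure propensity readout.
#'
#' @param dCa,dCp secondary shifts of 13Ca and 13C' (ppm); vectorised.
#' @return averaged secondary shift (ppm); \code{NA} where either
#'   input is missing.
#' @export
averagedSecondaryShift <- function(dCa, dCp) {
  (3 * dCa + 4 * dCp) / 7
}

#' Per-residue secondary shift profile
#'
#' Turns a long chemical-shift table into a per-residue profile of
#' \eqn{\Delta\delta C_\alpha}, \eqn{\Delta\delta C'} and
#' \eqn{\Delta\delta_{av}(C_\alpha C')}.
#'
#' @param shifts data.frame with columns \code{residue},
#'   \code{residueType} (one letter), \code{atom} (\code{"CA"} or
#'   \code{"C"}) and \code{shift} (ppm); at most one row per
#'   (residue, atom).
#' @param rcTable random-coil reference table.
#' @return data.frame with columns \code{residue},
#'   \code{residueType}, \code{dCa}, \code{dCp}, \code{dAv}.
#' @export
secondaryShiftProfile <- function(shifts, rcTable = randomCoilShifts()) {
  stopifnot(all(c("residue", "residueType", "atom", "shift") %in%
                  names(shifts)))
  if (any(duplicated(shifts[, c("residue", "atom")])))
    stop("at most one observed shift per (residue, atom)")
  res <- sort(unique(shifts$residue))
  getOne <- function(atom) {
    sel <- shifts[shifts$atom == atom, ]
    idx <- match(res, sel$residue)
    list(shift = sel$shift[idx], type = sel$residueType[idx])
  }
  ca <- getOne("CA")
  cp <- getOne("C")
  type <- ifelse(is.na(ca$type), cp$type, ca$type)
  dCa <- secondaryShift(ca$shift, ca$type, "CA", rcTable)
  dCp <- secondaryShift(cp$shift, cp$type, "C", rcTable)
  data.frame(residue = res, residueType = type, dCa = dCa, dCp = dCp,
             dAv = averagedSecondaryShift(dCa, dCp))
}

## runs of consecutive residues satisfying a predicate
consecutiveRuns <- function(residues, flag, minRun) {
  keep <- which(flag & !is.na(flag))
  if (!length(keep)) return(NULL)
  res <- residues[keep]
  brk <- c(0, which(diff(res) != 1), length(res))
  out <- list()
  for (b in seq_len(length(brk) - 1)) {
    idx <- (brk[b] + 1):brk[b + 1]
    if (length(idx) >= minRun)
      out[[length(out) + 1]] <- c(start = res[idx[1]], end = res[idx[length(idx)]])
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

#' Classify beta-strand and turn propensity regions
#'
#' Beta-strand propensity: runs of at least \code{minRunBeta}
#' consecutive residues with both \eqn{\Delta\delta_{av} < 0} and
#' \eqn{\Delta\delta C_\alpha < 0}.  Turn-like propensity: runs of at
#' least \code{minRunTurn} residues with \eqn{\Delta\delta_{av} > 0}
#' (positive values over the PGGG motifs signal the beta-turn).  All
#' other residues are coil; residues lacking data are \code{"no-data"}
#' and break runs.
#'
#' @param profile output of \code{\link{secondaryShiftProfile}}.
#' @param minRunBeta minimal beta run length (default 4, "more than
#'   three residues"); per-call configurable since a three-residue
#'   region can be meaningful.
#' @param minRunTurn minimal turn run length (default 3).
#' @return list with \code{regions} (data.frame \code{start},
#'   \code{end}, \code{type}, \code{meanDav}) and \code{profile} (the
#'   input with a \code{propensity} column added).
#' @export
classifyPropensity <- function(profile, minRunBeta = 4, minRunTurn = 3) {
  dAv <- profile$dAv
  betaFlag <- !is.na(dAv) & !is.na(profile$dCa) & dAv < 0 & profile$dCa < 0
  turnFlag <- !is.na(dAv) & dAv > 0
  betaRuns <- consecutiveRuns(profile$residue, betaFlag, minRunBeta)
  turnRuns <- consecutiveRuns(profile$residue, turnFlag, minRunTurn)
  cls <- ifelse(is.na(dAv), "no-data", "coil")
  regions <- list()
  addRuns <- function(runs, type) {
    if (is.null(runs)) return()
    for (r in seq_len(nrow(runs))) {
      sel <- profile$residue >= runs[r, "start"] &
        profile$residue <= runs[r, "end"]
      cls[sel] <<- type
      regions[[length(regions) + 1]] <<- data.frame(
        start = runs[r, "start"], end = runs[r, "end"], type = type,
        meanDav = mean(dAv[sel], na.rm = TRUE))
    }
  }
  addRuns(betaRuns, "beta")
  addRuns(turnRuns, "turn")
  profile$propensity <- cls
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(start = integer(), end = integer(), type = character(),
               meanDav = numeric())
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  list(regions = regions, profile = profile)
}

#' Synthetic chemical-shift table with planted propensity regions
#'
#' Observed shifts are the random-coil reference plus a planted
#' secondary-shift profile: negative runs over the amyloid motifs
#' PHF6* (275-280) and PHF6 (306-311) and over 296-298 (the region
#' corresponding to beta3 of the tau filament), positive runs over the
#' two PGGG motifs (270-273, 301-304), and a small alternating
#' coil dither elsewhere.  The \code{"p301l"} variant shrinks the
#' 296-298 beta run and the 301-304 turn run (the mutation reduces
#' both propensities) and substitutes L301.
#'
#' @param variant \code{"wt"} or \code{"p301l"}.
#' @param noiseSd Gaussian noise on the observed shifts (ppm).
#' @param seed integer seed.
#' @param mutantScale factor applied to the perturbed regions in the
#'   mutant (default 0.25).
#' @return data.frame in the format of
#'   \code{\link{secondaryShiftProfile}} input.
#' @export
syntheticShiftTable <- function(variant = c("wt", "p301l"),
                                noiseSd = 0.05, seed = 1L,
                                mutantScale = 0.25) {
  variant <- match.arg(variant)
  set.seed(seed)
  seqc <- strsplit(tauFragmentSequence(), "")[[1]]
  res <- 225:324
  if (variant == "p301l") seqc[res == 301] <- "L"
  dCa <- 0.12 * (-1)^(res)
  dCp <- 0.12 * (-1)^(res)
  plant <- function(rng, ca, cp) {
    sel <- res >= rng[1] & res <= rng[2]
    dCa[sel] <<- ca
    dCp[sel] <<- cp
  }
  plant(c(275, 280), -1.2, -0.8)
  plant(c(306, 311), -1.2, -0.8)
  scl <- if (variant == "p301l") mutantScale else 1
  plant(c(296, 298), -1.0 * scl, -0.7 * scl)
  plant(c(270, 273), 0.5, 0.9)
  plant(c(301, 304), 0.5 * scl, 0.9 * scl)
  # border residues neither extend a beta run (positive dCa) nor a turn
  # run (negative dAv), keeping the planted region boundaries crisp
  for (b in c(269, 274, 281, 295, 299, 300, 305, 312)) {
    sel <- res == b
    dCa[sel] <- 0.1
    dCp[sel] <- -0.35
  }
  rc <- randomCoilShifts()
  refCa <- rc$CA[match(seqc, rc$residueType)]
  refCp <- rc$C[match(seqc, rc$residueType)]
  n <- length(res)
  rbind(
    data.frame(residue = res, residueType = seqc, atom = "CA",
               shift = refCa + dCa + rnorm(n, 0, noiseSd)),
    data.frame(residue = res, residueType = seqc, atom = "C",
               shift = refCp + dCp + rnorm(n, 0, noiseSd))
  )
}

#' Read backbone 13C shifts from an NMR-STAR file
#'
#' Minimal reader for the \code{Atom_chem_shift} loop of NMR-STAR 3.x
#' chemical-shift deposits: extracts CA and C (carbonyl) rows and
#' returns them in the package's long shift-table format.
#'
#' @param path path to an NMR-STAR file.
#' @return data.frame with columns \code{residue}, \code{residueType},
#'   \code{atom}, \code{shift}.
#' @export
readNmrStar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loopStarts <- which(lines == "loop_")
  for (ls in loopStarts) {
    i <- ls + 1
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i])
      i <- i + 1
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    cols <- sub("^_Atom_chem_shift\\.", "", tags)
    rows <- list()
    while (i <= length(lines) && lines[i] == "") i <- i + 1
    while (i <= length(lines) && !lines[i] %in% c("stop_", "") &&
           !startsWith(lines[i], "_") && !startsWith(lines[i], "save_")) {
      rows[[length(rows) + 1]] <- strsplit(lines[i], "\\s+")[[1]]
      i <- i + 1
    }
    if (!length(rows)) next
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- cols[seq_len(ncol(tab))]
    seqCol <- intersect(c("Seq_ID", "Comp_index_ID"), names(tab))[1]
    atom <- tab$Atom_ID
    sel <- atom %in% c("CA", "C")
    aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
    return(data.frame(
      residue = as.integer(tab[[seqCol]][sel]),
      residueType = unname(aa3[toupper(tab$Comp_ID[sel])]),
      atom = atom[sel],
      shift = as.numeric(tab$Val[sel])))
  }
  stop("no Atom_chem_shift loop found in ", path)
}
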