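#' Write a per-residue rate table to TSV
#'
#' @param table rate table (columns \code{residue}, \code{value},
#'   \code{sd}, \code{masked}, ...).
#' @param path output file.
#' @param quantity optional quantity name recorded in a header comment.
#' @param seed optional seed recorded in a header comment.
#' @return the path, invisibly.
#' @export
writeRateTable <- function(table, path, quantity = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(quantity)) writeLines(paste0("# quantity: ", quantity), con)
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rate table written by \code{\link{writeRateTable}}
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readRateTable <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a peak-intensity table to TSV
#'
#' @param table peak table (columns \code{residue}, \code{delay_s},
#'   \code{intensity}, \code{replicate}).
#' @param path output file.
#' @param seed optional seed recorded in a header comment.
#' @return the path, invisibly.
#' @export
writePeakTable <- function(table, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Sparky-style peak list
#'
#' Reads whitespace-separated peak lists with columns
#' \code{assignment w1 w2 height} (extra columns ignored) and extracts
#' the residue number from assignments such as \code{K254N-H} or
#' \code{V275HN}.
#'
#' @param path peak-list file.
#' @return data.frame with columns \code{residue}, \code{intensity}.
#' @export
readSparkyPeakList <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[1] <- "assignment"
  hcol <- intersect(c("height", "Height", "Data.Height"), names(tab))
  if (!length(hcol)) hcol <- names(tab)[4]
  resno <- as.integer(sub("^[A-Za-z]*([0-9]+).*$", "\\1", tab$assignment))
  data.frame(residue = resno, intensity = as.numeric(tab[[hcol[1]]]))
}

#' Write a correlation map as a square CSV matrix
#'
#' @param map a \linkS4class{CorrelationMap}.
#' @param path output CSV path (residue numbers as headers; invalid
#'   entries empty).
#' @return the path, invisibly.
#' @export
writeCorrelationCsv <- function(map, path) {
  cc <- map@corr
  utils::write.csv(cc, path, na = "")
  invisible(path)
}

#' Write a detected segment table as BED-like TSV
#'
#' @param segments segment data.frame (\code{start}, \code{end},
#'   \code{meanCorr}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSegmentTable <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
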