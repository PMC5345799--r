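#' Genome coordinate model
#'
#' A genome is an ordered table of chromosome names and lengths.  All
#' coordinates in the package are 0-based, half-open; any 1-based inclusive
#' input must be converted at the boundary (see [from_one_based()]).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of chromosome lengths in bp, all > 0.
#' @return An object of class `genome` (a data frame with columns `chrom`
#'   and `length`).
#' @examples
#' gen <- genome(c("chr2L", "chrX"), c(23e6, 22e6))
#' chrom_lengths(gen)
#' @export
genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop("chrom and length must have equal length")
  }
  if (base::length(chrom) == 0L) stop("genome must contain at least one chromosome")
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be finite and > 0")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome", "data.frame")
  )
}

#' Named vector of chromosome lengths
#' @param genome a [genome()] object.
#' @return Named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  stats::setNames(genome$length, genome$chrom)
}

#' Read a chrom.sizes file
#'
#' Two tab-delimited columns: chromosome name, length in bp.
#'
#' @param path path to a chrom.sizes file.
#' @return A [genome()] object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric"))
  genome(tab[[1]], tab[[2]])
}

#' Convert 1-based inclusive interval coordinates to 0-based half-open
#'
#' @param start,end 1-based inclusive start/end positions.
#' @return A list with 0-based half-open `start` and `end`.
#' @examples
#' from_one_based(1, 10)  # -> start 0, end 10
#' @export
from_one_based <- function(start, end) {
  if (any(start < 1) || any(end < start)) {
    stop("1-based coordinates require start >= 1 and end >= start")
  }
  list(start = start - 1, end = end)
}

#' Number of fixed-width bins on a chromosome
#' @param genome a [genome()] object.
#' @param chrom chromosome name.
#' @param bin_width bin width in bp.
#' @return Integer bin count, `ceiling(length / bin_width)`.
#' @export
n_bins <- function(genome, chrom, bin_width) {
  len <- chrom_lengths(genome)
  if (!chrom %in% names(len)) stop("unknown chromosome: ", chrom)
  as.integer(ceiling(len[[chrom]] / bin_width))
}

# internal: check positions lie within [0, chrom length)
check_positions <- function(chrom, pos, genome, what = "feature") {
  len <- chrom_lengths(genome)
  unknown <- setdiff(unique(chrom), names(len))
  if (length(unknown) > 0) {
    stop("unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  bad <- which(pos < 0 | pos >= len[chrom])
  if (length(bad) > 0) {
    stop(sprintf("%s at %s:%g lies outside the chromosome", what,
                 chrom[bad[1]], pos[bad[1]]))
  }
  invisible(TRUE)
}

# internal: INFO-level logging, silenced unless option set
ca_log <- function(fmt, ...) {
  if (isTRUE(getOption("chromarch.verbose", FALSE))) {
    message(sprintf(paste0("[chromarch] ", fmt), ...))
  }
  invisible(NULL)
}
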