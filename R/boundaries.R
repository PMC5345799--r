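#' Extract the border set of a domain map
#'
#' Borders fall at D/E junctions.  A D and an E region separated by an
#' unassigned gap contribute a single border at the gap midpoint; a gap
#' flanked by the same label contributes none.  Chromosome-end borders
#' (position 0 and the chromosome length) are excluded by default, as
#' border-correspondence statistics compare internal boundaries.
#'
#' @param map a [domain_map()].
#' @param include_ends also emit the outermost region edges.
#' @return A [border_set()].
#' @export
domain_borders <- function(map, include_ends = FALSE) {
  stopifnot(inherits(map, "domain_map"))
  chroms <- character(0)
  pos <- numeric(0)
  for (cn in unique(map$chrom)) {
    sub <- map[map$chrom == cn, , drop = FALSE]
    i <- 1L
    while (i < nrow(sub)) {
      a <- sub$label[i]
      if (a %in% c("D", "E")) {
        if (sub$label[i + 1] %in% c("D", "E")) {
          if (sub$label[i + 1] != a) {
            chroms <- c(chroms, cn)
            pos <- c(pos, sub$end[i])
          }
        } else if (i + 2 <= nrow(sub) &&
                   sub$label[i + 2] %in% c("D", "E") &&
                   sub$label[i + 2] != a) {
          # D | gap | E: one border at the gap midpoint
          chroms <- c(chroms, cn)
          pos <- c(pos, (sub$start[i + 1] + sub$end[i + 1]) / 2)
        }
      }
      i <- i + 1L
    }
    if (include_ends && nrow(sub) > 0) {
      chroms <- c(chroms, cn, cn)
      pos <- c(pos, min(sub$start), max(sub$end))
    }
  }
  border_set(chroms, pos, source = "domain_map")
}

#' Border set of an interval table
#'
#' Both edges of every interval; interval sets such as TADs or polytene
#' bands become border sets this way.  Edges at position 0 or at the
#' chromosome length are excluded when a genome is supplied.
#'
#' @param intervals data frame with `chrom`, `start`, `end`.
#' @param genome optional [genome()] used to drop chromosome-end edges.
#' @param source optional source label.
#' @return A [border_set()].
#' @export
interval_borders <- function(intervals, genome = NULL, source = NA_character_) {
  chrom <- rep(intervals$chrom, 2)
  pos <- c(intervals$start, intervals$end)
  if (!is.null(genome)) {
    len <- chrom_lengths(genome)
    keep <- pos > 0 & pos < len[chrom]
    chrom <- chrom[keep]
    pos <- pos[keep]
  }
  border_set(chrom, pos, source = source)
}

#' Distance from each query border to the nearest reference border
#'
#' Query borders on chromosomes absent from the reference are skipped
#' (and counted in attribute `n_skipped`).
#'
#' @param query,reference [border_set()] objects.
#' @return Data frame with `chrom`, `pos`, `distance` (bp).
#' @export
nearest_border_distances <- function(query, reference) {
  stopifnot(inherits(query, "border_set"), inherits(reference, "border_set"))
  out <- list()
  skipped <- 0L
  for (cn in unique(query$chrom)) {
    ref <- reference$pos[reference$chrom == cn]
    q <- query$pos[query$chrom == cn]
    if (length(ref) == 0L) {
      skipped <- skipped + length(q)
      next
    }
    k <- findInterval(q, ref)
    left <- ifelse(k >= 1, q - ref[pmax(k, 1)], Inf)
    right <- ifelse(k < length(ref), ref[pmin(k + 1, length(ref))] - q, Inf)
    out[[cn]] <- data.frame(chrom = cn, pos = q,
                            distance = pmin(left, right),
                            stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    ca_log("nearest_border_distances: %d query borders skipped", skipped)
  }
  res <- if (length(out) > 0) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom = character(), pos = numeric(), distance = numeric())
  }
  attr(res, "n_skipped") <- skipped
  res
}

#' Fraction of distances within a tolerance
#'
#' "Within one 10-kb bin" corresponds to `tolerance = 10000`.
#'
#' @param distances numeric vector, or the data frame returned by
#'   [nearest_border_distances()].
#' @param tolerance distance tolerance in bp (>= 0).
#' @return Proportion of distances `<= tolerance`.
#' @export
fraction_within <- function(distances, tolerance) {
  if (is.data.frame(distances)) distances <- distances$distance
  stopifnot(tolerance >= 0)
  if (length(distances) == 0L) stop("empty distance list")
  mean(distances <= tolerance)
}

#' Histogram of border distances
#'
#' Counts per half-open distance bin `[0, w), [w, 2w), ...` up to
#' `max_distance`, with an overflow bin for larger distances.
#'
#' @param distances numeric vector or [nearest_border_distances()] output.
#' @param bin_width histogram bin width in bp.
#' @param max_distance upper edge of the last regular bin.
#' @return Data frame with `lower`, `upper` (`Inf` for overflow), `count`.
#' @export
distance_histogram <- function(distances, bin_width, max_distance) {
  if (is.data.frame(distances)) distances <- distances$distance
  stopifnot(bin_width > 0, max_distance >= bin_width)
  n_bins <- ceiling(max_distance / bin_width)
  idx <- ifelse(distances > max_distance, n_bins + 1L,
                pmin(floor(distances / bin_width) + 1L, n_bins))
  counts <- tabulate(idx, nbins = n_bins + 1L)
  data.frame(lower = c((seq_len(n_bins) - 1) * bin_width, max_distance),
             upper = c(seq_len(n_bins) * bin_width, Inf),
             count = counts)
}
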