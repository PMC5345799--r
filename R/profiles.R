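#' Scaled-domain tile profile of feature counts
#'
#' Every domain of a label is split into `n_tiles` equal tiles and
#' extended on both sides by `n_flank` tiles of the same (per-domain)
#' width.  Feature counts per tile are summed across domains of the same
#' label and multiplied by `1000 / n`, where `n` is the genome-wide total
#' feature count of the class, making classes of different abundance
#' comparable.  Flank tiles may extend into neighbouring domains; no
#' exclusion is applied.  Domains shorter than `n_tiles` bp are skipped.
#'
#' @param features a [feature_set()] (one class at a time, or use the
#'   `class` column and call per class).
#' @param map a [domain_map()].
#' @param n_tiles tiles per domain body (80 in the original analysis).
#' @param n_flank flank tiles per side (10 in the original analysis).
#' @param labels domain labels to profile.
#' @return Data frame with `label`, `tile` (1-based over
#'   `n_flank + n_tiles + n_flank`), `count` (raw summed count) and
#'   `scaled` (count * 1000/n).  Attribute `n_skipped` counts skipped
#'   short domains.
#' @export
scaled_tile_profile <- function(features, map, n_tiles = 80, n_flank = 10,
                                labels = c("D", "E")) {
  stopifnot(inherits(features, "feature_set"), inherits(map, "domain_map"),
            n_tiles > 0, n_flank >= 0)
  n_total <- nrow(features)
  if (n_total == 0L) stop("empty feature set")
  width <- n_tiles + 2L * n_flank
  out <- list()
  n_skipped <- 0L
  for (lb in labels) {
    counts <- numeric(width)
    doms <- map[map$label == lb, , drop = FALSE]
    for (i in seq_len(nrow(doms))) {
      dlen <- doms$end[i] - doms$start[i]
      if (dlen < n_tiles) {
        n_skipped <- n_skipped + 1L
        next
      }
      tw <- dlen / n_tiles
      fi <- which(features$chrom == doms$chrom[i] &
                    features$pos >= doms$start[i] - n_flank * tw &
                    features$pos < doms$end[i] + n_flank * tw)
      if (length(fi) == 0L) next
      off <- features$pos[fi] - doms$start[i]
      tile <- floor(off / tw)
      inside <- off >= 0 & off < dlen
      tile[inside] <- pmin(pmax(tile[inside], 0), n_tiles - 1)
      tile <- tile + n_flank + 1L
      tile <- tile[tile >= 1 & tile <= width]
      counts <- counts + tabulate(tile, nbins = width)
    }
    out[[lb]] <- data.frame(label = lb, tile = seq_len(width),
                            count = counts,
                            scaled = counts * 1000 / n_total,
                            stringsAsFactors = FALSE)
  }
  if (n_skipped > 0) {
    ca_log("scaled_tile_profile: %d domains shorter than %d bp skipped",
           n_skipped, n_tiles)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Accumulation profile of features around anchors
#'
#' Feature counts per offset bin relative to each anchor, summed over
#' anchors, scaled by `1000 / n` (n = feature total), divided by the
#' number of anchors, and finally mapped affinely so the profile minimum
#' is 0 and the maximum 10.
#'
#' @param features a [feature_set()].
#' @param anchors a [feature_set()] or [border_set()] supplying anchor
#'   positions.
#' @param window half-window in bp.
#' @param bin offset bin width in bp.
#' @return Data frame with `offset` (bin centre, bp), `count` (raw),
#'   `normalised` (1000/n-scaled, per anchor) and `scaled` (0-10 range).
#' @export
accumulation_profile <- function(features, anchors, window, bin) {
  stopifnot(inherits(features, "feature_set"), window > 0, bin > 0)
  apos <- anchors$pos
  achrom <- anchors$chrom
  n_anchor <- length(apos)
  if (n_anchor == 0L) stop("zero anchors")
  n_total <- nrow(features)
  if (n_total == 0L) stop("empty feature set")
  n_bins_side <- ceiling(window / bin)
  width <- 2L * n_bins_side
  counts <- numeric(width)
  for (cn in unique(achrom)) {
    fpos <- features$pos[features$chrom == cn]
    if (length(fpos) == 0L) next
    for (a in apos[achrom == cn]) {
      off <- fpos - a
      off <- off[off >= -window & off < window]
      if (length(off) == 0L) next
      idx <- floor(off / bin) + n_bins_side + 1L
      idx <- idx[idx >= 1 & idx <= width]
      counts <- counts + tabulate(idx, nbins = width)
    }
  }
  normalised <- counts * 1000 / n_total / n_anchor
  rng <- range(normalised)
  scaled <- if (rng[2] > rng[1]) {
    (normalised - rng[1]) / (rng[2] - rng[1]) * 10
  } else {
    rep(0, width)
  }
  data.frame(offset = (seq_len(width) - n_bins_side - 0.5) * bin,
             count = counts, normalised = normalised, scaled = scaled)
}

#' D/E occupancy across scaled band intervals
#'
#' Bands at least `min_length` bp long are linearly rescaled to
#' `target_length`; unscaled flanks of `flank` bp are appended on both
#' sides.  At each sampled position, the fraction of bands whose covering
#' domain is D (or E, or unassigned) is reported; the three fractions sum
#' to 1 at every position.
#'
#' @param map a [domain_map()].
#' @param bands data frame of band intervals (`chrom`, `start`, `end`).
#' @param target_length scaled body length in bp (200 kb in the original
#'   analysis).
#' @param flank unscaled flank in bp (50 kb).
#' @param min_length minimum band length, strict (75 kb: "over 75 kb").
#' @param step sampling step in bp.
#' @return Data frame with `position` (bp on the scaled axis, 0 = band
#'   start), `frac_D`, `frac_E`, `frac_gap`.
#' @export
scaled_interval_overlay <- function(map, bands, target_length = 200000,
                                    flank = 50000, min_length = 75000,
                                    step = 1000) {
  stopifnot(inherits(map, "domain_map"), target_length > 0, flank >= 0)
  bands <- bands[bands$end - bands$start > min_length, , drop = FALSE]
  if (nrow(bands) == 0L) stop("no bands longer than min_length")
  positions <- seq(-flank, target_length + flank, by = step)
  n_pos <- length(positions)
  acc <- matrix(0, n_pos, 3, dimnames = list(NULL, c("D", "E", "gap")))
  for (i in seq_len(nrow(bands))) {
    blen <- bands$end[i] - bands$start[i]
    g <- ifelse(positions < 0, bands$start[i] + positions,
                ifelse(positions > target_length,
                       bands$end[i] + (positions - target_length),
                       bands$start[i] + positions / target_length * blen))
    lab <- locate_in_map(rep(bands$chrom[i], n_pos), g, map)
    li <- match(lab, colnames(acc))
    acc[cbind(seq_len(n_pos), li)] <- acc[cbind(seq_len(n_pos), li)] + 1
  }
  data.frame(position = positions,
             frac_D = acc[, "D"] / nrow(bands),
             frac_E = acc[, "E"] / nrow(bands),
             frac_gap = acc[, "gap"] / nrow(bands))
}
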