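#' Short-/long-range interaction fractions per bin
#'
#' For each anchor bin, interactions to partners within `max_distance` on
#' both sides are collected and the anchor's interaction vector is
#' normalised to sum 1.  The short-range fraction is the normalised mass
#' at distances within `short_range` (5-50 kb: partners at least one bin
#' away), the long-range fraction the mass within `long_range`
#' (50-500 kb, lower bound exclusive).  Anchors within `end_exclusion`
#' of either chromosome end, anchors with no interactions, and anchors
#' whose raw interaction sum exceeds the `high_percentile` percentile of
#' retained sums are excluded.
#'
#' @param cm a [contact_matrix()] (5-kb resolution in the original
#'   analysis).
#' @param short_range,long_range numeric length-2 distance windows in bp;
#'   short is closed, long is left-open.
#' @param max_distance maximum collected distance (1 Mb).
#' @param end_exclusion chromosome-end exclusion in bp (1 Mb).
#' @param high_percentile exclusion percentile for extreme sums (97.5).
#' @return Data frame with one row per bin: `bin`, `start`, `retained`,
#'   `total` (raw sum), `short`, `long`, `ratio` (short/long, `NA` when
#'   undefined); `short`/`long`/`ratio` are `NA` for excluded bins.
#' @export
distance_fraction_profile <- function(cm, short_range = c(5000, 50000),
                                      long_range = c(50000, 500000),
                                      max_distance = 1e6,
                                      end_exclusion = 1e6,
                                      high_percentile = 97.5) {
  stopifnot(inherits(cm, "contact_matrix"))
  res <- cm$resolution
  m <- cm$values
  n <- nrow(m)
  max_d <- floor(max_distance / res)
  total <- numeric(n)
  short <- numeric(n)
  long <- numeric(n)
  for (d in seq_len(min(max_d, n - 1))) {
    v <- m[cbind(seq_len(n - d), seq_len(n - d) + d)]
    v[is.na(v)] <- 0
    dist_bp <- d * res
    in_short <- dist_bp >= short_range[1] && dist_bp <= short_range[2]
    in_long <- dist_bp > long_range[1] && dist_bp <= long_range[2]
    # partner at +d for anchors 1..n-d, at -d for anchors d+1..n
    total[seq_len(n - d)] <- total[seq_len(n - d)] + v
    total[seq_len(n - d) + d] <- total[seq_len(n - d) + d] + v
    if (in_short) {
      short[seq_len(n - d)] <- short[seq_len(n - d)] + v
      short[seq_len(n - d) + d] <- short[seq_len(n - d) + d] + v
    }
    if (in_long) {
      long[seq_len(n - d)] <- long[seq_len(n - d)] + v
      long[seq_len(n - d) + d] <- long[seq_len(n - d) + d] + v
    }
  }
  starts <- (seq_len(n) - 1) * res
  interior <- starts >= end_exclusion & (n * res - (starts + res)) >= end_exclusion
  nonzero <- total > 0
  kept <- interior & nonzero
  if (any(kept)) {
    cutoff <- stats::quantile(total[kept], high_percentile / 100, names = FALSE)
    kept <- kept & total <= cutoff
  }
  short_f <- ifelse(kept, short / total, NA_real_)
  long_f <- ifelse(kept, long / total, NA_real_)
  ratio <- ifelse(kept & long > 0, short / long, NA_real_)
  ca_log("distance_fraction_profile: %s %d/%d bins retained", cm$chrom,
         sum(kept), n)
  data.frame(bin = seq_len(n), start = starts, retained = kept,
             total = total, short = short_f, long = long_f, ratio = ratio)
}

# internal: 1-based indices of bins lying entirely inside [start, end)
bins_inside <- function(start, end, resolution, n) {
  lo <- ceiling(start / resolution) + 1
  hi <- floor(end / resolution)
  if (hi < lo || hi > n || lo < 1) return(integer(0))
  seq.int(lo, hi)
}

#' Within-domain interaction distance profiles for D and E
#'
#' For every domain longer than `min_length`, normalised counts of bin
#' pairs lying entirely inside the domain are collected into distance
#' bins (one bin per multiple of the resolution).  Per label, the median
#' count per distance bin is computed; a two-sided rank-sum test compares
#' the two labels' per-distance-bin medians over the distances observed
#' in both.
#'
#' @param cm a normalised [contact_matrix()] (10-kb resolution in the
#'   original analysis).
#' @param map a [domain_map()].
#' @param min_length minimum domain length in bp, strict (30 kb).
#' @return List with `table` (data frame `distance`, `median_D`,
#'   `median_E`, `n_D`, `n_E`), `p_value` (Wilcoxon rank-sum on the
#'   per-distance medians) and `n_domains` (named count per label).
#' @export
domain_distance_profile <- function(cm, map, min_length = 30000) {
  stopifnot(inherits(cm, "contact_matrix"), inherits(map, "domain_map"),
            min_length >= cm$resolution)
  res <- cm$resolution
  n <- nrow(cm$values)
  sub <- map[map$chrom == cm$chrom & map$label %in% c("D", "E") &
               (map$end - map$start) > min_length, , drop = FALSE]
  n_domains <- c(D = sum(sub$label == "D"), E = sum(sub$label == "E"))
  if (any(n_domains == 0)) {
    stop("no qualifying domains for label: ",
         paste(names(n_domains)[n_domains == 0], collapse = ", "))
  }
  vals <- list(D = list(), E = list())
  for (i in seq_len(nrow(sub))) {
    bins <- bins_inside(sub$start[i], sub$end[i], res, n)
    if (length(bins) < 2) next
    pairs <- utils::combn(bins, 2)
    d <- pairs[2, ] - pairs[1, ]
    v <- cm$values[cbind(pairs[1, ], pairs[2, ])]
    keep <- !is.na(v)
    lb <- sub$label[i]
    vals[[lb]][[length(vals[[lb]]) + 1L]] <-
      data.frame(distance = d[keep] * res, value = v[keep])
  }
  med <- lapply(vals, function(lst) {
    if (length(lst) == 0L) return(NULL)
    all <- do.call(rbind, lst)
    data.frame(distance = as.numeric(names(tapply(all$value, all$distance, stats::median))),
               median = as.numeric(tapply(all$value, all$distance, stats::median)),
               n = as.numeric(table(all$distance)))
  })
  common <- intersect(med$D$distance, med$E$distance)
  if (length(common) == 0L) stop("no common distance bins between D and E")
  dd <- med$D[match(common, med$D$distance), ]
  ee <- med$E[match(common, med$E$distance), ]
  pv <- stats::wilcox.test(dd$median, ee$median, exact = FALSE)$p.value
  list(table = data.frame(distance = common, median_D = dd$median,
                          median_E = ee$median, n_D = dd$n, n_E = ee$n),
       p_value = pv, n_domains = n_domains)
}

#' Detect D-D corner interaction hotspots over E domains
#'
#' Eligible E domains are those at least `min_e_length` long with a D
#' domain immediately adjacent on both sides (gaps break adjacency).
#' The corner region is the bin rectangle formed by the flanking D bins
#' (at most `max_flank_bins` per side, nearest the E domain) sitting atop
#' the E block.  Densities are aggregate observed/expected ratios: the
#' sum of values over the region divided by the sum of the matrix-wide
#' per-distance means over the same cells (removing the distance-decay
#' confound with minimal estimator variance).  The neighbour density is, by default
#' (`"adjacent_dd"`), the mean over the two same-shape rectangles that
#' couple each flanking D domain with the next D domain further out:
#' these cells belong to the same D-D coverage class as the corner, so
#' the comparison is unbiased under coverage-product normalisation,
#' which systematically inflates low-coverage D-D cells relative to
#' E-involving cells.  Alternatives: `"shifted"` (same-shape rectangles
#' shifted along the genome by one rectangle width, same interaction
#' distance) and `"ring"` (one-bin ring around the corner); both draw
#' neighbour cells partly from E-involving coverage classes and run hot.
#' A hotspot requires corner density strictly greater than
#' `fold_threshold` times the neighbour density.
#'
#' @param cm a normalised [contact_matrix()] (10-kb resolution).
#' @param map a [domain_map()].
#' @param min_e_length eligibility length threshold in bp (60 kb).
#' @param fold_threshold density ratio threshold (1.1).
#' @param max_flank_bins corner size cap per flanking D side (10 bins).
#' @param neighbour neighbour-density definition: `"adjacent_dd"`
#'   (default), `"shifted"` or `"ring"`.
#' @return Data frame with one row per eligible E domain: `chrom`,
#'   `start`, `end`, `corner`, `neighbour`, `ratio`, `hotspot`.
#' @export
detect_dd_hotspots <- function(cm, map, min_e_length = 60000,
                               fold_threshold = 1.1, max_flank_bins = 10,
                               neighbour = c("adjacent_dd", "shifted", "ring")) {
  neighbour <- match.arg(neighbour)
  stopifnot(inherits(cm, "contact_matrix"), inherits(map, "domain_map"),
            fold_threshold > 0, min_e_length >= cm$resolution)
  res <- cm$resolution
  n <- nrow(cm$values)
  sub <- map[map$chrom == cm$chrom, , drop = FALSE]
  corners <- eligible_e_corners(sub, n, res, min_e_length, max_flank_bins)
  # remove residual per-bin visibility by iterative proportional fitting
  # over cross-domain cells: coverage-product normalisation leaves
  # per-bin multiplicative residuals that would enter the corner and its
  # neighbours through different domains and confound the density ratio;
  # cross-domain cells isolate visibility from genuine domain structure
  dom_idx <- bin_domain_index(sub, n, res)
  same_dom <- outer(dom_idx, dom_idx, "==")
  same_dom[is.na(same_dom)] <- FALSE
  vals <- cm$values
  cross <- vals
  cross[same_dom] <- NA
  dmat <- abs(row(vals) - col(vals))
  dvec <- as.vector(dmat) + 1L
  fac <- rep(1, n)
  md <- rep(1, n)
  for (it in seq_len(30)) {
    u <- cross / outer(fac, fac)
    uv <- as.vector(u)
    ok <- !is.na(uv)
    md <- as.vector(rowsum(uv[ok], dvec[ok])) /
      as.vector(rowsum(rep(1, sum(ok)), dvec[ok]))
    md_full <- rep(NA_real_, n)
    md_full[sort(unique(dvec[ok]))] <- md
    r <- rowMeans(u / matrix(md_full[dvec], n, n), na.rm = TRUE)
    r[!is.finite(r) | r <= 0] <- NA
    r <- r / mean(r, na.rm = TRUE)
    r[is.na(r)] <- 1
    fac <- fac * r
  }
  vals <- vals / outer(fac, fac)
  md_full <- rep(NA_real_, n)
  uv <- as.vector(cross / outer(fac, fac))
  ok <- !is.na(uv)
  md_full[sort(unique(dvec[ok]))] <- as.vector(rowsum(uv[ok], dvec[ok])) /
    as.vector(rowsum(rep(1, sum(ok)), dvec[ok]))
  mdmat <- matrix(md_full[dvec], n, n)
  # flanking-D bin runs, used by the adjacent_dd neighbour
  dom_full_bins <- function(i) {
    midpoint_bins(sub$start[i], sub$end[i], res, n)
  }
  rect_sums <- function(rows, cols) {
    rows <- rows[rows >= 1 & rows <= n]
    cols <- cols[cols >= 1 & cols <= n]
    if (length(rows) == 0L || length(cols) == 0L) return(c(0, 0, 0))
    v <- vals[rows, cols, drop = FALSE]
    e <- mdmat[rows, cols, drop = FALSE]
    ok <- !is.na(v) & !is.na(e)
    c(sum(v[ok]), sum(e[ok]), sum(ok))
  }
  # aggregate observed/expected with one expected-cell of smoothing,
  # stabilising single-cell corner densities
  density_of <- function(s) {
    if (s[2] <= 0 || s[3] == 0) return(NA_real_)
    pseudo <- s[2] / s[3]
    (s[1] + pseudo) / (s[2] + pseudo)
  }
  out <- lapply(corners, function(rect) {
    corner <- density_of(rect_sums(rect$left, rect$right))
    nb <- if (neighbour == "adjacent_dd") {
      d_rows <- which(sub$label == "D")
      prev_d <- d_rows[d_rows < rect$row - 1L]
      next_d <- d_rows[d_rows > rect$row + 1L]
      s <- c(0, 0, 0)
      if (length(prev_d) > 0) {
        pb <- utils::tail(dom_full_bins(max(prev_d)), max_flank_bins)
        s <- s + rect_sums(pb, rect$right)
      }
      if (length(next_d) > 0) {
        nb2 <- utils::head(dom_full_bins(min(next_d)), max_flank_bins)
        s <- s + rect_sums(rect$left, nb2)
      }
      density_of(s)
    } else if (neighbour == "shifted") {
      w <- max(length(rect$left), length(rect$right))
      density_of(rect_sums(rect$left - w, rect$right - w) +
                   rect_sums(rect$left + w, rect$right + w))
    } else {
      ring_rows <- (min(rect$left) - 1L):(max(rect$left) + 1L)
      ring_cols <- (min(rect$right) - 1L):(max(rect$right) + 1L)
      cells <- expand.grid(r = ring_rows, c = ring_cols)
      on_ring <- cells$r < min(rect$left) | cells$r > max(rect$left) |
        cells$c < min(rect$right) | cells$c > max(rect$right)
      cells <- cells[on_ring & cells$r >= 1 & cells$r <= n &
                       cells$c >= 1 & cells$c <= n, ]
      if (nrow(cells) == 0L) NA_real_ else {
        v <- vals[cbind(cells$r, cells$c)]
        e <- mdmat[cbind(cells$r, cells$c)]
        ok <- !is.na(v) & !is.na(e)
        density_of(c(sum(v[ok]), sum(e[ok]), sum(ok)))
      }
    }
    data.frame(chrom = cm$chrom, start = sub$start[rect$row],
               end = sub$end[rect$row], corner = corner, neighbour = nb,
               ratio = corner / nb,
               hotspot = is.finite(corner / nb) &
                 corner > fold_threshold * nb,
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      corner = numeric(), neighbour = numeric(),
                      ratio = numeric(), hotspot = logical()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
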