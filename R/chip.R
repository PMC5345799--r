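#' Quantile-normalise a set of signal vectors
#'
#' Each output vector is a rank-preserving rearrangement of the common
#' reference distribution (the mean of order statistics across inputs),
#' with ties averaged.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param tracks list of numeric vectors of equal length (no missing
#'   values; apply the probe mask first), or a numeric matrix with one
#'   vector per column.
#' @return List (or matrix, matching the input) of normalised vectors.
#' @export
quantile_normalize <- function(tracks) {
  as_list <- is.list(tracks)
  m <- if (as_list) {
    if (length(tracks) < 2L) stop("need at least 2 vectors")
    n <- unique(lengths(tracks))
    if (length(n) != 1L) stop("vectors differ in length")
    do.call(cbind, tracks)
  } else {
    as.matrix(tracks)
  }
  if (ncol(m) < 2L) stop("need at least 2 vectors")
  if (anyNA(m)) stop("missing values not allowed; mask probes first")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  if (as_list) {
    res <- lapply(seq_len(ncol(out)), function(j) out[, j])
    names(res) <- names(tracks)
    res
  } else {
    out
  }
}

#' Scale a score vector so its median equals a target
#'
#' Multiplicative rescaling, as applied per array channel (target 500 in
#' the original processing).
#'
#' @param x numeric vector with positive median.
#' @param target target median.
#' @return Rescaled vector with `median(result) == target`.
#' @export
scale_median <- function(x, target = 500) {
  m <- stats::median(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("median must be positive")
  x * (target / m)
}

#' Bin a probe-level track by averaging
#'
#' Each probe is located by its interval midpoint; a bin's score is the
#' mean of the scores of probes whose midpoint falls in the bin.  Bins
#' with no probes are missing (`NA`), never zero.
#'
#' @param probes a `probe_track` data frame (chrom, start, end, score),
#'   e.g. from [read_bedgraph()].
#' @param genome a [genome()] object.
#' @param bin_width bin width in bp (1 kb in the original processing).
#' @return A [binned_track()].
#' @export
bin_track <- function(probes, genome, bin_width = 1000) {
  stopifnot(bin_width > 0)
  len <- chrom_lengths(genome)
  scores <- lapply(names(len), function(cn) {
    n <- as.integer(ceiling(len[[cn]] / bin_width))
    sub <- probes[probes$chrom == cn, , drop = FALSE]
    sc <- rep(NA_real_, n)
    if (nrow(sub) > 0) {
      mid <- (sub$start + sub$end) / 2
      idx <- pmin(floor(mid / bin_width) + 1L, n)
      sums <- rowsum(sub$score, idx)
      counts <- rowsum(rep(1, nrow(sub)), idx)
      sc[as.integer(rownames(sums))] <- sums[, 1] / counts[, 1]
    }
    sc
  })
  names(scores) <- names(len)
  binned_track(genome, bin_width, scores)
}

#' Median signal in symmetric windows around point features
#'
#' For each feature, the median of the scores overlapping
#' `[pos - half_width, pos + half_width]` (closed window, 500 bp by
#' default).  Works on a probe-level track (probe intervals overlapping
#' the window) or a [binned_track()] (bins overlapping the window).
#' Features with no covered score are `NA`.
#'
#' @param track a `probe_track` data frame or a [binned_track()].
#' @param features a [feature_set()] (class labels carried through).
#' @param half_width window half-width in bp.
#' @return Data frame (class `class_score_table`) with columns `chrom`,
#'   `pos`, `class`, `score`.
#' @export
tss_window_median <- function(track, features, half_width = 500) {
  stopifnot(half_width > 0, inherits(features, "feature_set"))
  score <- rep(NA_real_, nrow(features))
  if (inherits(track, "binned_track")) {
    bw <- track$bin_width
    for (cn in unique(features$chrom)) {
      sc <- track$scores[[cn]]
      if (is.null(sc)) next
      fi <- which(features$chrom == cn)
      for (i in fi) {
        lo <- max(1L, floor((features$pos[i] - half_width) / bw) + 1L)
        hi <- min(length(sc), floor((features$pos[i] + half_width) / bw) + 1L)
        if (hi < lo) next
        v <- sc[lo:hi]
        v <- v[!is.na(v)]
        if (length(v) > 0) score[i] <- stats::median(v)
      }
    }
  } else {
    for (cn in unique(features$chrom)) {
      sub <- track[track$chrom == cn, , drop = FALSE]
      if (nrow(sub) == 0L) next
      fi <- which(features$chrom == cn)
      for (i in fi) {
        # probes sorted, non-overlapping: overlap of a closed window
        # [w1, w2] with [start, end) requires end > w1 and start <= w2
        lo <- findInterval(features$pos[i] - half_width, sub$end) + 1L
        hi <- findInterval(features$pos[i] + half_width, sub$start)
        if (hi >= lo) score[i] <- stats::median(sub$score[lo:hi])
      }
    }
  }
  out <- data.frame(chrom = features$chrom, pos = features$pos,
                    class = features$class, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_score_table", "data.frame")
  out
}

#' Relative position of a class mean between two anchor means
#'
#' Places `mean_x` on the axis where the housekeeping-class mean is 0 and
#' the Polycomb-target-class mean is 1:
#' `(mean_x - mean_hk) / (mean_pc - mean_hk)`.
#'
#' @param mean_hk,mean_pc,mean_x class mean scores.
#' @return Unitless ratio.
#' @export
relative_class_position <- function(mean_hk, mean_pc, mean_x) {
  if (mean_pc == mean_hk) stop("anchor means are equal; scale undefined")
  (mean_x - mean_hk) / (mean_pc - mean_hk)
}
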