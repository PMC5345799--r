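#' Maximum-likelihood block segmentation of a contact matrix
#'
#' Block-diagonal Gaussian model on `log(1 + x)`-transformed normalised
#' values: cells within a diagonal block share a block mean, all other
#' cells share a single background mean `mu0`, with a common variance.
#' For each boundary count `K <= max_boundaries` the optimal boundaries
#' are found exactly by dynamic programming over segment endpoints.
#' Masked (`NA`) cells carry no likelihood term.
#'
#' Per-boundary log-likelihood gains are computed along a greedy forward
#' selection over the K = `max_boundaries` solution: boundaries are added
#' one at a time, each scored by its marginal log-likelihood increase.
#'
#' @param cm a normalised [contact_matrix()].
#' @param max_boundaries maximum number of internal boundaries (default
#'   `floor(bins / 15)`, i.e. mean TAD length >= 150 kb at 10-kb bins).
#' @param background off-block mean on the transformed scale; default is
#'   the mean over all unmasked transformed cells.
#' @param transform `TRUE` (default) applies `log1p` to the values.
#' @param max_band maximum interaction distance (bp) contributing to the
#'   likelihood (default 500 kb, the long-range limit of the
#'   interaction-distance analysis).  Cells at larger distance carry no
#'   boundary-scale information but otherwise dominate the cell count;
#'   `Inf` disables the band.
#' @return An object of class `tad_segmentation`: list with `chrom`,
#'   `resolution`, `boundaries` (bin indices, a boundary `b` falls at
#'   `b * resolution` bp), `gains` (per-boundary log-likelihood gain,
#'   aligned with `boundaries`), `loglik` (total model log-likelihood
#'   for K = 0..max_boundaries) and `background`.
#' @export
segment_matrix <- function(cm, max_boundaries = NULL, background = NULL,
                           transform = TRUE, max_band = 500000) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- nrow(cm$values)
  if (n < 3) stop("matrix must have at least 3 bins")
  y <- if (transform) log1p(cm$values) else cm$values
  if (is.finite(max_band)) {
    band_bins <- floor(max_band / cm$resolution)
    y[abs(row(y) - col(y)) > band_bins] <- NA
  }
  if (is.null(max_boundaries)) max_boundaries <- max(1L, floor(n / 15))
  max_boundaries <- min(max_boundaries, n - 1L)
  if (max_boundaries < 1) stop("max_boundaries must be >= 1")
  mu0 <- if (is.null(background)) mean(y, na.rm = TRUE) else background
  z <- y - mu0
  obs <- !is.na(z)
  z[!obs] <- 0
  M <- sum(obs)
  tss <- sum(z^2)

  # padded 2-D prefix sums of z and of the observed-cell indicator
  pad2 <- function(m) {
    p <- matrix(0, n + 1, n + 1)
    p[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum)
    t(p)
  }
  Pz <- pad2(z)
  Pc <- pad2(obs * 1)
  dPz <- diag(Pz)
  dPc <- diag(Pc)
  # gain of diagonal block [a..b]^2: m_block * (mu_block - mu0)^2
  gain_vec <- function(b) {
    a <- seq_len(b)
    zs <- Pz[b + 1, b + 1] - Pz[a, b + 1] - Pz[b + 1, a] + dPz[a]
    mc <- Pc[b + 1, b + 1] - Pc[a, b + 1] - Pc[b + 1, a] + dPc[a]
    ifelse(mc > 0, zs^2 / mc, 0)
  }

  S <- max_boundaries + 1L       # segments
  best <- matrix(-Inf, S, n)
  arg <- matrix(0L, S, n)
  g_by_end <- lapply(seq_len(n), gain_vec)  # g_by_end[[b]][a] = gain(a, b)
  best[1, ] <- vapply(seq_len(n), function(b) g_by_end[[b]][1], 0)
  for (s in 2:S) {
    for (b in s:n) {
      cand <- best[s - 1, (s - 1):(b - 1)] + g_by_end[[b]][s:b]
      k <- which.max(cand)
      best[s, b] <- cand[k]
      arg[s, b] <- (s - 1L) + k - 1L   # end bin of previous segment
    }
  }

  ll_of_gain <- function(g) {
    sse <- max(tss - g, 1e-12)
    -M / 2 * (log(2 * pi) + log(sse / M) + 1)
  }
  loglik <- vapply(seq_len(S), function(s) {
    ll_of_gain(if (s == 1) g_by_end[[n]][1] else best[s, n])
  }, 0)

  backtrack <- function(s) {
    bounds <- integer(0)
    b <- n
    while (s > 1) {
      prev <- arg[s, b]
      bounds <- c(prev, bounds)
      b <- prev
      s <- s - 1L
    }
    bounds
  }
  boundaries <- backtrack(S)

  # greedy forward selection within the DP-optimal boundary set
  seg_gain <- function(bounds) {
    cuts <- c(0L, sort(bounds), n)
    sum(vapply(seq_len(length(cuts) - 1L),
               function(i) g_by_end[[cuts[i + 1]]][cuts[i] + 1L], 0))
  }
  gains <- rep(NA_real_, length(boundaries))
  chosen <- integer(0)
  ll_cur <- ll_of_gain(seg_gain(integer(0)))
  remaining <- boundaries
  while (length(remaining) > 0) {
    ll_new <- vapply(remaining,
                     function(b) ll_of_gain(seg_gain(c(chosen, b))), 0)
    k <- which.max(ll_new)
    gains[match(remaining[k], boundaries)] <- ll_new[k] - ll_cur
    ll_cur <- ll_new[k]
    chosen <- c(chosen, remaining[k])
    remaining <- remaining[-k]
  }

  structure(list(chrom = cm$chrom, resolution = cm$resolution,
                 boundaries = boundaries, gains = gains, loglik = loglik,
                 background = mu0),
            class = "tad_segmentation")
}

#' @export
print.tad_segmentation <- function(x, ...) {
  cat(sprintf("tad_segmentation: %s, %d boundaries\n", x$chrom,
              length(x$boundaries)))
  invisible(x)
}

#' Filter segmentation boundaries by log-likelihood gain
#'
#' Boundaries are ranked by individual gain (descending); the elbow of
#' the sorted gain curve is located as the point of maximum distance to
#' the chord joining the first and last points.  Boundaries from the
#' elbow onward form the "linear portion", and the lowest `drop_fraction`
#' of that portion (by gain rank, ties broken by genomic position with
#' the leftmost kept) is removed.
#'
#' @param seg a `tad_segmentation` from [segment_matrix()].
#' @param drop_fraction fraction of the linear portion to drop (0.10 in
#'   the original analysis); 0 retains everything.
#' @return Integer vector of retained boundary bin indices in genomic
#'   order.
#' @export
filter_boundaries <- function(seg, drop_fraction = 0.10) {
  stopifnot(inherits(seg, "tad_segmentation"),
            drop_fraction >= 0, drop_fraction < 1)
  b <- seg$boundaries
  g <- seg$gains
  if (length(b) < 3) {
    if (length(b) > 0) warning("fewer than 3 boundaries; all retained")
    return(sort(b))
  }
  if (drop_fraction == 0) return(sort(b))
  ord <- order(-g, b)
  gs <- g[ord]
  n <- length(gs)
  # chord distance from (i, g_i) to the line (1, g_1)-(n, g_n)
  dx <- n - 1
  dy <- gs[n] - gs[1]
  dist <- abs(dy * (seq_len(n) - 1) - dx * (gs - gs[1])) / sqrt(dx^2 + dy^2)
  elbow <- which.max(dist)
  portion <- elbow:n
  n_drop <- floor(drop_fraction * length(portion) + 1e-9)
  if (n_drop == 0) return(sort(b))
  port_idx <- ord[portion]
  drop_order <- port_idx[order(g[port_idx], -b[port_idx])]
  dropped <- drop_order[seq_len(n_drop)]
  sort(b[-dropped])
}

#' Convert boundaries to TAD intervals
#'
#' Consecutive boundaries plus the chromosome ends define the TADs; the
#' interval set tiles the chromosome exactly.
#'
#' @param boundaries sorted boundary bin indices.
#' @param chrom_length chromosome length in bp.
#' @param resolution bin width in bp.
#' @param chrom chromosome name.
#' @return Data frame of TAD intervals (`chrom`, `start`, `end`).
#' @export
boundaries_to_tads <- function(boundaries, chrom_length, resolution,
                               chrom = "chr") {
  bp <- sort(boundaries) * resolution
  starts <- c(0, bp)
  ends <- c(bp, chrom_length)
  data.frame(chrom = chrom, start = starts, end = ends,
             stringsAsFactors = FALSE)
}
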