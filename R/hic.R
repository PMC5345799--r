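#' Bin valid pairs into per-chromosome contact matrices
#'
#' Intra-chromosomal pairs increment the count at
#' `(floor(pos1/res), floor(pos2/res))`, symmetrised; a pair with both
#' ends in one bin increments the diagonal once.  Trans pairs are counted
#' and discarded.
#'
#' @param pairs data frame from [read_pairs()] (columns `chrom1`, `pos1`,
#'   `chrom2`, `pos2`).
#' @param genome a [genome()] object.
#' @param resolution bin width in bp (10 kb in the original analysis).
#' @return Named list of raw-count [contact_matrix()] objects, one per
#'   chromosome with data; attribute `n_trans` gives the discarded
#'   trans-pair count.
#' @export
bin_pairs <- function(pairs, genome, resolution = 10000) {
  stopifnot(resolution > 0)
  len <- chrom_lengths(genome)
  trans <- pairs$chrom1 != pairs$chrom2
  n_trans <- sum(trans)
  cis <- pairs[!trans, , drop = FALSE]
  ca_log("bin_pairs: %d intra pairs retained, %d trans pairs discarded",
         nrow(cis), n_trans)
  out <- list()
  for (cn in intersect(names(len), unique(cis$chrom1))) {
    sub <- cis[cis$chrom1 == cn, , drop = FALSE]
    n <- as.integer(ceiling(len[[cn]] / resolution))
    i <- pmin(floor(sub$pos1 / resolution) + 1L, n)
    j <- pmin(floor(sub$pos2 / resolution) + 1L, n)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    m <- matrix(0, n, n)
    tab <- tabulate((hi - 1L) * n + lo, nbins = n * n)
    m[] <- tab
    m <- m + t(m) - diag(diag(m))
    out[[cn]] <- contact_matrix(cn, resolution, m)
  }
  attr(out, "n_trans") <- n_trans
  out
}

#' Normalise a contact matrix by the coverage-product expected model
#'
#' Binomial coverage-product observed/expected normalisation: with total
#' intra-chromosomal pair count `N` and relative coverage
#' `r_i` = (read ends in bin i) / (2N) (a diagonal pair contributes both
#' ends to its bin, so the shares sum to 1), the expected count is
#' `2 r_i r_j N` off the diagonal and `r_i^2 N` on it; the normalised
#' value is observed/expected.  Bins with zero coverage are masked invalid and
#' their cells set to `NA`.  Invariant under scaling of the counts.
#'
#' @param cm a raw-count [contact_matrix()].
#' @return A normalised [contact_matrix()].
#' @export
normalize_coverage_product <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$values
  N <- (sum(m) + sum(diag(m))) / 2
  if (N <= 0) stop("all-zero contact matrix")
  rs <- rowSums(m) + diag(m)
  r <- rs / (2 * N)
  expected <- 2 * N * outer(r, r)
  diag(expected) <- r^2 * N
  norm <- m / expected
  norm[expected <= 0] <- NA_real_
  valid <- rs > 0
  norm[!valid, ] <- NA_real_
  norm[, !valid] <- NA_real_
  ca_log("normalize_coverage_product: %s N=%g, %d/%d bins valid",
         cm$chrom, N, sum(valid), length(valid))
  contact_matrix(cm$chrom, cm$resolution, norm, valid)
}
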