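#' Fixed-width binned signal track
#'
#' Per-chromosome score vectors at a fixed bin width; `NA` marks bins with
#' no underlying probes.  Vector lengths equal
#' `ceiling(chrom length / bin_width)`.
#'
#' @param genome a [genome()] object.
#' @param bin_width bin width in bp.
#' @param scores named list (by chromosome) of numeric score vectors.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(genome, bin_width, scores) {
  stopifnot(inherits(genome, "genome"), bin_width > 0, is.list(scores))
  len <- chrom_lengths(genome)
  for (cn in names(scores)) {
    if (!cn %in% names(len)) stop("unknown chromosome in track: ", cn)
    expect <- ceiling(len[[cn]] / bin_width)
    if (length(scores[[cn]]) != expect) {
      stop(sprintf("track on %s has %d bins, expected %d", cn,
                   length(scores[[cn]]), expect))
    }
    if (any(!is.finite(scores[[cn]]) & !is.na(scores[[cn]]))) {
      stop("non-finite score on ", cn)
    }
  }
  structure(list(genome = genome, bin_width = bin_width, scores = scores),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), bin width %g bp\n",
              length(x$scores), x$bin_width))
  for (cn in names(x$scores)) {
    sc <- x$scores[[cn]]
    cat(sprintf("  %s: %d bins (%d missing)\n", cn, length(sc), sum(is.na(sc))))
  }
  invisible(x)
}

#' Labelled domain map
#'
#' Ordered, non-overlapping intervals labelled `"D"`, `"E"` or `"gap"`
#' (unassigned).  Coordinates are 0-based half-open.
#'
#' @param chrom,start,end,label parallel vectors describing the intervals.
#' @return An object of class `domain_map` (a data frame).
#' @export
domain_map <- function(chrom, start, end, label) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$end <= df$start)) stop("domain with end <= start")
    if (!all(df$label %in% c("D", "E", "gap"))) {
      stop("domain labels must be D, E or gap")
    }
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    for (cn in unique(df$chrom)) {
      sub <- df[df$chrom == cn, , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
        stop("overlapping domains on ", cn)
      }
    }
  }
  class(df) <- c("domain_map", "data.frame")
  df
}

#' Point feature set
#'
#' Point features (TSSs, binding summits) with optional strand and class
#' label.  A feature belongs to at most one class.
#'
#' @param chrom,pos parallel chromosome / position (bp) vectors.
#' @param strand optional strand vector (carried, never used by windows).
#' @param class optional class label vector.
#' @param name optional per-feature identifier (e.g. gene id).
#' @return An object of class `feature_set` (a data frame).
#' @export
feature_set <- function(chrom, pos, strand = NA_character_,
                        class = NA_character_, name = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   strand = as.character(strand), class = as.character(class),
                   name = as.character(name), stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$pos < 0)) stop("negative feature position")
  class(df) <- c("feature_set", "data.frame")
  df
}

#' Symmetric binned contact matrix
#'
#' One chromosome's intra-chromosomal interaction values (raw counts or
#' normalised frequencies) at a declared resolution, with a per-bin
#' validity mask.
#'
#' @param chrom chromosome name.
#' @param resolution bin width in bp.
#' @param values symmetric numeric matrix (NA allowed for masked cells).
#' @param valid logical per-bin validity mask (default all valid).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, resolution, values, valid = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values), resolution > 0)
  finite <- !is.na(values)
  if (any(values[finite] < 0)) stop("negative contact value")
  asym <- abs(values - t(values))
  if (any(asym[!is.na(asym)] > 1e-9)) stop("contact matrix is not symmetric")
  if (is.null(valid)) valid <- rep(TRUE, nrow(values))
  stopifnot(length(valid) == nrow(values))
  structure(list(chrom = chrom, resolution = resolution, values = values,
                 valid = valid),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins at %g bp (%d invalid)\n",
              x$chrom, nrow(x$values), x$resolution, sum(!x$valid)))
  invisible(x)
}

#' Sorted set of domain/TAD border positions
#'
#' @param chrom,pos parallel chromosome / border position (bp) vectors;
#'   duplicates within a chromosome are removed.
#' @param source optional label describing the border origin.
#' @return An object of class `border_set` (a data frame).
#' @export
border_set <- function(chrom, pos, source = NA_character_) {
  df <- unique(data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                          stringsAsFactors = FALSE))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source") <- source
  class(df) <- c("border_set", "data.frame")
  df
}
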