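# internal: label of the domain containing each feature position
# (half-open: a feature exactly at a domain start belongs to that domain;
# positions outside every region are "gap")
locate_in_map <- function(chrom, pos, map) {
  lab <- rep("gap", length(pos))
  for (cn in unique(chrom)) {
    sub <- map[map$chrom == cn, , drop = FALSE]
    fi <- which(chrom == cn)
    if (nrow(sub) == 0L) next
    k <- findInterval(pos[fi], sub$start)
    inside <- k >= 1 & pos[fi] < sub$end[pmax(k, 1)]
    lab[fi[inside]] <- sub$label[k[inside]]
  }
  lab
}

#' Assign point features to D/E domains
#'
#' Each feature is assigned to the unique domain containing its position
#' (0-based half-open, so a feature exactly at a domain start belongs to
#' that domain).  Features falling in unassigned gaps are reported
#' separately and excluded from the D/E fraction denominator, so
#' `frac_D + frac_E = 1` per class.
#'
#' @param features a [feature_set()].
#' @param map a [domain_map()] covering the feature chromosomes.
#' @param genome optional [genome()]; when given, features beyond a
#'   chromosome end raise an error naming the feature.
#' @return A list with `assignments` (per-feature data frame with a
#'   `domain` column) and `table` (per-class counts `n_D`, `n_E`,
#'   `n_gap` and fractions `frac_D`, `frac_E`).
#' @export
assign_points <- function(features, map, genome = NULL) {
  stopifnot(inherits(features, "feature_set"), inherits(map, "domain_map"))
  if (!is.null(genome)) check_positions(features$chrom, features$pos, genome)
  missing_chrom <- setdiff(unique(features$chrom), unique(map$chrom))
  if (length(missing_chrom) > 0) {
    stop("map does not cover chromosome: ", paste(missing_chrom, collapse = ", "))
  }
  lab <- locate_in_map(features$chrom, features$pos, map)
  assignments <- as.data.frame(features)
  assignments$domain <- lab
  cls <- ifelse(is.na(features$class), "(unlabelled)", features$class)
  tab <- lapply(unique(cls), function(cl) {
    l <- lab[cls == cl]
    n_d <- sum(l == "D"); n_e <- sum(l == "E")
    data.frame(class = cl, n_D = n_d, n_E = n_e, n_gap = sum(l == "gap"),
               frac_D = if (n_d + n_e > 0) n_d / (n_d + n_e) else NA_real_,
               frac_E = if (n_d + n_e > 0) n_e / (n_d + n_e) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(assignments = assignments,
       table = do.call(rbind, c(tab, list(make.row.names = FALSE))))
}

#' Base-pair composition of domains by annotation state
#'
#' For each domain label (D, E), the base-pair overlap with each
#' annotation label (e.g. the five chromatin-state colours), normalised
#' to the total overlapped bp per domain label.
#'
#' @param map a [domain_map()].
#' @param annotation data frame of non-overlapping labelled intervals
#'   (`chrom`, `start`, `end`, `label`).
#' @return Data frame with `domain_label`, `annotation_label`, `bp`,
#'   `fraction` (fractions sum to 1 per domain label).
#' @export
state_composition <- function(map, annotation) {
  stopifnot(inherits(map, "domain_map"))
  acc <- list()
  add <- function(dl, al, bp) {
    key <- paste(dl, al, sep = "\r")
    acc[[key]] <<- (if (is.null(acc[[key]])) 0 else acc[[key]]) + bp
  }
  for (cn in unique(annotation$chrom)) {
    dom <- map[map$chrom == cn & map$label != "gap", , drop = FALSE]
    ann <- annotation[annotation$chrom == cn, , drop = FALSE]
    if (nrow(dom) == 0L || nrow(ann) == 0L) next
    for (i in seq_len(nrow(ann))) {
      # domains are sorted and disjoint: overlapping range by binary search
      lo <- findInterval(ann$start[i], dom$end, left.open = TRUE) + 1L
      hi <- findInterval(ann$end[i], dom$start, left.open = TRUE)
      if (hi < lo) next
      for (j in lo:hi) {
        bp <- min(ann$end[i], dom$end[j]) - max(ann$start[i], dom$start[j])
        if (bp > 0) add(dom$label[j], ann$label[i], bp)
      }
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(domain_label = character(), annotation_label = character(),
                      bp = numeric(), fraction = numeric()))
  }
  keys <- do.call(rbind, strsplit(names(acc), "\r", fixed = TRUE))
  out <- data.frame(domain_label = keys[, 1], annotation_label = keys[, 2],
                    bp = unlist(acc, use.names = FALSE), stringsAsFactors = FALSE)
  out <- out[order(out$domain_label, out$annotation_label), , drop = FALSE]
  tot <- tapply(out$bp, out$domain_label, sum)
  out$fraction <- out$bp / as.numeric(tot[out$domain_label])
  rownames(out) <- NULL
  out
}

#' D/E fractions by expression breadth
#'
#' A gene's expression breadth is the number of conditions (cell lines)
#' in which its score is strictly above the threshold (score 300 over 25
#' cell lines in the original analysis).  Genes are assigned to D or E
#' via their TSS; for each breadth value 0..n the fraction of that
#' breadth class in D and in E is reported.
#'
#' @param scores data frame: column `gene` plus one numeric column per
#'   condition.
#' @param tss a [feature_set()] whose `name` column holds gene ids.
#' @param map a [domain_map()].
#' @param threshold expression threshold (strict inequality).
#' @param n_conditions expected number of condition columns.
#' @return Data frame with `breadth`, `n_D`, `n_E`, `frac_D`, `frac_E`;
#'   attribute `n_missing` counts genes absent from the TSS set.
#' @export
expression_breadth_fractions <- function(scores, tss, map, threshold = 300,
                                         n_conditions = 25) {
  stopifnot(inherits(tss, "feature_set"), inherits(map, "domain_map"))
  cond_cols <- setdiff(names(scores), "gene")
  if (length(cond_cols) != n_conditions) {
    stop(sprintf("expected %d condition columns, found %d", n_conditions,
                 length(cond_cols)))
  }
  breadth <- rowSums(as.matrix(scores[, cond_cols]) > threshold)
  idx <- match(scores$gene, tss$name)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    ca_log("expression_breadth_fractions: %d genes missing from TSS set",
           n_missing)
  }
  keep <- !is.na(idx)
  lab <- locate_in_map(tss$chrom[idx[keep]], tss$pos[idx[keep]], map)
  br <- breadth[keep]
  out <- lapply(0:n_conditions, function(b) {
    l <- lab[br == b]
    n_d <- sum(l == "D"); n_e <- sum(l == "E")
    data.frame(breadth = b, n_D = n_d, n_E = n_e,
               frac_D = if (n_d + n_e > 0) n_d / (n_d + n_e) else NA_real_,
               frac_E = if (n_d + n_e > 0) n_e / (n_d + n_e) else NA_real_)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "n_missing") <- n_missing
  res
}
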