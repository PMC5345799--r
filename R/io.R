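#' Read a bedGraph track
#'
#' Four tab-delimited columns (chrom, start, end, score), 0-based half-open.
#' Records are returned sorted by chromosome then start; overlapping records
#' on a chromosome are rejected, as are records outside the genome.
#'
#' @param path path to a bedGraph file.
#' @param genome a [genome()] object used to validate coordinates.
#' @return A data frame of class `probe_track` with columns `chrom`,
#'   `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path, genome) {
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(empty_probe_track())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1]
    stop(sprintf("malformed bedGraph line %d: expected 4 tab-delimited fields, got %d",
                 line_no[i], nf[i]))
  }
  mat <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  score <- suppressWarnings(as.numeric(mat[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(score))
  if (length(bad) > 0) {
    stop(sprintf("malformed bedGraph line %d: non-numeric field", line_no[bad[1]]))
  }
  bad <- which(end <= start)
  if (length(bad) > 0) {
    stop(sprintf("malformed bedGraph line %d: end <= start", line_no[bad[1]]))
  }
  df <- data.frame(chrom = mat[, 1], start = start, end = end, score = score,
                   stringsAsFactors = FALSE)
  len <- chrom_lengths(genome)
  unknown <- setdiff(unique(df$chrom), names(len))
  if (length(unknown) > 0) {
    stop("unknown chromosome in bedGraph: ", paste(unknown, collapse = ", "))
  }
  if (any(df$end > len[df$chrom])) {
    i <- which(df$end > len[df$chrom])[1]
    stop(sprintf("bedGraph record %s:%g-%g extends beyond the chromosome",
                 df$chrom[i], df$start[i], df$end[i]))
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (cn in unique(df$chrom)) {
    sub <- df[df$chrom == cn, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping bedGraph records on ", cn)
    }
  }
  ca_log("read_bedgraph: %d records on %d chromosomes from %s",
         nrow(df), length(unique(df$chrom)), path)
  class(df) <- c("probe_track", "data.frame")
  df
}

empty_probe_track <- function() {
  structure(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               score = numeric(), stringsAsFactors = FALSE),
    class = c("probe_track", "data.frame")
  )
}

#' Write a track to bedGraph
#'
#' Accepts either a probe-level track data frame or a [binned_track()];
#' missing bins of a binned track are omitted from the output.
#'
#' @param track a `probe_track` data frame or a `binned_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (inherits(track, "binned_track")) track <- track_to_records(track)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(track)))
  out <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                 as.integer(track$end), formatC(track$score, format = "g", digits = 10))
  writeLines(out, path)
  invisible(path)
}

# internal: binned track -> bedGraph-style records (non-missing bins only)
track_to_records <- function(track) {
  len <- chrom_lengths(track$genome)
  recs <- lapply(names(track$scores), function(cn) {
    sc <- track$scores[[cn]]
    i <- which(!is.na(sc))
    if (length(i) == 0L) return(NULL)
    data.frame(chrom = cn,
               start = (i - 1) * track$bin_width,
               end = pmin(i * track$bin_width, len[[cn]]),
               score = sc[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}

#' Read Hi-C valid pairs
#'
#' Tab-delimited chrom1, pos1, chrom2, pos2.  Pairs with either end on a
#' chromosome absent from the genome are skipped (and counted), not fatal.
#' Inter-chromosomal pairs are retained with `trans = TRUE`; the matrix
#' builder excludes them.
#'
#' @param path path to the pairs file.
#' @param genome a [genome()] object.
#' @return Data frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `trans`; attribute `n_skipped` holds the unknown-chromosome count.
#' @export
read_pairs <- function(path, genome) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom1", "pos1", "chrom2", "pos2"),
                           colClasses = c("character", "numeric", "character", "numeric"))
  len <- chrom_lengths(genome)
  known <- tab$chrom1 %in% names(len) & tab$chrom2 %in% names(len)
  n_skipped <- sum(!known)
  tab <- tab[known, , drop = FALSE]
  rownames(tab) <- NULL
  tab$trans <- tab$chrom1 != tab$chrom2
  ca_log("read_pairs: %d pairs parsed, %d skipped (unknown chromosome), %d trans",
         nrow(tab), n_skipped, sum(tab$trans))
  attr(tab, "n_skipped") <- n_skipped
  tab
}

#' Write a domain map as BED
#'
#' One line per domain, label in the BED name column, deterministic
#' (chromosome, start) ordering.  An empty map yields an empty file.
#'
#' @param map a [domain_map()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_map <- function(map, path) {
  stopifnot(inherits(map, "domain_map"))
  map <- map[order(map$chrom, map$start), , drop = FALSE]
  out <- sprintf("%s\t%d\t%d\t%s", map$chrom, as.integer(map$start),
                 as.integer(map$end), map$label)
  writeLines(out, path)
  invisible(path)
}

#' Read a domain map from BED
#'
#' @param path BED path (chrom, start, end, name = label).
#' @param genome optional [genome()] for coordinate validation.
#' @return A [domain_map()] object.
#' @export
read_domain_map <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (length(lines) == 0L) {
    return(domain_map(character(), numeric(), numeric(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) stop("domain map BED requires 4 columns")
  mat <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
  map <- domain_map(mat[, 1], as.numeric(mat[, 2]), as.numeric(mat[, 3]), mat[, 4])
  if (!is.null(genome)) {
    check_positions(map$chrom, map$start, genome, "domain")
  }
  map
}

#' Read point features from BED
#'
#' The feature position is the interval start (summit convention for
#' 1-bp records).  Column 4, if present, is the class label; column 6 the
#' strand.  Strand is carried but ignored by all window operations.
#'
#' @param path BED path.
#' @param genome optional [genome()] for validation.
#' @return A [feature_set()] object.
#' @export
read_features <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (length(lines) == 0L) return(feature_set(character(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, "", 1)
  pos <- as.numeric(vapply(fields, `[`, "", 2))
  cls <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else NA_character_, "")
  fs <- feature_set(chrom, pos, class = cls, strand = strand)
  if (!is.null(genome)) check_positions(fs$chrom, fs$pos, genome)
  fs
}

#' Write point features as BED
#' @param features a [feature_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  cls <- ifelse(is.na(features$class), ".", features$class)
  out <- sprintf("%s\t%d\t%d\t%s", features$chrom, as.integer(features$pos),
                 as.integer(features$pos) + 1L, cls)
  writeLines(out, path)
  invisible(path)
}

#' Write a contact matrix in sparse triplet format
#'
#' Header line `# chrom=<name> resolution=<bp> n=<bins>` followed by
#' `bin_i  bin_j  value` (1-based, upper triangle including the diagonal,
#' non-zero entries only).
#'
#' @param cm a [contact_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$values
  idx <- which(upper.tri(m, diag = TRUE) & m != 0 & !is.na(m), arr.ind = TRUE)
  header <- sprintf("# chrom=%s resolution=%d n=%d", cm$chrom,
                    as.integer(cm$resolution), nrow(m))
  body <- sprintf("%d\t%d\t%s", idx[, 1], idx[, 2],
                  formatC(m[idx], format = "g", digits = 10))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a contact matrix written by [write_contact_matrix()]
#' @param path triplet-format path.
#' @return A [contact_matrix()] with symmetric values.
#' @export
read_contact_matrix <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("chrom=(\\S+) resolution=(\\d+) n=(\\d+)", header))[[1]]
  if (length(m) != 4) stop("missing or malformed contact-matrix header")
  chrom <- m[2]; res <- as.numeric(m[3]); n <- as.integer(m[4])
  vals <- matrix(0, n, n)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", skip = 1, header = FALSE,
                      colClasses = c("integer", "integer", "numeric")),
    error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0) {
    vals[cbind(tab[[1]], tab[[2]])] <- tab[[3]]
    vals[cbind(tab[[2]], tab[[1]])] <- tab[[3]]
  }
  contact_matrix(chrom, res, vals)
}
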