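#' Simulation configuration
#'
#' Bundles the ground-truth parameters for the synthetic-data generators:
#' the two-state hidden Markov signal model for the ChIP track, the
#' contact-matrix model (power-law distance decay with elevated E blocks,
#' planted D-D corner hotspots and multiplicative bin-coverage bias), and
#' the per-class feature placement model.
#'
#' Defaults describe the study conditions the package is validated under:
#' 1-kb signal bins with emission means -0.3 / +0.6 (log2-ratio units),
#' SDs 0.25 / 0.35 and stay probabilities 0.98 (domain medians in the
#' tens-of-kb range); 10-kb Hi-C bins with 1000 expected counts per bin
#' pair at zero distance, decay exponent 1, 3-fold E-block enrichment,
#' 2-fold hotspot enrichment planted at rate 0.35; housekeeping-like
#' features placed in D domains with probability 0.95 and regulated-like
#' features with probability 0.25.
#'
#' @param genome a [genome()] object.
#' @param bin_width ChIP signal bin width (bp).
#' @param emission_means,emission_sds numeric length-2; state 1 is the
#'   low-mean (depleted) state.
#' @param stay_prob numeric length-2 self-transition probabilities.
#' @param initial numeric length-2 initial state distribution.
#' @param missing_rate probability per bin of starting a probe gap.
#' @param missing_mean_len mean probe-gap length in bins (geometric).
#' @param hic_resolution Hi-C bin width (bp).
#' @param background expected contact count at zero distance.
#' @param decay power-law distance-decay exponent (>= 0).
#' @param e_block_factor within-E-block enrichment factor (>= 1).
#' @param d_short_factor within-D short-range enrichment factor (>= 1);
#'   depleted domains show a preponderance of short-range contacts, which
#'   keeps per-bin visibility comparable between domain types.
#' @param d_short_range distance (bp) up to which `d_short_factor` applies.
#' @param hotspot_factor D-D corner enrichment factor (>= 1).
#' @param hotspot_prob probability an eligible E domain carries a planted
#'   hotspot.
#' @param hotspot_max_flank corner size cap, bins per flanking D side.
#' @param min_hotspot_e_length minimum E-domain length (bp) for hotspot
#'   eligibility.
#' @param coverage_bias_sd SD of log-normal per-bin coverage bias (0 = off).
#' @param balance_coverage rescale the expected matrix (symmetric
#'   Sinkhorn iterations) so each bin's expected coverage matches the
#'   pure distance-decay profile: enrichment then redistributes contacts
#'   instead of adding reads, emulating the fixed per-fragment ligation
#'   budget of a Hi-C experiment.  Default `TRUE`; set `FALSE` to make
#'   the expectation exactly multiplicative in the enrichment factors.
#' @param feature_counts named integer vector: features per class.
#' @param feature_d_prob named numeric vector: per-class probability of
#'   placement inside D domains.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome,
                       bin_width = 1000,
                       emission_means = c(-0.3, 0.6),
                       emission_sds = c(0.25, 0.35),
                       stay_prob = c(0.98, 0.98),
                       initial = c(0.5, 0.5),
                       missing_rate = 0,
                       missing_mean_len = 5,
                       hic_resolution = 10000,
                       background = 1000,
                       decay = 1,
                       e_block_factor = 3,
                       d_short_factor = 3,
                       d_short_range = 50000,
                       hotspot_factor = 2,
                       hotspot_prob = 0.35,
                       hotspot_max_flank = 10,
                       min_hotspot_e_length = 60000,
                       coverage_bias_sd = 0,
                       balance_coverage = TRUE,
                       feature_counts = c(housekeeping = 2000, regulated = 2000),
                       feature_d_prob = c(housekeeping = 0.95, regulated = 0.25)) {
  stopifnot(inherits(genome, "genome"))
  if (any(emission_sds <= 0)) stop("emission SDs must be > 0")
  if (any(stay_prob < 0 | stay_prob > 1)) stop("stay probabilities in [0,1]")
  if (abs(sum(initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  if (e_block_factor < 1 || hotspot_factor < 1 || d_short_factor < 1) {
    stop("enrichment factors must be >= 1")
  }
  if (hotspot_prob < 0 || hotspot_prob > 1) stop("hotspot_prob in [0,1]")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate in [0,1]")
  if (!identical(sort(names(feature_counts)), sort(names(feature_d_prob)))) {
    stop("feature_counts and feature_d_prob must share class names")
  }
  structure(as.list(environment()), class = "sim_config")
}

# internal: sample a 2-state Markov chain of length n (states 1/2)
sample_chain <- function(n, stay_prob, initial) {
  states <- integer(n)
  states[1] <- sample.int(2L, 1L, prob = initial)
  if (n > 1) {
    flip <- stats::runif(n - 1)
    for (t in 2:n) {
      s <- states[t - 1]
      states[t] <- if (flip[t - 1] < stay_prob[s]) s else 3L - s
    }
  }
  states
}

#' Simulate a ChIP track with known domain truth
#'
#' Per bin, a hidden state is drawn from the configured Markov chain and
#' the score from that state's normal emission.  Optional probe gaps
#' (runs of missing bins) are overlaid at the configured rate; the hidden
#' truth is unaffected by masking.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; same seed, same output.
#' @return A list with `track` (a [binned_track()]), `truth` (the true
#'   [domain_map()], alternating D/E labels) and `states` (per-chromosome
#'   integer state vectors, 1 = D, 2 = E).
#' @export
simulate_chip_track <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  len <- chrom_lengths(cfg$genome)
  scores <- list()
  states_out <- list()
  maps <- list()
  for (cn in names(len)) {
    n <- as.integer(ceiling(len[[cn]] / cfg$bin_width))
    if (n == 0L) stop("zero-length chromosome ", cn)
    states <- sample_chain(n, cfg$stay_prob, cfg$initial)
    sc <- stats::rnorm(n, cfg$emission_means[states], cfg$emission_sds[states])
    if (cfg$missing_rate > 0) {
      gap_start <- which(stats::runif(n) < cfg$missing_rate)
      if (length(gap_start) > 0) {
        gap_len <- 1L + stats::rgeom(length(gap_start),
                                     prob = 1 / cfg$missing_mean_len)
        masked <- unlist(Map(function(s, l) s:min(s + l - 1L, n),
                             gap_start, gap_len))
        sc[unique(masked)] <- NA_real_
      }
    }
    scores[[cn]] <- sc
    states_out[[cn]] <- states
    r <- rle(states)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0L, ends_bin[-length(ends_bin)])
    maps[[cn]] <- data.frame(
      chrom = cn,
      start = starts_bin * cfg$bin_width,
      end = pmin(ends_bin * cfg$bin_width, len[[cn]]),
      label = c("D", "E")[r$values],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, c(maps, list(make.row.names = FALSE)))
  list(track = binned_track(cfg$genome, cfg$bin_width, scores),
       truth = domain_map(truth$chrom, truth$start, truth$end, truth$label),
       states = states_out)
}

# internal: per-bin domain index and label for one chromosome
# (domain covering the bin midpoint; bins beyond the last domain -> NA)
bin_domain_index <- function(map_chrom, n, resolution) {
  mid <- (seq_len(n) - 0.5) * resolution
  idx <- findInterval(mid, map_chrom$start)
  idx[idx < 1] <- NA
  inside <- !is.na(idx) & mid <= map_chrom$end[pmax(idx, 1)]
  idx[!inside] <- NA
  idx
}

# internal: bins whose midpoint lies in [start, end) -- the bin-labelling
# convention shared by the simulator and the hotspot detector
midpoint_bins <- function(start, end, resolution, n) {
  lo <- max(1L, as.integer(ceiling(start / resolution + 0.5)))
  hi <- min(n, as.integer(ceiling(end / resolution + 0.5)) - 1L)
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

# internal: eligible E domains (>= min length, strictly flanked by D) with
# their corner bin rectangles; rows refer to the per-chromosome map subset
eligible_e_corners <- function(map_chrom, n, resolution, min_e_length,
                               max_flank) {
  dom_bins <- function(i) {
    midpoint_bins(map_chrom$start[i], map_chrom$end[i], resolution, n)
  }
  out <- list()
  for (i in seq_len(nrow(map_chrom))) {
    if (map_chrom$label[i] != "E") next
    if (map_chrom$end[i] - map_chrom$start[i] < min_e_length) next
    if (i == 1L || i == nrow(map_chrom)) next
    if (map_chrom$label[i - 1] != "D" || map_chrom$label[i + 1] != "D") next
    left <- dom_bins(i - 1L)
    right <- dom_bins(i + 1L)
    if (length(left) == 0L || length(right) == 0L) next
    left <- utils::tail(left, max_flank)
    right <- utils::head(right, max_flank)
    out[[length(out) + 1L]] <- list(row = i, left = left, right = right)
  }
  out
}

#' Simulate a symmetric Hi-C contact matrix for one chromosome
#'
#' Expected count at bin pair (i, j) is
#' `background * (1 + |i - j|)^(-decay)`, multiplied by the E-block factor
#' when both bins lie in the same E domain, by the hotspot factor when
#' (i, j) couples the two D domains flanking an E domain selected for a
#' planted hotspot, and by the per-bin coverage biases `b_i * b_j`.
#' Counts are Poisson draws around the expectation, symmetrised.
#'
#' @param cfg a [sim_config()].
#' @param domains a [domain_map()] covering the chromosome.
#' @param chrom chromosome to simulate (default: first in the map).
#' @param seed integer seed.
#' @return A [contact_matrix()] of raw counts.  Attribute `planted` is a
#'   data frame of eligible E domains with their planted-hotspot flag;
#'   attribute `bias` holds the per-bin coverage biases.
#' @export
simulate_contact_matrix <- function(cfg, domains, chrom = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(domains, "domain_map"))
  set.seed(seed)
  if (is.null(chrom)) chrom <- domains$chrom[1]
  map_chrom <- domains[domains$chrom == chrom, , drop = FALSE]
  if (nrow(map_chrom) == 0L) stop("no domains on ", chrom)
  len <- chrom_lengths(cfg$genome)
  if (!chrom %in% names(len)) stop("unknown chromosome: ", chrom)
  res <- cfg$hic_resolution
  n <- as.integer(ceiling(len[[chrom]] / res))
  if (max(map_chrom$end) < len[[chrom]] - res || min(map_chrom$start) > 0) {
    stop("domain map does not cover chromosome ", chrom,
         " at resolution ", res)
  }
  dom_idx <- bin_domain_index(map_chrom, n, res)
  is_e <- !is.na(dom_idx) & map_chrom$label[pmax(dom_idx, 1)] == "E"

  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expected <- cfg$background * (1 + d)^(-cfg$decay)

  same_e <- outer(ifelse(is_e, dom_idx, NA), ifelse(is_e, dom_idx, NA), "==")
  same_e[is.na(same_e)] <- FALSE
  expected[same_e] <- expected[same_e] * cfg$e_block_factor

  is_d <- !is.na(dom_idx) & map_chrom$label[pmax(dom_idx, 1)] == "D"
  same_d <- outer(ifelse(is_d, dom_idx, NA), ifelse(is_d, dom_idx, NA), "==")
  same_d[is.na(same_d)] <- FALSE
  same_d <- same_d & d * res <= cfg$d_short_range
  expected[same_d] <- expected[same_d] * cfg$d_short_factor

  corners <- eligible_e_corners(map_chrom, n, res, cfg$min_hotspot_e_length,
                                cfg$hotspot_max_flank)
  planted <- logical(length(corners))
  if (length(corners) > 0) {
    planted <- stats::runif(length(corners)) < cfg$hotspot_prob
    for (k in which(planted)) {
      rect <- corners[[k]]
      expected[rect$left, rect$right] <- expected[rect$left, rect$right] *
        cfg$hotspot_factor
      expected[rect$right, rect$left] <- expected[rect$right, rect$left] *
        cfg$hotspot_factor
    }
  }

  if (cfg$balance_coverage) {
    target <- rowSums(cfg$background * (1 + d)^(-cfg$decay))
    cvec <- rep(1, n)
    for (it in seq_len(25)) {
      rs <- as.vector(expected %*% cvec) * cvec
      cvec <- cvec * sqrt(target / pmax(rs, .Machine$double.eps))
    }
    expected <- expected * outer(cvec, cvec)
  }

  if (cfg$coverage_bias_sd > 0) {
    b <- exp(stats::rnorm(n, 0, cfg$coverage_bias_sd))
  } else {
    b <- rep(1, n)
  }
  expected <- expected * outer(b, b)

  counts <- matrix(0, n, n)
  ut <- upper.tri(counts, diag = TRUE)
  counts[ut] <- stats::rpois(sum(ut), expected[ut])
  counts <- counts + t(counts) - diag(diag(counts))

  cm <- contact_matrix(chrom, res, counts)
  rows <- vapply(corners, `[[`, 0L, "row")
  attr(cm, "planted") <- data.frame(
    chrom = rep(chrom, length(rows)),
    start = map_chrom$start[rows],
    end = map_chrom$end[rows],
    planted = planted, stringsAsFactors = FALSE)
  attr(cm, "bias") <- b
  cm
}

# internal: sample k positions uniformly over a set of intervals
sample_in_intervals <- function(k, starts, ends) {
  widths <- ends - starts
  if (k == 0L) return(numeric(0))
  i <- sample.int(length(starts), k, replace = TRUE, prob = widths)
  floor(starts[i] + stats::runif(k) * widths[i])
}

#' Simulate point features with class-specific domain preference
#'
#' For each class, each feature lands uniformly within D domains with the
#' class's D-placement probability, otherwise uniformly within E domains.
#'
#' @param cfg a [sim_config()].
#' @param domains a [domain_map()].
#' @param seed integer seed.
#' @return A [feature_set()] with class labels; attribute `in_d` records
#'   the true placement indicator.
#' @export
simulate_features <- function(cfg, domains, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), inherits(domains, "domain_map"))
  set.seed(seed)
  d <- domains[domains$label == "D", , drop = FALSE]
  e <- domains[domains$label == "E", , drop = FALSE]
  out <- list()
  for (cls in names(cfg$feature_counts)) {
    k <- cfg$feature_counts[[cls]]
    p <- cfg$feature_d_prob[[cls]]
    in_d <- stats::runif(k) < p
    if (any(in_d) && nrow(d) == 0L) {
      stop("no D domains available for class ", cls,
           " with D-placement probability ", p)
    }
    if (any(!in_d) && nrow(e) == 0L) {
      stop("no E domains available for class ", cls)
    }
    pos <- numeric(k)
    chrom <- character(k)
    if (any(in_d)) {
      i <- sample.int(nrow(d), sum(in_d), replace = TRUE, prob = d$end - d$start)
      pos[in_d] <- floor(d$start[i] + stats::runif(sum(in_d)) * (d$end[i] - d$start[i]))
      chrom[in_d] <- d$chrom[i]
    }
    if (any(!in_d)) {
      i <- sample.int(nrow(e), sum(!in_d), replace = TRUE, prob = e$end - e$start)
      pos[!in_d] <- floor(e$start[i] + stats::runif(sum(!in_d)) * (e$end[i] - e$start[i]))
      chrom[!in_d] <- e$chrom[i]
    }
    out[[cls]] <- data.frame(chrom = chrom, pos = pos, class = cls,
                             in_d = in_d, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  fs <- feature_set(all$chrom, all$pos, class = all$class)
  attr(fs, "in_d") <- all$in_d
  fs
}

#' Simulate a band-like interval set around E domains
#'
#' One band per selected E domain; band borders equal the E-domain
#' borders plus independent normal jitter of SD `jitter_sd`.
#'
#' @param cfg a [sim_config()] (supplies the genome for clamping).
#' @param domains a [domain_map()].
#' @param jitter_sd border jitter SD in bp (>= 0).
#' @param min_e_length only E domains at least this long get a band.
#' @param seed integer seed.
#' @return Data frame of band intervals (`chrom`, `start`, `end`).
#' @export
simulate_band_set <- function(cfg, domains, jitter_sd = 5000,
                              min_e_length = 0, seed = 1L) {
  stopifnot(inherits(domains, "domain_map"), jitter_sd >= 0)
  set.seed(seed)
  len <- chrom_lengths(cfg$genome)
  e <- domains[domains$label == "E" &
                 (domains$end - domains$start) >= min_e_length, , drop = FALSE]
  if (nrow(e) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  start <- e$start + stats::rnorm(nrow(e), 0, jitter_sd)
  end <- e$end + stats::rnorm(nrow(e), 0, jitter_sd)
  start <- pmax(0, pmin(start, len[e$chrom]))
  end <- pmax(0, pmin(end, len[e$chrom]))
  ok <- end > start
  if (any(!ok)) ca_log("simulate_band_set: dropped %d degenerate bands", sum(!ok))
  data.frame(chrom = e$chrom[ok], start = start[ok], end = end[ok],
             stringsAsFactors = FALSE)
}
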