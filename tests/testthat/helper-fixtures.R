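# shared fixtures: small genomes, designed domain maps, random tracks

toy_genome <- function(len = 1e6, chrom = "chr2L") genome(chrom, len)

# alternating D/E map with fixed block sizes (bp), tiling [0, len)
alternating_map <- function(len, d_size, e_size, chrom = "chrT") {
  starts <- c(); ends <- c(); labels <- c()
  pos <- 0
  lab <- "D"
  while (pos < len) {
    w <- if (lab == "D") d_size else e_size
    starts <- c(starts, pos)
    ends <- c(ends, min(pos + w, len))
    labels <- c(labels, lab)
    pos <- pos + w
    lab <- if (lab == "D") "E" else "D"
  }
  domain_map(rep(chrom, length(starts)), starts, ends, labels)
}

# random sorted non-overlapping probe track on one chromosome
random_probe_track <- function(n, len = 1e6, chrom = "chr2L",
                               probe_len = 50) {
  gap <- floor(len / n)
  start <- (seq_len(n) - 1) * gap + sample.int(gap - probe_len, n, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = start + probe_len,
                   score = rnorm(n), stringsAsFactors = FALSE)
  class(df) <- c("probe_track", "data.frame")
  df
}

# symmetric non-negative random matrix
random_symmetric_matrix <- function(n, lambda = 20) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), lambda)
  m + t(m) - diag(diag(m))
}

# default-condition Hi-C simulation on one chromosome: domain truth drawn
# at 10-kb granularity with the package's 50-kb mean domain scale
simulate_hic_case <- function(seed, len = 1e7, chrom = "chrH") {
  gen <- genome(chrom, len)
  cfg <- sim_config(gen, bin_width = 10000, stay_prob = c(0.8, 0.8))
  sim <- simulate_chip_track(cfg, seed = seed)
  cmx <- simulate_contact_matrix(cfg, sim$truth, seed = seed)
  list(cfg = cfg, truth = sim$truth, counts = cmx,
       normalized = normalize_coverage_product(cmx))
}
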