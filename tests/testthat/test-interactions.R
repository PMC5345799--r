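test_that("distance fractions classify short and long range correctly", {
  # 30 bins at 5 kb; anchor 10 has all mass at 10 kb (short range)
  n <- 30
  m <- matrix(0, n, n)
  m[10, 12] <- 8; m[12, 10] <- 8
  cm <- contact_matrix("c", 5000, m)
  prof <- distance_fraction_profile(cm, end_exclusion = 0,
                                    high_percentile = 100)
  expect_equal(prof$short[10], 1)
  expect_equal(prof$long[10], 0)

  # equal mass at 10 kb and 100 kb: short 0.5, long 0.5, ratio 1
  m2 <- matrix(0, n, n)
  m2[5, 7] <- 4; m2[7, 5] <- 4     # 10 kb
  m2[5, 25] <- 4; m2[25, 5] <- 4   # 100 kb
  cm2 <- contact_matrix("c", 5000, m2)
  prof2 <- distance_fraction_profile(cm2, end_exclusion = 0,
                                     high_percentile = 100)
  expect_equal(prof2$short[5], 0.5)
  expect_equal(prof2$long[5], 0.5)
  expect_equal(prof2$ratio[5], 1)
})

test_that("distance fractions match brute force under every exclusion rule", {
  withr::local_seed(91)
  n <- 50
  m <- random_symmetric_matrix(n, lambda = 3)
  cm <- contact_matrix("c", 5000, m)
  max_d <- 100000; end_ex <- 25000; pct <- 90
  prof <- distance_fraction_profile(cm, max_distance = max_d,
                                    end_exclusion = end_ex,
                                    high_percentile = pct)
  totals <- sapply(seq_len(n), function(i) {
    j <- setdiff(which(abs(seq_len(n) - i) * 5000 <= max_d), i)
    sum(m[i, j])
  })
  interior <- (seq_len(n) - 1) * 5000 >= end_ex &
    (n * 5000 - seq_len(n) * 5000) >= end_ex
  kept <- interior & totals > 0
  cutoff <- quantile(totals[kept], pct / 100, names = FALSE)
  kept <- kept & totals <= cutoff
  expect_equal(prof$retained, kept)
  for (i in which(kept)) {
    j <- setdiff(seq_len(n), i)
    d <- abs(j - i) * 5000
    keep <- d <= max_d
    v <- m[i, j[keep]]; d <- d[keep]
    expect_equal(prof$short[i], sum(v[d >= 5000 & d <= 50000]) / sum(v))
    expect_equal(prof$long[i], sum(v[d > 50000 & d <= 500000]) / sum(v))
    # mass conservation: short + long + residual = 1
    resid <- sum(v[d < 5000 | d > 500000]) / sum(v)
    expect_equal(prof$short[i] + prof$long[i] + resid, 1)
  }
})

test_that("domain distance profiles collect within-domain pairs by distance", {
  map <- domain_map(c("c", "c"), c(0, 100000), c(100000, 200000),
                    c("D", "E"))
  withr::local_seed(92)
  m <- random_symmetric_matrix(20, lambda = 10)
  cm <- contact_matrix("c", 10000, m)
  res <- domain_distance_profile(cm, map, min_length = 30000)
  # brute force: D occupies bins 1..10, E bins 11..20
  for (d in res$table$distance / 10000) {
    i <- 1:(10 - d)
    want_d <- median(m[cbind(i, i + d)])
    i2 <- 11:(20 - d)
    want_e <- median(m[cbind(i2, i2 + d)])
    row <- res$table[res$table$distance == d * 10000, ]
    expect_equal(row$median_D, want_d)
    expect_equal(row$median_E, want_e)
  }
  # identical interaction structure in both labels: rank-sum p near 1
  sym <- m
  sym[11:20, 11:20] <- m[1:10, 1:10]
  res2 <- domain_distance_profile(contact_matrix("c", 10000, sym), map)
  expect_gt(res2$p_value, 0.9)

  expect_error(domain_distance_profile(cm,
    domain_map("c", 0, 200000, "E"), min_length = 30000), "D")
})

test_that("D domains run short-range hot and E domains mid-range hot by design", {
  case <- simulate_hic_case(93)
  res <- domain_distance_profile(case$normalized, case$truth)
  mid <- res$table$distance > 50000 & res$table$distance <= 200000
  expect_true(mean(res$table$median_D[mid] < res$table$median_E[mid]) > 0.9)
  expect_lt(res$p_value, 0.05)
})

test_that("planted corner hotspots are detected and homogeneous nulls are not", {
  gen <- genome("chrT", 6e6)
  map <- alternating_map(6e6, 5e4, 8e4, chrom = "chrT")
  cfg_all <- sim_config(gen, hotspot_prob = 1, hotspot_factor = 2)
  cm_all <- simulate_contact_matrix(cfg_all, map, seed = 94)
  hs_all <- detect_dd_hotspots(normalize_coverage_product(cm_all), map)
  expect_gt(nrow(hs_all), 20)
  expect_gt(mean(hs_all$hotspot), 0.95)
  expect_gt(min(hs_all$ratio), 1.3)

  cfg_none <- sim_config(gen, hotspot_prob = 0)
  cm_none <- simulate_contact_matrix(cfg_none, map, seed = 94)
  hs_none <- detect_dd_hotspots(normalize_coverage_product(cm_none), map)
  expect_lt(mean(hs_none$hotspot), 0.15)
  expect_lt(abs(median(hs_none$ratio) - 1), 0.1)

  # no eligible E domains yields an empty table, not an error
  lone <- domain_map("chrT", 0, 6e6, "E")
  hs_empty <- detect_dd_hotspots(normalize_coverage_product(cm_none), lone)
  expect_equal(nrow(hs_empty), 0L)
})

test_that("eligibility requires length and strict D adjacency", {
  gen <- genome("chrT", 2e6)
  # E of 80 kb flanked by D both sides: eligible; E next to a gap: not
  map <- domain_map(rep("chrT", 7),
                    c(0, 3e5, 3.8e5, 6.8e5, 7.4e5, 8.2e5, 1.2e6),
                    c(3e5, 3.8e5, 6.8e5, 7.4e5, 8.2e5, 1.2e6, 2e6),
                    c("D", "E", "D", "gap", "E", "D", "D"))
  cfg <- sim_config(gen, hotspot_prob = 0)
  cm <- simulate_contact_matrix(cfg, map, seed = 95)
  hs <- detect_dd_hotspots(normalize_coverage_product(cm), map,
                           min_e_length = 60000)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$start, 3e5)
})
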