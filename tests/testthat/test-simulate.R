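test_that("chip simulator emits from the configured state model", {
  gen <- genome("chrS", 1e7)
  cfg <- sim_config(gen, bin_width = 1000, emission_means = c(0, 1.5),
                    emission_sds = c(0.1, 0.1), stay_prob = c(0.99, 0.99))
  sim <- simulate_chip_track(cfg, seed = 1)
  st <- sim$states$chrS
  sc <- sim$track$scores$chrS
  expect_lt(abs(mean(sc[st == 1]) - 0), 0.02)
  expect_lt(abs(mean(sc[st == 2]) - 1.5), 0.02)

  # absorbing chain: identity transitions keep the initial state
  cfg2 <- sim_config(genome("c", 5e4), stay_prob = c(1, 1), initial = c(1, 0))
  sim2 <- simulate_chip_track(cfg2, seed = 2)
  expect_true(all(sim2$states$c == 1L))
  expect_equal(nrow(sim2$truth), 1L)
  expect_equal(sim2$truth$label, "D")

  # determinism and truth tiling with alternating labels
  sim3a <- simulate_chip_track(cfg, seed = 7)
  sim3b <- simulate_chip_track(cfg, seed = 7)
  expect_identical(sim3a$track$scores, sim3b$track$scores)
  tr <- sim3a$truth
  expect_equal(tr$start[-1], tr$end[-nrow(tr)])
  expect_true(all(tr$label[-1] != tr$label[-nrow(tr)]))
  expect_equal(max(tr$end), 1e7)
})

test_that("probe gaps are masked at the configured rate without touching truth", {
  gen <- genome("chrS", 5e6)
  cfg <- sim_config(gen, missing_rate = 0.02, missing_mean_len = 5)
  sim <- simulate_chip_track(cfg, seed = 3)
  frac_na <- mean(is.na(sim$track$scores$chrS))
  expect_gt(frac_na, 0.03)
  expect_lt(frac_na, 0.25)
  expect_equal(max(sim$truth$end), 5e6)
})

test_that("contact expectation depends only on distance when factors are off", {
  gen <- genome("chrT", 3e5)
  map <- alternating_map(3e5, 5e4, 5e4)
  cfg <- sim_config(gen, hic_resolution = 10000, background = 5e4,
                    e_block_factor = 1, d_short_factor = 1,
                    hotspot_prob = 0, coverage_bias_sd = 0)
  cm <- simulate_contact_matrix(cfg, map, seed = 4)
  m <- cm$values
  expect_equal(m, t(m))
  expect_true(all(m >= 0))
  for (d in c(2, 5)) {
    v <- m[cbind(seq_len(nrow(m) - d), seq_len(nrow(m) - d) + d)]
    expect_lt(sd(v) / mean(v), 0.05)  # counts ~ Poisson around a common mean
  }
})

test_that("E-block factor sets the within-block to background ratio", {
  withr::local_seed(5)
  gen <- genome("chrT", 2e6)
  map <- alternating_map(2e6, 5e4, 8e4)   # E blocks of 8 bins at 10 kb
  cfg <- sim_config(gen, hic_resolution = 10000, background = 2e4,
                    e_block_factor = 3, d_short_factor = 1, hotspot_prob = 0,
                    balance_coverage = FALSE)
  cm <- simulate_contact_matrix(cfg, map, seed = 5)
  m <- cm$values
  n <- nrow(m)
  mid <- (seq_len(n) - 0.5) * 1e4
  idx <- findInterval(mid, map$start)
  lab <- map$label[idx]
  d <- 3
  i <- seq_len(n - d)
  same_e <- lab[i] == "E" & lab[i + d] == "E" & idx[i] == idx[i + d]
  backgrounds <- lab[i] == "D" & lab[i + d] == "D" & idx[i] != idx[i + d] |
    lab[i] != lab[i + d]
  v <- m[cbind(i, i + d)]
  ratio <- mean(v[same_e]) / mean(v[backgrounds])
  expect_lt(abs(ratio - 3), 0.3)
})

test_that("hotspots are planted at the configured Bernoulli rate", {
  gen <- genome("chrT", 8e6)
  map <- alternating_map(8e6, 5e4, 8e4)   # every E (80 kb) is eligible
  cfg <- sim_config(gen, hic_resolution = 10000, background = 100,
                    hotspot_prob = 0.35)
  cm <- simulate_contact_matrix(cfg, map, seed = 6)
  pl <- attr(cm, "planted")
  n_elig <- nrow(pl)
  expect_gt(n_elig, 40)
  p_hat <- mean(pl$planted)
  expect_lt(abs(p_hat - 0.35), 3 * sqrt(0.35 * 0.65 / n_elig))
})

test_that("feature placement follows the per-class D probability", {
  gen <- genome("chrT", 2e6)
  map <- alternating_map(2e6, 5e4, 5e4)
  cfg <- sim_config(gen,
                    feature_counts = c(hk = 4000, reg = 1000),
                    feature_d_prob = c(hk = 0.95, reg = 0))
  fs <- simulate_features(cfg, map, seed = 7)
  lab <- chromarch:::locate_in_map(fs$chrom, fs$pos, map)
  hk_d <- mean(lab[fs$class == "hk"] == "D")
  expect_lt(abs(hk_d - 0.95), 3 * sqrt(0.95 * 0.05 / 4000))
  expect_true(all(lab[fs$class == "reg"] == "E"))

  expect_identical(simulate_features(cfg, map, seed = 8),
                   simulate_features(cfg, map, seed = 8))

  # all features forced into D with no D available is an error
  map_e <- domain_map("chrT", 0, 2e6, "E")
  cfg1 <- sim_config(gen, feature_counts = c(hk = 10),
                     feature_d_prob = c(hk = 1))
  expect_error(simulate_features(cfg1, map_e, seed = 1), "no D domains")

  cfg_all_d <- sim_config(gen, feature_counts = c(hk = 500),
                          feature_d_prob = c(hk = 1))
  fs_d <- simulate_features(cfg_all_d, map, seed = 9)
  expect_true(all(chromarch:::locate_in_map(fs_d$chrom, fs_d$pos, map) == "D"))
})

test_that("band borders jitter around E-domain borders as configured", {
  gen <- genome("chrT", 1e7)
  map <- alternating_map(1e7, 5e4, 8e4)
  cfg <- sim_config(gen)

  exact <- simulate_band_set(cfg, map, jitter_sd = 0, seed = 10)
  e <- map[map$label == "E", ]
  expect_equal(exact$start, e$start)
  expect_equal(exact$end, e$end)

  jit <- simulate_band_set(cfg, map, jitter_sd = 5000, seed = 10)
  borders <- domain_borders(map)
  d <- nearest_border_distances(interval_borders(jit, gen), borders)
  expect_gt(fraction_within(d, 15000), 0.98)  # 3 sigma of a 5-kb normal

  expect_identical(simulate_band_set(cfg, map, jitter_sd = 5000, seed = 11),
                   simulate_band_set(cfg, map, jitter_sd = 5000, seed = 11))
})
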