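test_that("a lone midpoint summit lands in the central tile with scaled count 1000", {
  map <- domain_map("c", 100000, 180000, "D")
  fs <- feature_set("c", 140000, class = "x")   # exact domain midpoint
  prof <- scaled_tile_profile(fs, map, n_tiles = 80, n_flank = 10,
                              labels = "D")
  hit <- prof$tile[prof$count > 0]
  expect_equal(hit, 10 + 40 + 1)                # flank offset + n_tiles/2
  expect_equal(prof$scaled[prof$tile == hit], 1000)

  # a summit outside the domain but within flank range is counted there
  fs2 <- feature_set("c", 99000, class = "x")   # 1 kb left of the domain
  prof2 <- scaled_tile_profile(fs2, map, labels = "D")
  expect_equal(sum(prof2$count), 1)
  expect_lte(prof2$tile[prof2$count > 0], 10)
})

test_that("tile counts match a brute-force tally and scale comparably", {
  withr::local_seed(81)
  map <- alternating_map(2e6, 6e4, 9e4, chrom = "c")
  pos <- sample.int(2e6, 400) - 1
  fs <- feature_set(rep("c", 400), pos, class = "x")
  prof <- scaled_tile_profile(fs, map, n_tiles = 20, n_flank = 5,
                              labels = c("D", "E"))
  for (lb in c("D", "E")) {
    want <- numeric(30)
    for (i in which(map$label == lb)) {
      tw <- (map$end[i] - map$start[i]) / 20
      for (p in pos) {
        off <- p - map$start[i]
        if (off >= -5 * tw && off < (map$end[i] - map$start[i]) + 5 * tw) {
          t <- floor(off / tw)
          if (off >= 0 && off < map$end[i] - map$start[i]) {
            t <- min(max(t, 0), 19)
          }
          want[t + 6] <- want[t + 6] + 1
        }
      }
    }
    expect_equal(prof$count[prof$label == lb], want)
  }
  # 1000/n scaling makes proportionally identical classes comparable:
  # duplicating every feature leaves the scaled profile unchanged
  fs2 <- feature_set(rep("c", 800), rep(pos, 2), class = "x")
  prof2 <- scaled_tile_profile(fs2, map, n_tiles = 20, n_flank = 5,
                               labels = c("D", "E"))
  expect_equal(prof2$scaled, prof$scaled)

  # unscaled tile sums never exceed the feature total
  expect_lte(sum(prof$count[prof$label == "D"]), 400)
})

test_that("short domains are skipped with a count", {
  map <- domain_map(c("c", "c"), c(0, 100), c(50, 200100), c("D", "D"))
  fs <- feature_set("c", 25, class = "x")
  prof <- scaled_tile_profile(fs, map, n_tiles = 80, labels = "D")
  expect_equal(attr(prof, "n_skipped"), 1L)
})

test_that("accumulation profiles are anchored, bounded and brute-force exact", {
  anchors <- border_set("c", c(1, 2, 3) * 1e5)
  feats <- feature_set(rep("c", 3), c(1, 2, 3) * 1e5, class = "x")
  prof <- accumulation_profile(feats, anchors, window = 10000, bin = 1000)
  centre <- prof$offset == 0.5 * 1000
  expect_equal(prof$scaled[prof$count == max(prof$count)][1], 10)
  expect_true(all(prof$scaled >= 0 & prof$scaled <= 10))

  withr::local_seed(82)
  fpos <- sample.int(5e5, 200)
  feats2 <- feature_set(rep("c", 200), fpos, class = "x")
  anchors2 <- border_set("c", sample.int(5e5, 10))
  prof2 <- accumulation_profile(feats2, anchors2, window = 20000, bin = 2000)
  want <- numeric(20)
  for (a in anchors2$pos) {
    off <- fpos - a
    off <- off[off >= -20000 & off < 20000]
    for (o in off) want[floor(o / 2000) + 11] <- want[floor(o / 2000) + 11] + 1
  }
  expect_equal(prof2$count, want)
  expect_true(all(prof2$scaled >= 0 & prof2$scaled <= 10))
  expect_equal(min(prof2$scaled), 0)
  expect_equal(max(prof2$scaled), 10)

  expect_error(accumulation_profile(feats2, border_set(character(), numeric()),
                                    1000, 100), "zero anchors")
})

test_that("scaled band overlays report occupancy fractions that sum to one", {
  # bands exactly on E domains flanked by D: interior all E, flanks all D
  map <- alternating_map(2e6, 1e5, 2e5, chrom = "c")
  e <- map[map$label == "E", ]
  e <- e[e$start > 0 & e$end < 2e6, ]
  bands <- data.frame(chrom = "c", start = e$start, end = e$end)
  ov <- scaled_interval_overlay(map, bands, target_length = 200000,
                                flank = 50000, min_length = 75000,
                                step = 10000)
  interior <- ov$position > 0 & ov$position < 200000
  expect_true(all(ov$frac_E[interior] == 1))
  expect_true(all(ov$frac_D[ov$position < 0] == 1))
  expect_true(all(abs(ov$frac_D + ov$frac_E + ov$frac_gap - 1) < 1e-12))

  # a single half-D half-E band maps its halves faithfully
  map2 <- domain_map(c("c", "c"), c(0, 100000), c(100000, 200000),
                     c("D", "E"))
  band2 <- data.frame(chrom = "c", start = 20000, end = 180000)
  ov2 <- scaled_interval_overlay(map2, band2, target_length = 160000,
                                 flank = 0, min_length = 0, step = 20000)
  expect_equal(ov2$frac_D[ov2$position == 20000], 1)
  expect_equal(ov2$frac_E[ov2$position == 140000], 1)

  expect_error(scaled_interval_overlay(map2, band2, min_length = 1e6),
               "no bands")
})
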