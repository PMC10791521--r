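test_that("interval-weighted rho matches hand examples", {
  win <- data.table(chrom = "chr1", start = 0L, end = 200000L)
  ## one interval fully inside the window
  iv1 <- data.table(chrom = "chr1", left_pos = 100L, right_pos = 200L,
                    rho_per_bp = 0.02)
  expect_equal(window_weighted_rho(iv1, win, min_coverage = 0)$rho_per_bp, 0.02)
  ## two intervals: (0.01*100 + 0.04*300) / 400 = 0.0325
  iv2 <- data.table(chrom = "chr1", left_pos = c(0L, 100L),
                    right_pos = c(100L, 400L), rho_per_bp = c(0.01, 0.04))
  expect_equal(window_weighted_rho(iv2, win, min_coverage = 0)$rho_per_bp,
               0.0325)
  ## an interval spanning a window boundary is apportioned 50/50
  w2 <- data.table(chrom = "chr1", start = c(0L, 200000L),
                   end = c(200000L, 400000L))
  iv3 <- data.table(chrom = "chr1", left_pos = 150000L, right_pos = 250000L,
                    rho_per_bp = 0.05)
  r <- window_weighted_rho(iv3, w2, min_coverage = 0)
  expect_equal(r$covered_bp, c(50000, 50000))
  expect_equal(r$rho_per_bp, c(0.05, 0.05))
})

test_that("aggregation equals the brute-force per-bp oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    L <- sample(2000:10000, 1)
    bp <- sort(sample(0:L, sample(3:12, 1)))
    bp <- unique(c(0, bp, L))
    iv <- data.table(chrom = "c", left_pos = head(bp, -1),
                     right_pos = tail(bp, -1),
                     rho_per_bp = runif(length(bp) - 1, 0, 0.1))
    ts <- sort(sample(0:(L - 10), 2))
    te <- c(ts[2], min(L, ts[2] + sample(100:2000, 1)))
    tg <- data.table(chrom = "c", start = ts, end = te)
    got <- window_weighted_rho(iv, tg, min_coverage = 0)$rho_per_bp
    want <- c(bp_weighted_rho_oracle(iv, ts[1], te[1]),
              bp_weighted_rho_oracle(iv, ts[2], te[2]))
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-12)
  }
})

test_that("aggregation is invariant to splitting an interval at an interior point", {
  iv <- data.table(chrom = "c", left_pos = c(0L, 500L),
                   right_pos = c(500L, 2000L), rho_per_bp = c(0.02, 0.07))
  split_iv <- data.table(chrom = "c", left_pos = c(0L, 500L, 1200L),
                         right_pos = c(500L, 1200L, 2000L),
                         rho_per_bp = c(0.02, 0.07, 0.07))
  tg <- data.table(chrom = "c", start = c(0L, 300L), end = c(2000L, 1500L))
  expect_equal(window_weighted_rho(iv, tg, min_coverage = 0)$rho_per_bp,
               window_weighted_rho(split_iv, tg, min_coverage = 0)$rho_per_bp)
})

test_that("unsorted or overlapping rho intervals are rejected", {
  bad <- data.table(chrom = "c", left_pos = c(0L, 50L),
                    right_pos = c(100L, 150L), rho_per_bp = c(0.1, 0.1))
  tg <- data.table(chrom = "c", start = 0L, end = 100L)
  expect_error(window_weighted_rho(bad, tg), "non-overlapping")
})

test_that("genome-wide Ne estimation and cM/Mb conversion are consistent", {
  ## rho = 0.04/bp at 3 cM/Mb -> Ne = 0.04 / (4 * 3e-8) = 333333.3
  rw <- data.table(rho_per_bp = 0.04, covered_bp = 1e6)
  expect_equal(estimate_genomewide_ne(rw, 3), 0.04 / (4 * 3e-8))
  ## noise-free inverse identity
  ne_true <- 250000
  rw2 <- data.table(rho_per_bp = c(0.01, 0.05, 0.2), covered_bp = c(1, 2, 3) * 1e6)
  map <- rw2$rho_per_bp / (4 * ne_true) * 1e8
  expect_equal(estimate_genomewide_ne(rw2, map), ne_true)
  expect_error(estimate_genomewide_ne(rw2, rep(0, 3)), "zero")
  ## conversion: 0.037 / (4 * 3e5) * 1e8 = 3.0833 cM/Mb
  expect_equal(convert_to_cm(0.037, 3e5), 3.0833333, tolerance = 1e-6)
  expect_equal(convert_to_cm(0, 3e5), 0)
  expect_error(convert_to_cm(0.037, -1), "positive")
  ## round trip through the Ne estimate reproduces the map mean
  ne_hat <- estimate_genomewide_ne(rw2, map)
  expect_equal(sum(convert_to_cm(rw2$rho_per_bp, ne_hat) * rw2$covered_bp) /
                 sum(rw2$covered_bp),
               sum(map * rw2$covered_bp) / sum(rw2$covered_bp))
})

test_that("conservation classification handles degenerate and clear cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_true(all(classify_rate_conservation(x, x) == "conserved"))
  ## one strong off-diagonal window among many diagonal ones is divergent
  ## with A higher
  a <- c(1:20, 30); b <- c(1:20, 5)
  lab <- classify_rate_conservation(a, b)
  expect_equal(lab[21], "divergent_A_higher")
  expect_gt(mean(lab[1:20] == "conserved"), 0.8)
  expect_error(classify_rate_conservation(1:2, 1:2), "at least 3")
})

test_that("coarse aggregates track the pedigree map better than fine ones", {
  cfg <- sim_config(seed = 21)
  ls <- gen_recombination_landscape(cfg)
  w200 <- ls$windows[, .(chrom, start, end)]
  r200 <- window_weighted_rho(ls$intervals_B, w200)
  c200 <- correlate(r200$rho_per_bp, ls$linkage_map$cm_mb)$R
  w5 <- make_windows(cfg$chrom_spec, 5e6)[, .(chrom, start, end)]
  r5 <- window_weighted_rho(ls$intervals_B, w5)
  ## aggregate the 200 kb map to 5 Mb windows
  lm <- copy(ls$linkage_map)
  lm[, w5s := 5e6 * floor(start / 5e6)]
  m5 <- lm[, .(cm_mb = sum(cm_mb * (end - start)) / sum(end - start)),
           by = .(chrom, start = w5s)]
  m5 <- merge(r5, m5, by = c("chrom", "start"))
  c5 <- correlate(m5$rho_per_bp, m5$cm_mb)$R
  expect_gt(c5, c200)
  expect_gt(c200, 0.5)
})
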