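test_that("a fixed difference between large equal samples gives FST near 1", {
  n <- 50
  g1 <- matrix(2L, 1, n); g2 <- matrix(0L, 1, n)
  comp <- wc_fst_components(g1, g2)
  fst <- comp$a / (comp$a + comp$b + comp$c)
  expect_gt(fst, 0.99)
  w <- window_fst(g1, g2, "chr1", 100L,
                  data.table(chrom = "chr1", start = 0L, end = 1000L))
  expect_gt(w$fst, 0.99)
})

test_that("identical populations give window FST near zero", {
  d <- sim_identical_pops(400, 30, 30, seed = 2)
  w <- window_fst(d$g1, d$g2, rep("chr1", 400), seq_len(400) * 10L,
                  data.table(chrom = "chr1", start = 0L, end = 10000L))
  expect_lt(abs(w$fst), 0.02)
})

test_that("per-site components equal an independent scalar oracle", {
  set.seed(11)
  for (rep in 1:6) {
    ns <- sample(10:50, 1)
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    p <- runif(ns, 0.02, 0.98)
    g1 <- t(vapply(p, function(pp) rbinom(n1, 2, pp), integer(n1)))
    g2 <- t(vapply(p, function(pp) {
      rbinom(n2, 2, pmin(1, pmax(0, pp + runif(1, -0.2, 0.2))))
    }, integer(n2)))
    comp <- wc_fst_components(g1, g2)
    for (j in seq_len(ns)) {
      want <- wc_oracle_site(g1[j, ], g2[j, ])
      got <- unlist(comp[j])
      if (any(is.na(want))) {
        expect_true(all(is.na(got)))
      } else {
        expect_lt(max(abs(got - want)), 1e-12)
      }
    }
  }
})

test_that("windows with only monomorphic sites are missing; low call counts error", {
  g1 <- matrix(0L, 3, 5); g2 <- matrix(0L, 3, 5)
  w <- window_fst(g1, g2, rep("chr1", 3), c(1L, 2L, 3L),
                  data.table(chrom = "chr1", start = 0L, end = 10L))
  expect_true(is.na(w$fst))
  g_na <- matrix(c(0L, NA, NA, NA, NA), 1, 5)
  expect_error(wc_fst_components(g_na, matrix(0L, 1, 5)), "fewer than 2")
})

test_that("Z-transform standardizes per chromosome and is idempotent", {
  x <- c(rnorm(20, 5, 2), rnorm(30, -1, 0.5))
  ch <- rep(c("c1", "c2"), c(20, 30))
  z <- ztransform_by_chrom(x, ch)
  expect_equal(as.numeric(tapply(z, ch, mean)), c(0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(tapply(z, ch, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(ztransform_by_chrom(z, ch), z, tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing reproduces cubics exactly", {
  x <- 1:25
  for (coefs in list(c(2, 0, 0, 0), c(1, -2, 0.5, 0.03))) {
    y <- coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
    expect_lt(max(abs(smooth_zfst(y) - y)), 1e-10)
  }
  ## constant series unchanged; short series pass through
  expect_equal(smooth_zfst(rep(3, 10)), rep(3, 10))
  expect_equal(smooth_zfst(c(1, 5, 2)), c(1, 5, 2))
})

test_that("centre point of the 7-point cubic filter equals the least-squares fit", {
  set.seed(4)
  y <- rnorm(7)
  ## independent oracle: fit a cubic to the 7 points, predict the centre
  fit <- lm(y ~ poly(1:7, 3, raw = TRUE))
  want <- unname(predict(fit)[4])
  got <- smooth_zfst(y)[4]
  expect_equal(got, want, tolerance = 1e-10)
  ## which equals the classical (-2,3,6,7,6,3,-2)/21 convolution
  expect_equal(got, sum(c(-2, 3, 6, 7, 6, 3, -2) / 21 * y), tolerance = 1e-10)
})

test_that("peak calling merges threshold-exceeding runs", {
  w <- data.table(chrom = "c1", start = (0:9) * 1e5, end = (1:10) * 1e5,
                  zfst_smooth = c(0, 0, 2.5, 2.6, 2.2, 0, 2.4, 0, 0, 0))
  pk <- call_fst_peaks(w)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$start, c(2e5, 6e5))
  expect_equal(pk$end, c(5e5, 7e5))
  expect_equal(pk$n_windows, c(3L, 1L))
  ## nothing above threshold -> empty
  w2 <- copy(w)[, zfst_smooth := 0.5]
  expect_equal(nrow(call_fst_peaks(w2)), 0)
  ## two runs separated by one sub-threshold window stay two peaks
  w3 <- copy(w)[, zfst_smooth := c(2.5, 2.5, 0, 2.5, 2.5, 0, 0, 0, 0, 0)]
  expect_equal(nrow(call_fst_peaks(w3)), 2)
})

test_that("peaks are shared on any overlap, unique otherwise", {
  p1 <- data.table(chrom = c("c1", "c1"), start = c(0, 5e5), end = c(2e5, 7e5))
  p2 <- data.table(chrom = "c1", start = 199999, end = 4e5)
  cl <- classify_peaks(p1, p2)
  expect_equal(cl$peaks1$label, c("shared", "A_unique"))  # 1-bp overlap counts
  expect_equal(cl$peaks2$label, "shared")
  cl0 <- classify_peaks(p1, p2[0])
  expect_equal(cl0$peaks1$label, c("A_unique", "A_unique"))
})

test_that("positional enrichment flags peaks concentrated at chromosome ends", {
  ## several microchromosomes, each with its peaks in the outermost bin;
  ## the circular null then rarely reproduces the end concentration
  w <- rbindlist(lapply(1:4, function(k) {
    data.table(chrom = paste0("m", k), start = (0:23) * 1e5,
               end = (1:24) * 1e5, class = "micro", peak = FALSE)
  }))
  w[start < 2e5, peak := TRUE]
  enr <- positional_peak_enrichment(w, n_perm = 500, seed = 3)
  b1 <- enr[bin == 1]
  expect_gt(b1$enrichment, 1)
  expect_lt(b1$p_value, 0.05)
  ## no peaks at all: p-values 1, enrichment undefined
  w0 <- copy(w)[, peak := FALSE]
  enr0 <- positional_peak_enrichment(w0, n_perm = 100, seed = 3)
  expect_true(all(is.na(enr0$enrichment)))
  expect_true(all(enr0$p_value == 1))
})
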