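test_that("theta0 follows 4*mu*L with input validation", {
  expect_equal(scaled_mutation_rate(4.6e-9, 564393274), 10.38, tolerance = 1e-3)
  expect_equal(scaled_mutation_rate(0, 1e6), 0)
  expect_equal(scaled_mutation_rate(1e-8, 1e8), 4.0)
  expect_error(scaled_mutation_rate(1e-8, 0), "positive")
  cfg <- tiny_config()
  expect_equal(cfg$theta0, 4 * cfg$mu * cfg$L)
})

test_that("configuration validation catches impossible setups", {
  expect_error(sim_config(chrom_spec = data.table(name = "c", length = 1e4,
                                                  class = "macro")),
               "shorter than one window")
  expect_error(sim_config(sweep_truth = data.table(chrom = "chr1", pos = 99e9,
                                                   alpha = 1e-5, species = "A")),
               "outside chromosome")
  expect_error(sim_config(divergent_fraction = 1.5))
})

test_that("landscape construction: divergent fraction, labels, trends", {
  cfg <- sim_config(seed = 3, divergent_fraction = 0.24)
  ls <- gen_recombination_landscape(cfg)
  wt <- ls$windows
  frac <- mean(wt$divergent_truth)
  ## Bernoulli(0.24) within 4 binomial SEs
  expect_lt(abs(frac - 0.24), 4 * sqrt(0.24 * 0.76 / nrow(wt)))
  expect_true(all(wt$divergent_label[!wt$divergent_truth] == "conserved"))
  expect_true(all(wt$divergent_label[wt$divergent_truth] != "conserved"))
  ## divergent_A_higher means exactly that on the truth landscape
  dah <- wt[divergent_label == "divergent_A_higher"]
  expect_true(all(dah$rho_A > dah$rho_B))
  ## positional trends: macro centre-reduced, micro end-reduced
  wt[, relpos := pmin((start + end) / 2, chrlen - (start + end) / 2) / (chrlen / 2)]
  macro <- wt[class == "macro"]
  micro <- wt[class == "micro"]
  mr <- function(d) mean(log(d[relpos > 0.6]$rho_A)) - mean(log(d[relpos < 0.4]$rho_A))
  expect_lt(mr(macro), 0)  # centre lower than ends... centre has relpos ~1
  expect_gt(mr(micro), 0)
})

test_that("a zero divergent fraction leaves the species landscapes congruent", {
  cfg <- sim_config(seed = 4, divergent_fraction = 0, rho_noise_sd = 1e-3,
                    interval_noise_sd = 1e-3)
  ls <- gen_recombination_landscape(cfg)
  expect_gt(cor(log(ls$windows$rho_A), log(ls$windows$rho_B)), 0.999)
})

test_that("landscapes and datasets are seed-deterministic", {
  cfg <- tiny_config(seed = 17)
  l1 <- gen_recombination_landscape(cfg)
  l2 <- gen_recombination_landscape(cfg)
  expect_identical(l1, l2)
  d1 <- sim_dataset(cfg)
  d2 <- sim_dataset(cfg)
  expect_identical(d1$variants$sites, d2$variants$sites)
  expect_identical(d1$variants$geno, d2$variants$geno)
  expect_identical(d1$coding$alignments, d2$coding$alignments)
  ## different seeds differ
  d3 <- sim_dataset(tiny_config(seed = 18))
  expect_false(identical(d1$variants$sites, d3$variants$sites))
})

test_that("diversity is higher in high-recombination windows", {
  cfg <- tiny_config(seed = 23)
  ls <- gen_recombination_landscape(cfg)
  vd <- gen_variant_data(cfg, ls)
  s <- vd$sites; wt <- ls$windows
  nh <- 2 * ncol(vd$geno$A)
  der <- rowSums(vd$geno$A)
  pi_site <- 2 * der * (nh - der) / (nh * (nh - 1))
  key <- paste(s$chrom, floor(s$pos0 / cfg$window_bp))
  piw <- tapply(pi_site, key, sum)
  wt[, key := paste(chrom, floor(start / cfg$window_bp))]
  wt[, piw := as.numeric(piw[key])]
  wt[is.na(piw), piw := 0]
  q <- quantile(wt$rho_A, c(1 / 3, 2 / 3))
  expect_gt(mean(wt[rho_A > q[2]]$piw), mean(wt[rho_A < q[1]]$piw))
})

test_that("the dataset round-trips through its on-disk formats", {
  cfg <- tiny_config(seed = 29, n_genes = 25L)
  dat <- sim_dataset(cfg)
  dir <- file.path(tempdir(), "rt_dataset")
  unlink(dir, recursive = TRUE)
  write_dataset(dat, dir)
  rd <- read_dataset(dir)
  expect_equal(rd$manifest$seed, cfg$seed)
  expect_equal(rd$manifest$n_sites, nrow(dat$variants$sites))
  ## VCF round trip: identical coordinates and ALT-dosage matrix
  expect_equal(rd$groupA$sites$pos0, dat$variants$sites$pos0)
  expect_equal(rd$groupA$sites$ref, dat$variants$sites$ref)
  alt_is_der <- dat$variants$sites$alt == dat$variants$sites$der
  dosA <- dat$variants$geno$A
  dosA[!alt_is_der, ] <- 2L - dosA[!alt_is_der, , drop = FALSE]
  got <- rd$groupA$dosage[, seq_len(ncol(dosA)), drop = FALSE]
  dimnames(got) <- NULL
  expect_equal(got, dosA)
  ## interval and map tables identical
  expect_equal(rd$rho_A$rho_per_bp, dat$landscape$intervals_A$rho_per_bp)
  expect_equal(rd$linkage_map$cm_mb, dat$landscape$linkage_map$cm_mb)
  ## alignments round trip
  g1 <- names(dat$coding$alignments)[1]
  expect_equal(unname(rd$alignments[[g1]][c("A", "B", "OUT")]),
               unname(dat$coding$alignments[[g1]][c("A", "B", "OUT")]))
  ## a missing component is reported by name
  unlink(file.path(dir, "rho_B.tsv"))
  expect_error(read_dataset(dir), "rho_B.tsv")
  expect_error(write_dataset(list(cfg = cfg), tempdir()), "missing component")
})

test_that("a zero SNP rate still yields a valid, empty VCF", {
  cfg <- tiny_config(seed = 30, snp_per_bp = 0, fix_frac = 0, n_genes = 20L)
  dat <- sim_dataset(cfg)
  expect_equal(nrow(dat$variants$sites), 0)
  dir <- file.path(tempdir(), "empty_vcf_ds")
  unlink(dir, recursive = TRUE)
  write_dataset(dat, dir)
  v <- readLines(file.path(dir, "groupA.vcf"))
  expect_true(any(grepl("^##fileformat=VCFv4.2", v)))
  expect_equal(sum(!grepl("^#", v)), 0)
})

test_that("byte-identical files come from identical configurations", {
  cfg <- tiny_config(seed = 44, n_genes = 15L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  write_dataset(sim_dataset(cfg), d1)
  write_dataset(sim_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("coding truth: neutral DFE makes fourfold and zerofold spectra agree", {
  cfg <- tiny_config(seed = 51, dfe_truth = c(mean = 1e-6, shape = 1),
                     n_genes = 120L)
  ls <- gen_recombination_landscape(cfg)
  cd <- gen_coding_data(cfg, ls)
  v <- cd$coding_variants[species == "A"]
  nh <- 2 * cfg$n_dip[["A"]]
  s4 <- tabulate(v[class == "fourfold", count], nbins = nh - 1)
  s0 <- tabulate(v[class == "zerofold", count], nbins = nh - 1)
  ## same shape up to sampling noise: compare normalized spectra
  p4 <- s4 / sum(s4); p0 <- s0 / sum(s0)
  se <- sqrt(p4 * (1 - p4) / sum(s4) + p0 * (1 - p0) / sum(s0))
  expect_lt(max(abs(p4 - p0) / pmax(se, 1e-6)), 4)
  ## truth table lists recombination and conservation per gene
  expect_true(all(c("rho_A_truth", "rho_B_truth", "divergent_label_truth")
                  %in% names(cd$genes)))
  expect_false(anyNA(cd$genes$rho_A_truth))
})
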