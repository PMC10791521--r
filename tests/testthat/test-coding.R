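test_that("degeneracy classes match hand examples from the code table", {
  ## GGG: third position fourfold; ATG: all positions zerofold
  expect_equal(classify_degeneracy("GGG")[3], "fourfold")
  expect_equal(classify_degeneracy("ATG"), rep("zerofold", 3))
  ## TTA position 1: T->C synonymous (CTA = Leu), T->A/G nonsynonymous
  expect_equal(classify_degeneracy("TTA")[1], "other")
  ## GGG positions 1-2 admit no synonymous change (Arg/Trp, Glu/Ala/Val)
  ## and the incomplete terminal codon is "other"
  expect_equal(classify_degeneracy("GGGA"),
               c("zerofold", "zerofold", "fourfold", "other"))
})

test_that("degeneracy matches exhaustive enumeration over 64 codons x 3 positions", {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  for (cd in names(code)) {
    got <- classify_degeneracy(cd)
    for (p in 1:3) {
      alts <- setdiff(bases, substr(cd, p, p))
      syn <- vapply(alts, function(b) {
        mut <- cd; substr(mut, p, p) <- b
        unname(code[mut]) == unname(code[cd])
      }, TRUE)
      want <- if (all(syn)) "fourfold" else if (!any(syn)) "zerofold" else "other"
      expect_equal(got[p], want)
    }
  }
})

test_that("degeneracy is invariant under the strand convention", {
  set.seed(8)
  cds <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  plus <- classify_degeneracy(cds)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cds, "")[[1]]), collapse = ""))
  minus <- classify_degeneracy(rc, strand = "-")
  ## the minus-strand call, returned in input orientation, must agree with
  ## the plus-strand call after reversing
  expect_equal(rev(minus), plus)
})

test_that("diversity matches mean pairwise difference on haplotype matrices", {
  ## one SNP at derived count 2 of n = 4 over 10 callable sites:
  ## mean pairwise difference 4/6 per 10 sites = 0.0667
  expect_equal(diversity_by_class(2, 4, 10), 2 / 3 / 10, tolerance = 1e-12)
  expect_equal(diversity_by_class(integer(0), 4, 10), 0)
  ## small-instance oracle: explicit haplotype matrix
  set.seed(12)
  n <- 6; sites <- 40
  hap <- matrix(rbinom(n * sites, 1, 0.3), sites, n)
  counts <- rowSums(hap)
  seg <- counts > 0 & counts < n
  pairs <- combn(n, 2)
  mpd <- mean(apply(pairs, 2, function(pr) sum(hap[, pr[1]] != hap[, pr[2]])))
  expect_equal(diversity_by_class(counts[seg], n, sites), mpd / sites,
               tolerance = 1e-12)
  ## GC-conservative filter zeroes the numerator for a lone WS variant
  expect_equal(diversity_by_class(2, 4, 10, gc_conservative_flag = FALSE,
                                  gc_conservative = TRUE), 0)
  expect_error(diversity_by_class(2, 4, 0), "denominator")
})

test_that("parsimony assigns focal-branch substitutions and classifies them", {
  ## focal T, sister and outgroup C at a fourfold third position (GGx)
  r <- map_substitutions("GGT", "GGC", "GGC")
  expect_equal(r$s_subs, 1L)
  expect_equal(r$n_subs, 0L)
  ## all identical: nothing
  r0 <- map_substitutions("GGC", "GGC", "GGC")
  expect_equal(r0$s_subs + r0$n_subs, 0L)
  ## focal C -> G at a zerofold position: GC-conservative nonsynonymous
  ## CCA (Pro) focal GCA (Ala): first position, C->G is S<->S
  rg <- map_substitutions("GCA", "CCA", "CCA", gc_conservative = TRUE)
  expect_equal(rg$n_subs, 1L)
  expect_equal(rg$s_subs, 0L)
  ## the same substitution is counted without the filter too
  ra <- map_substitutions("GCA", "CCA", "CCA")
  expect_equal(ra$n_subs, 1L)
  ## sites where all three sequences differ are skipped
  rs <- map_substitutions("ATT", "GTT", "CTT")
  expect_equal(rs$n_subs + rs$s_subs, 0L)
  ## a non-GC-conservative focal change is excluded under the filter
  rx <- map_substitutions("GGT", "GGC", "GGC", gc_conservative = TRUE)
  expect_equal(rx$s_subs + rx$n_subs, 0L)  # C->T is weak/strong mixed
})

test_that("site opportunities partition codon positions", {
  ## without the filter each codon contributes 3 sites total
  r <- map_substitutions("GGCAAT", "GGCAAT", "GGCAAT")
  expect_equal(r$n_sites + r$s_sites, 6, tolerance = 1e-12)
  ## with the GC filter each site contributes exactly one opportunity
  rg <- map_substitutions("GGCAAT", "GGCAAT", "GGCAAT", gc_conservative = TRUE)
  expect_equal(rg$n_sites + rg$s_sites, 6)
})

test_that("dN/dS aggregation excludes short genes and divides mean by mean", {
  g <- data.table(dn = c(0.01, 0.03), ds = c(0.02, 0.02),
                  exon_len = c(500, 300))
  expect_equal(aggregate_dnds(g)$dnds, 1.0)
  ## a 150 bp gene is excluded
  g2 <- rbind(g, data.table(dn = 10, ds = 10, exon_len = 150))
  expect_equal(aggregate_dnds(g2)$dnds, 1.0)
  expect_equal(aggregate_dnds(g2)$n_genes, 2L)
  ## all-zero dS flagged as undefined
  g3 <- data.table(dn = c(0.1, 0.2), ds = c(0, 0), exon_len = 500)
  expect_false(aggregate_dnds(g3)$defined)
  expect_true(is.na(aggregate_dnds(g3)$dnds))
  expect_error(aggregate_dnds(g[exon_len > 600]), "no genes")
})

test_that("gene binning: equal-count terciles, median density split, tie rules", {
  b <- bin_genes(rho = 1:9, functional_density = rep(0.5, 9), pos = 1:9)
  expect_equal(as.vector(table(b$rho_bin)), rep(3L, 3))
  ## constant density still yields a ceiling/floor split by position
  expect_equal(b$density_bin[b$rho_bin == 1], c("low", "low", "high"))
  ## tie at the tercile boundary goes to the lower bin for the earlier gene
  b2 <- bin_genes(rho = c(1, 2, 2, 3, 4, 5), functional_density = 1:6,
                  pos = c(10, 30, 20, 40, 50, 60), k_bins = 3)
  expect_equal(b2$rho_bin[3], 1L)  # earlier coordinate of the tied pair
  expect_equal(b2$rho_bin[2], 2L)
  expect_error(bin_genes(1:2, 1:2, 1:2, k_bins = 3), "fewer genes")
})

test_that("dN/dS over synthetic alignments recovers the generator's omega", {
  cfg <- tiny_config(seed = 31, n_genes = 150L)
  ls <- gen_recombination_landscape(cfg)
  cd <- gen_coding_data(cfg, ls)
  subs <- rbindlist(lapply(names(cd$alignments), function(gn) {
    a <- cd$alignments[[gn]]
    as.data.table(map_substitutions(a[["A"]], a[["B"]], a[["OUT"]]))
  }))
  subs[, exon_len := cd$genes$exon_len]
  est <- aggregate_dnds(subs)
  expect_equal(est$dnds, cfg$omega_truth, tolerance = 0.25)
  ## neutral-limit sanity of the coding SFS: fourfold bin means ~ theta/i
  v4 <- cd$coding_variants[species == "A" & class == "fourfold"]
  n4 <- sum(cd$coding_sites$n_fourfold)
  nh <- 2 * cfg$n_dip[["A"]]
  obs <- tabulate(v4$count, nbins = nh - 1)
  expected <- cfg$theta_coding * n4 / seq_len(nh - 1)
  ## chi-square-style agreement within Monte-Carlo error on the first bins
  z <- (obs - expected) / sqrt(expected)
  expect_lt(max(abs(z[1:8])) / 4, 1)
})
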