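test_that("three-group fixation rule assigns ancestral states", {
  v <- data.table(
    ref = c("A", "A", "T", "C"), alt = c("G", "G", "C", "T"),
    ## outgroup fixed ref, group a fixed ref, group b polymorphic -> ref
    a_ref = c(10, 4, 0, 5), a_alt = c(0, 6, 10, 5),
    b_ref = c(6, 3, 0, 4), b_alt = c(4, 7, 10, 6),
    o_ref = c(1, 0, 0, 0), o_alt = c(0, 1, 1, 1))
  p <- polarize_variants(v)
  ## site 1: groups A (fixed ref) + outgroup (fixed ref) agree
  expect_true(p$polarized[1])
  expect_equal(p$ancestral[1], "A")
  expect_equal(p$derived[1], "G")
  ## site 2: only outgroup fixed -> unpolarized
  expect_false(p$polarized[2])
  ## site 3: groups A and B fixed alt, outgroup fixed alt -> ancestral alt
  expect_true(p$polarized[3])
  expect_equal(p$ancestral[3], "C")
  ## site 4: all three polymorphic or conflicting -> unpolarized
  expect_false(p$polarized[4])
})

test_that("two groups fixed for different alleles leave the site unpolarized", {
  v <- data.table(ref = "T", alt = "C",
                  a_ref = 10, a_alt = 0,   # fixed ref
                  b_ref = 0, b_alt = 10,   # fixed alt
                  o_ref = 0, o_alt = 0)    # no calls: cannot vote
  v$o_ref <- 1; v$o_alt <- 1               # het outgroup: not fixed
  p <- polarize_variants(v)
  expect_false(p$polarized[1])
})

test_that("polarization equals brute-force enumeration over fixation configs", {
  ## enumerate small allele-count grids for the three groups
  grid <- expand.grid(a_ref = 0:2, a_alt = 0:2, b_ref = 0:2, b_alt = 0:2,
                      o_ref = 0:1, o_alt = 0:1)
  grid <- grid[rowSums(grid) > 0, ]
  v <- data.table(ref = "A", alt = "G", grid)
  p <- polarize_variants(v)
  brute <- apply(grid, 1, function(r) {
    fixed <- function(nr, na) {
      if (nr + na == 0) return(NA_character_)
      if (na == 0) return("ref")
      if (nr == 0) return("alt")
      NA_character_
    }
    f <- c(fixed(r["a_ref"], r["a_alt"]), fixed(r["b_ref"], r["b_alt"]),
           fixed(r["o_ref"], r["o_alt"]))
    tb <- table(f)
    if (length(tb) && max(tb) >= 2) names(tb)[which.max(tb)] else NA_character_
  })
  expect_equal(p$polarized, unname(!is.na(brute)))
  anc_expect <- unname(ifelse(brute == "ref", "A", "G"))
  expect_equal(p$ancestral[p$polarized], anc_expect[!is.na(brute)])
})

test_that("swapping ref/alt labels leaves the ancestral base unchanged", {
  set.seed(3)
  n <- 200
  v <- data.table(ref = sample(c("A", "C"), n, TRUE), alt = "G",
                  a_ref = sample(0:5, n, TRUE), a_alt = sample(0:5, n, TRUE),
                  b_ref = sample(0:5, n, TRUE), b_alt = sample(0:5, n, TRUE),
                  o_ref = sample(0:1, n, TRUE), o_alt = sample(0:1, n, TRUE))
  v <- v[a_ref + a_alt + b_ref + b_alt + o_ref + o_alt > 0]
  p1 <- polarize_variants(v)
  vs <- copy(v)
  setnames(vs, c("ref", "alt", "a_ref", "a_alt", "b_ref", "b_alt",
                 "o_ref", "o_alt"),
           c("alt", "ref", "a_alt", "a_ref", "b_alt", "b_ref",
             "o_alt", "o_ref"))
  p2 <- polarize_variants(vs)
  expect_equal(p1$polarized, p2$polarized)
  expect_equal(p1$ancestral[p1$polarized], p2$ancestral[p2$polarized])
  expect_equal(p1$mut_class, p2$mut_class)
})

test_that("mutation classes and the GC-conservative flag follow base strength", {
  v <- data.table(ref = c("A", "C", "A", "C"), alt = c("T", "G", "G", "T"),
                  a_ref = 2, a_alt = 0, b_ref = 2, b_alt = 0,
                  o_ref = 1, o_alt = 0)
  p <- polarize_variants(v)
  expect_equal(p$mut_class, c("WW", "SS", "WS", "SW"))
  expect_equal(p$gc_conservative, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("sites with zero called alleles everywhere raise an error", {
  v <- data.table(ref = "A", alt = "G", a_ref = 0, a_alt = 0,
                  b_ref = 0, b_alt = 0, o_ref = 0, o_alt = 0)
  expect_error(polarize_variants(v), "zero called")
})

test_that("callable-site tallies intersect mask and class intervals", {
  mask <- data.table(chrom = "chr1", start = 0L, end = 100L)
  cls <- list(four = data.table(chrom = "chr1", start = 50L, end = 150L))
  t1 <- tally_site_classes(mask, cls)
  expect_equal(t1[class == "four", callable_bp], 50)
  expect_equal(t1[class == "all", callable_bp], 100)
  ## three disjoint intervals sum their lengths
  mask3 <- data.table(chrom = "chr1", start = c(0L, 200L, 400L),
                      end = c(100L, 250L, 430L))
  t3 <- tally_site_classes(mask3)
  expect_equal(t3[class == "all", callable_bp], 180)
  ## overlapping mask intervals are rejected
  bad <- data.table(chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L))
  expect_error(tally_site_classes(bad), "non-overlapping")
})

test_that("unfolded SFS bins count derived copies and bound-check", {
  s <- build_sfs(c(3), 10, invariant_count = 99)
  expect_equal(s$bins, c(0, 0, 1, rep(0, 6)))
  expect_equal(s$invariant, 99)
  ## unpolarized sites (NA) contribute nothing
  s2 <- build_sfs(c(3, NA, NA), 10)
  expect_equal(sum(s2$bins), 1)
  ## monomorphic (0) and fixed (n) counted separately
  s3 <- build_sfs(c(0, 10, 5), 10, invariant_count = 7)
  expect_equal(s3$invariant, 8)
  expect_equal(s3$fixed, 1)
  expect_error(build_sfs(c(11), 10), "derived counts")
  full <- sfs_full_spectrum(s3)
  expect_length(full, 11)
  expect_equal(full[1], 8)
  expect_equal(full[11], 1)
})

test_that("SFS bins plus invariant sites account for every callable site", {
  cfg <- tiny_config(seed = 9)
  ls <- gen_recombination_landscape(cfg)
  vd <- gen_variant_data(cfg, ls)
  callable <- vd$mask[, sum(end - start)]
  der <- rowSums(vd$geno$A)
  use <- der >= 1
  s <- build_sfs(der[use], 2 * ncol(vd$geno$A),
                 invariant_count = callable - sum(use))
  expect_equal(sum(s$bins) + s$invariant + s$fixed, callable)
})
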