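library(data.table)

## small two-chromosome configuration used by fast pipeline-level tests
tiny_config <- function(seed = 5, n_genes = 60L, ...) {
  sim_config(
    seed = seed,
    chrom_spec = data.table(name = c("chr1", "chr21"),
                            length = c(3e6, 2e6),
                            class = c("macro", "micro")),
    sweep_truth = data.table(chrom = "chr1", pos = 2.4e6, alpha = 2e-5,
                             species = "A"),
    peak_truth = data.table(chrom = "chr1", start = 1.0e6, end = 1.6e6,
                            class = "shared"),
    n_genes = n_genes,
    ...)
}

## brute-force per-bp expansion oracle for interval-weighted aggregation
bp_weighted_rho_oracle <- function(intervals, target_start, target_end) {
  ## intervals: data.table(left_pos, right_pos, rho_per_bp), one chromosome
  bp <- target_start:(target_end - 1)
  rho <- rep(NA_real_, length(bp))
  for (j in seq_len(nrow(intervals))) {
    sel <- bp >= intervals$left_pos[j] & bp < intervals$right_pos[j]
    rho[sel] <- intervals$rho_per_bp[j]
  }
  if (all(is.na(rho))) return(NA_real_)
  mean(rho, na.rm = TRUE)
}

## independent per-site Weir-Cockerham (1984) two-population estimator,
## written as a literal scalar transcription of the published formulas
wc_oracle_site <- function(g1, g2) {
  n1 <- sum(!is.na(g1)); n2 <- sum(!is.na(g2))
  p1 <- sum(g1, na.rm = TRUE) / (2 * n1)
  p2 <- sum(g2, na.rm = TRUE) / (2 * n2)
  h1 <- sum(g1 == 1, na.rm = TRUE) / n1
  h2 <- sum(g2 == 1, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) return(c(a = NA, b = NA, c = NA))
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

## simulate two populations with identical allele/genotype frequencies
sim_identical_pops <- function(n_sites, n1, n2, seed = 1) {
  set.seed(seed)
  p <- runif(n_sites, 0.05, 0.95)
  g1 <- t(vapply(p, function(pp) rbinom(n1, 2, pp), integer(n1)))
  g2 <- t(vapply(p, function(pp) rbinom(n2, 2, pp), integer(n2)))
  list(g1 = g1, g2 = g2)
}
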