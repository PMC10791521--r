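## Windowed Weir-Cockerham FST between two populations, per-chromosome
## Z-transformation, Savitzky-Golay smoothing, differentiation-peak calling,
## shared/lineage-specific classification, and positional enrichment.

#' Per-site Weir-Cockerham variance components for two populations
#'
#' Computes the (a, b, c) variance components of Weir & Cockerham's (1984)
#' theta estimator per biallelic site from diploid genotype dosages, using
#' observed heterozygosity: a = among-population, b = between individuals
#' within populations, c = within individuals. Sites monomorphic across both
#' populations get NA components (they carry no information and are excluded
#' from ratio-of-sums aggregation).
#'
#' @param geno1,geno2 integer matrices (sites x individuals) of alt-allele
#'   dosages 0/1/2, NA = missing genotype
#' @return data.table with columns a, b, c (NA for monomorphic sites)
#' @export
wc_fst_components <- function(geno1, geno2) {
  g1 <- as.matrix(geno1); g2 <- as.matrix(geno2)
  stopifnot(nrow(g1) == nrow(g2))
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("site(s) with fewer than 2 called individuals in a population")
  }
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1
  a[mono] <- NA_real_; b[mono] <- NA_real_; cc[mono] <- NA_real_
  data.table(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST
#'
#' Ratio-of-sums estimator per window: FST = sum(a) / sum(a + b + c) over the
#' polymorphic sites in the window. Windows with no polymorphic site are NA.
#'
#' @param geno1,geno2 genotype dosage matrices (sites x individuals)
#' @param chrom,pos0 site coordinates (0-based)
#' @param windows data.table with chrom, start, end
#' @return the windows table with fst and n_sites columns added
#' @export
window_fst <- function(geno1, geno2, chrom, pos0, windows) {
  comp <- wc_fst_components(geno1, geno2)
  comp[, `:=`(chrom = chrom, pos0 = pos0)]
  wt <- as.data.table(windows)
  wt[, idx__ := .I]
  setkey(wt, chrom, start, end)
  comp[, `:=`(start = pos0, end = pos0 + 1)]
  ov <- foverlaps(comp[!is.na(a)], wt[, .(chrom, start, end, idx__)],
                  by.x = c("chrom", "start", "end"), nomatch = NULL)
  agg <- ov[, .(fst = sum(a) / sum(a + b + c), n_sites = .N), by = idx__]
  out <- as.data.table(windows)
  out[, `:=`(fst = NA_real_, n_sites = 0L)]
  out[agg$idx__, `:=`(fst = agg$fst, n_sites = agg$n_sites)]
  out[]
}

#' Per-chromosome Z-transformation
#'
#' Standardizes values to zero mean and unit variance within each chromosome,
#' accounting for differences in mean FST among chromosomes. NA values are
#' preserved.
#'
#' @param x numeric values (e.g. window FST)
#' @param chrom chromosome per value
#' @return Z-transformed values
#' @export
ztransform_by_chrom <- function(x, chrom) {
  ave_ok <- function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2 || sd(v[ok]) == 0) return(ifelse(ok, 0, NA_real_))
    (v - mean(v[ok])) / sd(v[ok])
  }
  unsplit(lapply(split(x, chrom), ave_ok), chrom)
}

#' Savitzky-Golay smoothing of a per-chromosome series
#'
#' Cubic (polynomial order 3) least-squares smoothing with a 7-point filter,
#' evaluated at the centre point; at the series edges the cubic is fitted to
#' the terminal 7 points and evaluated at the edge positions, so polynomials
#' of degree <= 3 are reproduced exactly everywhere. Series shorter than the
#' filter length pass through unchanged. Missing windows must be removed by
#' the caller beforehand (the filter operates on present-window order).
#'
#' @param z numeric series (one chromosome, ordered by window index, no NA)
#' @param p polynomial order (default 3)
#' @param n filter length (default 7, odd)
#' @return smoothed series of the same length
#' @export
smooth_zfst <- function(z, p = 3, n = 7) {
  if (anyNA(z)) stop("remove missing windows before smoothing")
  if (length(z) < n) return(z)
  as.vector(signal::sgolayfilt(z, p = p, n = n))
}

#' Call differentiation peaks from smoothed ZFST
#'
#' Windows whose smoothed ZFST exceeds `z_threshold` (two standard deviations
#' above the chromosome mean, on the per-chromosome standardized scale) are
#' merged into maximal runs of consecutive present windows; each run becomes
#' one peak spanning the first to the last window.
#'
#' @param windows data.table with chrom, start, end and a smoothed-Z column
#' @param zcol name of the smoothed Z column (default "zfst_smooth")
#' @param z_threshold threshold (default 2)
#' @return data.table of peaks: chrom, start, end, n_windows, max_z
#' @export
call_fst_peaks <- function(windows, zcol = "zfst_smooth", z_threshold = 2) {
  wt <- as.data.table(windows)[!is.na(get(zcol))]
  setorder(wt, chrom, start)
  out <- wt[, {
    zz <- get(zcol)
    above <- zz > z_threshold
    if (!any(above)) {
      data.table(start = numeric(), end = numeric(),
                 n_windows = integer(), max_z = numeric())
    } else {
      r <- rle(above)
      hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
      keep <- r$values
      data.table(start = start[lo[keep]], end = end[hi[keep]],
                 n_windows = r$lengths[keep],
                 max_z = vapply(which(keep), function(j) {
                   max(zz[lo[j]:hi[j]])
                 }, 0))
    }
  }, by = chrom]
  out[]
}

#' Classify peaks from two species comparisons as shared or unique
#'
#' A peak is shared iff it overlaps (by at least 1 bp) any peak of the other
#' comparison; otherwise it is unique to its own comparison.
#'
#' @param peaks1,peaks2 peak tables (chrom, start, end) from the two
#'   species comparisons
#' @param labels labels for comparison-specific peaks, default
#'   c("A_unique", "B_unique")
#' @return list of the two tables with a `label` column
#'   (shared / A_unique / B_unique) added
#' @export
classify_peaks <- function(peaks1, peaks2, labels = c("A_unique", "B_unique")) {
  p1 <- as.data.table(peaks1); p2 <- as.data.table(peaks2)
  overlaps_any <- function(p, q) {
    if (nrow(p) == 0) return(logical(0))
    if (nrow(q) == 0) return(rep(FALSE, nrow(p)))
    vapply(seq_len(nrow(p)), function(j) {
      any(q$chrom == p$chrom[j] & q$start < p$end[j] & q$end > p$start[j])
    }, TRUE)
  }
  p1[, label := ifelse(overlaps_any(p1, p2), "shared", labels[1])]
  p2[, label := ifelse(overlaps_any(p2, p1), "shared", labels[2])]
  list(peaks1 = p1[], peaks2 = p2[])
}

#' Positional enrichment of peak windows along chromosomes
#'
#' Each window's relative position is min(distance to either chromosome end)
#' divided by half the chromosome length (0 = end, 1 = centre). Windows are
#' grouped into equal relative-position bins per chromosome class
#' (macro/micro), and the observed fraction of peak windows per bin is
#' compared with the class-wide expectation under circular permutation of
#' peak labels within chromosomes; two-sided p-values use the
#' (1 + k) / (1 + N) convention. Chromosomes with fewer than 2 windows are
#' excluded.
#'
#' @param windows data.table with chrom, start, end, class (macro/micro) and
#'   a logical `peak` column
#' @param n_bins number of relative-position bins (default 4; bin 1 = ends)
#' @param n_perm number of circular permutations (default 1000)
#' @param seed RNG seed for the permutations
#' @return data.table: class, bin, n_windows, n_peaks, enrichment, p_value
#' @export
positional_peak_enrichment <- function(windows, n_bins = 4, n_perm = 1000,
                                       seed = 1) {
  wt <- as.data.table(windows)
  stopifnot(all(c("chrom", "start", "end", "class", "peak") %in% names(wt)))
  wt <- wt[, if (.N >= 2) .SD, by = chrom]
  wt[, chrlen := max(end), by = chrom]
  wt[, mid := (start + end) / 2]
  wt[, relpos := pmin(mid, chrlen - mid) / (chrlen / 2)]
  wt[, bin := pmin(floor(relpos * n_bins) + 1L, n_bins)]
  setorder(wt, chrom, start)

  obs <- wt[, .(n_windows = .N, n_peaks = sum(peak)), by = .(class, bin)]
  class_rate <- wt[, .(rate = mean(peak)), by = class]
  obs <- merge(obs, class_rate, by = "class")
  obs[, enrichment := ifelse(rate > 0, (n_peaks / n_windows) / rate, NA_real_)]
  setorder(obs, class, bin)

  ## circular permutations of the peak vector within each chromosome
  perm_counts <- with_seed(seed, {
    chroms <- split(seq_len(nrow(wt)), wt$chrom)
    reps <- matrix(0L, nrow(obs), n_perm)
    key <- paste(wt$class, wt$bin)
    okey <- paste(obs$class, obs$bin)
    for (b in seq_len(n_perm)) {
      pk <- wt$peak
      for (idx in chroms) {
        off <- sample.int(length(idx), 1L) - 1L
        pk[idx] <- pk[idx][(seq_along(idx) + off - 1L) %% length(idx) + 1L]
      }
      cnt <- vapply(split(pk, factor(key, levels = okey)), sum, 0)
      reps[, b] <- cnt
    }
    reps
  })
  obs[, p_value := vapply(seq_len(.N), function(j) {
    k_hi <- sum(perm_counts[j, ] >= n_peaks[j])
    k_lo <- sum(perm_counts[j, ] <= n_peaks[j])
    min(1, 2 * min((1 + k_hi) / (1 + n_perm), (1 + k_lo) / (1 + n_perm)))
  }, 0)]
  obs[, rate := NULL]
  obs[]
}
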