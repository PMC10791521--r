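## Aggregation of interval-based population-scaled recombination estimates
## (rho = 4*Ne*r per bp) into windows and gene spans, conversion to cM/Mb via
## a pedigree linkage map, and classification of windows/genes into
## conserved vs divergent recombination rate between two species.

#' Distance-weighted mean recombination rate per target interval
#'
#' Aggregates SNP-pair interval estimates of rho/bp into target intervals
#' (windows or gene spans), weighting each interval by the number of bp it
#' contributes inside the target, so intervals spanning a target boundary are
#' apportioned between the adjacent targets. Targets with zero overlap get
#' NA; targets covered by less than `min_coverage` of their length get NA.
#'
#' @param intervals data.table with chrom, left_pos, right_pos (bp, 0-based
#'   half-open) and rho_per_bp; must be sorted, non-overlapping per chromosome
#' @param targets data.table with chrom, start, end
#' @param min_coverage minimum covered fraction of the target (default 0.2)
#' @return data.table of targets with mean rho_per_bp and covered_bp
#' @export
window_weighted_rho <- function(intervals, targets, min_coverage = 0.2) {
  iv <- as.data.table(intervals)
  stopifnot(all(c("chrom", "left_pos", "right_pos", "rho_per_bp") %in% names(iv)))
  if (any(iv$rho_per_bp < 0)) stop("negative rho")
  check_disjoint_sorted(iv[, .(chrom, start = left_pos, end = right_pos)],
                        "rho intervals")
  tg <- as.data.table(targets)[, .(chrom, start, end)]
  tg[, idx__ := .I]
  src <- iv[, .(chrom, start = left_pos, end = right_pos, rho_per_bp)]
  setkey(src, chrom, start, end)
  ov <- foverlaps(tg, src, by.x = c("chrom", "start", "end"), nomatch = NULL)
  ov[, overlap_bp := pmin(end, i.end) - pmax(start, i.start)]
  agg <- ov[overlap_bp > 0,
            .(rho = sum(rho_per_bp * overlap_bp) / sum(overlap_bp),
              covered_bp = sum(overlap_bp)), by = idx__]
  out <- as.data.table(targets)
  out[, rho_per_bp := NA_real_]
  out[, covered_bp := 0]
  out[agg$idx__, `:=`(rho_per_bp = agg$rho, covered_bp = agg$covered_bp)]
  out[covered_bp < min_coverage * (end - start), rho_per_bp := NA_real_]
  out[]
}

#' Genome-wide effective population size from rho and a pedigree map
#'
#' Ne = mean(rho/bp) / (4 * mean(pedigree rate)), with the pedigree rate
#' converted from cM/Mb to crossover events per bp per generation
#' (1 cM/Mb = 1e-8 events/bp); both means are weighted by covered bp.
#' Intended to be applied at coarse (e.g. 5 Mb) window resolution, where the
#' correlation between LD-based and pedigree-based rates is strongest.
#'
#' @param rho_windows data.table with rho_per_bp and covered_bp per window
#' @param map_rate pedigree rate (cM/Mb) per window, aligned with rho_windows
#' @return estimated Ne (scalar)
#' @export
estimate_genomewide_ne <- function(rho_windows, map_rate) {
  rw <- as.data.table(rho_windows)
  ok <- !is.na(rw$rho_per_bp) & !is.na(map_rate)
  if (!any(ok)) stop("no window with both rho and pedigree rate")
  w <- rw$covered_bp[ok]
  mean_rho <- sum(rw$rho_per_bp[ok] * w) / sum(w)
  mean_r <- sum(map_rate[ok] * 1e-8 * w) / sum(w)
  if (mean_r <= 0) stop("mean pedigree rate is zero")
  mean_rho / (4 * mean_r)
}

#' Convert population-scaled recombination rate to cM/Mb
#'
#' r = rho / (4 * Ne) events/bp/generation; cM/Mb = r * 1e8.
#'
#' @param rho_per_bp rho (4*Ne*r) per bp
#' @param ne genome-wide effective population size (> 0)
#' @return recombination rate in cM/Mb
#' @export
convert_to_cm <- function(rho_per_bp, ne) {
  if (length(ne) != 1 || is.na(ne) || ne <= 0) stop("Ne must be positive")
  rho_per_bp / (4 * ne) * 1e8
}

#' Classify paired recombination rates as conserved or divergent
#'
#' Standardizes each species' rates to zero mean and unit variance (optionally
#' after log10 transform), runs a PCA on the two-column matrix, and labels an
#' observation conserved iff its PC2 score lies within one standard deviation
#' of the PC2 mean. Divergent observations are sub-labelled by which species'
#' standardized rate is higher. If PC2 has zero variance (identical
#' landscapes) everything is conserved.
#'
#' @param rates_a,rates_b paired rates (windows or genes); NA pairs are
#'   classified NA
#' @param log10_transform log10-transform before standardizing (default FALSE)
#' @param sd_mult width of the conserved band in PC2 standard deviations
#' @return character vector of labels: conserved, divergent_A_higher,
#'   divergent_B_higher (NA where either input is NA)
#' @export
classify_rate_conservation <- function(rates_a, rates_b,
                                       log10_transform = FALSE,
                                       sd_mult = 1) {
  stopifnot(length(rates_a) == length(rates_b))
  ok <- !is.na(rates_a) & !is.na(rates_b)
  if (sum(ok) < 3) stop("need at least 3 paired non-missing observations")
  a <- rates_a[ok]; b <- rates_b[ok]
  if (log10_transform) {
    if (any(a <= 0) || any(b <= 0)) stop("log10 transform requires positive rates")
    a <- log10(a); b <- log10(b)
  }
  za <- as.vector(scale(a)); zb <- as.vector(scale(b))
  if (sd(a) == 0) za <- rep(0, length(a))
  if (sd(b) == 0) zb <- rep(0, length(b))
  pc <- prcomp(cbind(za, zb), center = TRUE, scale. = FALSE)
  s2 <- pc$x[, 2]
  lab <- rep("conserved", length(a))
  ## PC2 variance at floating-point noise level means identical landscapes
  if (sd(s2) > 1e-9 * max(sd(pc$x[, 1]), 1e-300)) {
    div <- abs(s2 - mean(s2)) > sd_mult * sd(s2)
    lab[div & za > zb] <- "divergent_A_higher"
    lab[div & zb >= za] <- "divergent_B_higher"
  }
  out <- rep(NA_character_, length(rates_a))
  out[ok] <- lab
  out
}
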