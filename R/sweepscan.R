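## Composite likelihood ratio sweep scan against a genome-wide background SFS,
## with post-processing of significant sites into sweep regions and
## presence/absence calls per window.

#' Sweep-distorted site frequency spectrum
#'
#' Distribution of the derived-allele count in a sample of n haplotypes at a
#' site at distance d from a completed hard sweep, given the per-lineage
#' escape probability p_e = 1 - exp(-alpha * d). Each of the n sampled
#' lineages escapes the sweep independently with probability p_e; the
#' escapees are a hypergeometric subsample of a pre-sweep background sample,
#' while all non-escapees inherit the allelic type of one additional
#' background draw (the sweeping haplotype). With p_e = 1 the background is
#' returned unchanged; with p_e = 0 the sample is monomorphic (all-ancestral
#' or all-derived).
#'
#' @param background background SFS over derived copies 0..n (counts or
#'   probabilities; normalized internally)
#' @param p_e per-lineage escape probability in [0, 1]
#' @param n sample size in haplotypes (>= 2)
#' @return probability vector q over derived copies 0..n (sums to 1)
#' @export
sweep_site_spectrum <- function(background, p_e, n) {
  if (length(p_e) != 1 || is.na(p_e) || p_e < 0 || p_e > 1) {
    stop("p_e must be a single value in [0, 1]")
  }
  stopifnot(n >= 2, length(background) == n + 1)
  p <- as.numeric(background)
  if (any(p < 0) || sum(p) <= 0) stop("invalid background spectrum")
  p <- p / sum(p)
  q <- numeric(n + 1L)
  pe_binom <- dbinom(0:n, n, p_e)
  ## e = n escapees: the full pre-sweep configuration is retained
  q <- q + pe_binom[n + 1L] * p
  for (e in 0:(n - 1L)) {
    if (pe_binom[e + 1L] < 1e-15) next
    h <- 0:e
    for (k in 0:n) {
      if (p[k + 1L] < 1e-300) next
      ## subsample e+1 of n lineages (e escapees + the sweeping haplotype);
      ## h = derived among escapees, t = type of the sweeping haplotype
      pr1 <- dhyper(h + 1L, k, n - k, e + 1L) * (h + 1L) / (e + 1L)
      pr0 <- dhyper(h, k, n - k, e + 1L) * (e + 1L - h) / (e + 1L)
      w <- pe_binom[e + 1L] * p[k + 1L]
      ## t = 1: all n-e non-escapees are derived
      j1 <- h + (n - e)
      q[j1 + 1L] <- q[j1 + 1L] + w * pr1
      q[h + 1L] <- q[h + 1L] + w * pr0
    }
  }
  q / sum(q)
}

## grid of escape probabilities used to tabulate q for interpolation
pe_grid_default <- function() {
  sort(unique(c(
    exp(seq(log(1e-6), log(0.99), length.out = 40)),
    1 - exp(seq(log(0.05), log(1e-6), length.out = 12)), 1
  )))
}

## Q matrix: rows = pe grid, cols = derived copies 0..n
sweep_q_table <- function(background, n, pe_grid = pe_grid_default()) {
  Q <- t(vapply(pe_grid, function(pe) sweep_site_spectrum(background, pe, n),
                numeric(n + 1L)))
  list(pe = pe_grid, Q = Q)
}

#' Composite likelihood ratio scan for selective sweeps
#'
#' For every polarized variant position (the test grid), contrasts the
#' composite likelihood of the flanking variants' derived-allele counts under
#' a hard-sweep model at sweep intensity alpha against the background-only
#' composite likelihood. The sweep model distorts the background SFS through
#' the per-lineage escape probability p_e = 1 - exp(-alpha * d) at distance d
#' (see [sweep_site_spectrum()]). alpha is maximized on a log-spaced grid of
#' 25 values spanning p_e in [1e-4, 0.9999] at the median inter-variant
#' distance, followed by golden-section refinement. The likelihood conditions
#' on the observed site classes (derived copies 1..n), and the statistic is
#' Lambda = 2 * (log CL(alpha_hat) - log CL0), floored at 0 because the
#' background model is included as a candidate.
#'
#' Variants at distances where p_e >= 0.999 contribute essentially nothing
#' and are skipped; the flanking horizon is additionally capped at
#' `max_flank_bp` for tractability.
#'
#' @param pos variant positions (bp, one chromosome), sorted or sortable
#' @param count derived-allele counts per variant (1..n)
#' @param n haplotype sample size
#' @param background background SFS over derived copies 0..n (typically
#'   genome-wide, from [build_sfs()]; bin 0 may hold invariant sites)
#' @param n_alpha number of alpha grid values (default 25)
#' @param max_flank_bp cap on the flanking horizon per side (default 200 kb)
#' @param refine logden golden-section refinement of alpha (default TRUE)
#' @return data.table with position, Lambda and alpha_hat per grid site
#' @export
clr_scan <- function(pos, count, n, background, n_alpha = 25L,
                     max_flank_bp = 2e5, refine = TRUE) {
  if (length(pos) == 0) stop("empty variant set")
  stopifnot(length(pos) == length(count), all(count >= 1), all(count <= n))
  o <- order(pos)
  pos <- as.numeric(pos[o]); count <- as.integer(count[o])
  nv <- length(pos)
  qt <- sweep_q_table(background, n)
  peg <- qt$pe; Q <- qt$Q
  ## condition on observable classes 1..n
  keep <- 2:(n + 1L)
  p_bg <- as.numeric(background) / sum(background)
  lb <- log(p_bg[count + 1L] / sum(p_bg[keep]))
  cum_lb <- c(0, cumsum(lb))
  normQ <- rowSums(Q[, keep, drop = FALSE])
  lognormQ <- log(normQ)
  logQ <- log(pmax(Q, 1e-300))

  if (nv == 1) {
    return(data.table(pos = pos, Lambda = 0, alpha_hat = NA_real_))
  }
  d_med <- max(1, median(diff(pos)))
  pe_targets <- exp(seq(log(1e-4), log(0.9999), length.out = n_alpha))
  alphas <- -log(1 - pe_targets) / d_med

  loglik_at <- function(s, alpha) {
    horizon <- min(max_flank_bp, 6.9078 / alpha)  # p_e >= 0.999 beyond this
    lo <- findInterval(pos[s] - horizon, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos[s] + horizon, pos)
    idx <- lo:hi
    pe <- -expm1(-alpha * abs(pos[idx] - pos[s]))
    pe <- pmin(pmax(pe, peg[1]), 1)
    gi <- findInterval(pe, peg, rightmost.closed = TRUE)
    gi <- pmin(gi, length(peg) - 1L)
    w <- (pe - peg[gi]) / (peg[gi + 1L] - peg[gi])
    ci <- count[idx] + 1L
    lq <- (1 - w) * logQ[cbind(gi, ci)] + w * logQ[cbind(gi + 1L, ci)]
    ln <- (1 - w) * lognormQ[gi] + w * lognormQ[gi + 1L]
    sum(lq - ln) - (cum_lb[hi + 1L] - cum_lb[lo])
  }

  Lambda <- numeric(nv)
  alpha_hat <- rep(NA_real_, nv)
  la <- log(alphas)
  for (s in seq_len(nv)) {
    ll <- vapply(alphas, function(a) loglik_at(s, a), 0)
    b <- which.max(ll)
    best_ll <- ll[b]; best_a <- alphas[b]
    if (refine && best_ll > 0) {
      lo <- la[max(1L, b - 1L)]; hi <- la[min(n_alpha, b + 1L)]
      gr <- (sqrt(5) - 1) / 2
      x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
      f1 <- loglik_at(s, exp(x1)); f2 <- loglik_at(s, exp(x2))
      for (it in 1:12) {
        if (f1 < f2) {
          lo <- x1; x1 <- x2; f1 <- f2
          x2 <- lo + gr * (hi - lo); f2 <- loglik_at(s, exp(x2))
        } else {
          hi <- x2; x2 <- x1; f2 <- f1
          x1 <- hi - gr * (hi - lo); f1 <- loglik_at(s, exp(x1))
        }
      }
      if (max(f1, f2) > best_ll) {
        best_ll <- max(f1, f2)
        best_a <- exp(if (f1 > f2) x1 else x2)
      }
    }
    Lambda[s] <- 2 * max(0, best_ll)
    alpha_hat[s] <- if (best_ll > 0) best_a else NA_real_
  }
  data.table(pos = pos, Lambda = Lambda, alpha_hat = alpha_hat)
}

#' Merge significant CLR sites into sweep regions
#'
#' Maximal runs of consecutive significant grid sites become candidate
#' regions spanning the first to last significant site. Regions with fewer
#' than two significant sites, or with a significant-site density below one
#' per kb, are discarded.
#'
#' @param scan data.table from [clr_scan()] (pos, Lambda)
#' @param threshold CLR significance threshold (> 0); the default 46.25 is
#'   the background-selection-aware value used for this study system
#' @return data.table of regions: start, end (bp, inclusive of end site),
#'   n_sites, density_per_kb, max_Lambda
#' @export
merge_significant_sites <- function(scan, threshold = 46.25) {
  stopifnot(threshold > 0)
  scan <- as.data.table(scan)
  sig <- scan[Lambda >= threshold][order(pos)]
  if (nrow(sig) == 0) {
    return(data.table(start = numeric(), end = numeric(),
                      n_sites = integer(), density_per_kb = numeric(),
                      max_Lambda = numeric()))
  }
  ## runs of consecutive significant sites on the full grid ordering
  scan <- scan[order(pos)]
  is_sig <- scan$Lambda >= threshold
  r <- rle(is_sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.table(
    start = scan$pos[starts[r$values]],
    end = scan$pos[ends[r$values]],
    n_sites = r$lengths[r$values]
  )
  out[, max_Lambda := vapply(seq_len(.N), function(j) {
    max(scan$Lambda[scan$pos >= start[j] & scan$pos <= end[j]])
  }, 0)]
  out[, density_per_kb := n_sites / pmax((end - start) / 1000, 1e-9)]
  out <- out[n_sites >= 2L & density_per_kb >= 1]
  out[]
}

#' Flag windows overlapping sweep regions
#'
#' A window is flagged as containing a sweep iff it overlaps at least one
#' merged sweep region by at least 1 bp.
#'
#' @param regions data.table with start, end (bp) on one chromosome, or with a
#'   chrom column matching the windows
#' @param windows data.table with chrom, start, end
#' @return logical vector, one element per window row
#' @export
sweep_window_presence <- function(regions, windows) {
  windows <- as.data.table(windows)
  regions <- as.data.table(regions)
  if (nrow(regions) == 0) return(rep(FALSE, nrow(windows)))
  if (!"chrom" %in% names(regions)) regions[, chrom := windows$chrom[1]]
  present <- rep(FALSE, nrow(windows))
  for (j in seq_len(nrow(regions))) {
    hit <- windows$chrom == regions$chrom[j] &
      windows$start <= regions$end[j] & windows$end > regions$start[j]
    present <- present | hit
  }
  present
}
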