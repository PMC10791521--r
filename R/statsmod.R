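## Correlation, logistic-regression and permutation machinery behind the
## summary grids comparing selection signatures with recombination rate.

#' Correlation with two-sided p-value
#'
#' Thin wrapper around `cor.test` for Pearson (product-moment) or Spearman
#' (rank) correlation on paired non-missing values.
#'
#' @param x,y paired numeric vectors
#' @param method "pearson" or "spearman"
#' @return list with estimate R, p_value, n
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 paired non-missing values")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) stop("zero variance in x or y")
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method,
                                  exact = FALSE))
  list(R = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Logistic regression of sweep presence on recombination rate
#'
#' Univariate logistic fit (IRLS via `glm`) of a binary per-window outcome
#' (e.g. sweep presence) on a per-window rate; reports the slope, its Wald
#' p-value and McFadden's pseudo-R-squared. Complete separation raises an
#' error advising a penalized refit.
#'
#' @param presence logical/0-1 outcome per window
#' @param rate numeric predictor per window
#' @return object of class `logistic_fit`: slope, intercept, p_value,
#'   mcfadden_r2, converged, n
#' @export
logistic_sweep_model <- function(presence, rate) {
  ok <- !is.na(presence) & !is.na(rate)
  y <- as.integer(presence[ok]); x <- rate[ok]
  if (length(unique(y)) < 2) {
    stop("need windows in both outcome classes (all present or all absent)")
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  mu <- fitted(fit)
  if (!fit$converged || any(mu > 1 - 1e-10) || any(mu < 1e-10)) {
    if (max(abs(coef(fit))) > 15) {
      stop("complete (or quasi-complete) separation detected; ",
           "consider a penalized (ridge) refit")
    }
  }
  null_fit <- glm(y ~ 1, family = binomial())
  r2 <- 1 - as.numeric(logLik(fit)) / as.numeric(logLik(null_fit))
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = sm["x", "Pr(>|z|)"],
                 mcfadden_r2 = r2, converged = fit$converged,
                 n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: slope = %.4g (p = %.3g), McFadden R2 = %.3f, n = %d\n",
              x$slope, x$p_value, x$mcfadden_r2, x$n))
  invisible(x)
}

#' Permutation test for a difference between two groups
#'
#' Two-sided permutation test of the caller-supplied statistic (default:
#' difference in group means, group 1 minus group 2) with uniformly
#' reshuffled labels; p = (1 + k) / (1 + N) where k counts permutations at
#' least as extreme in absolute value.
#'
#' @param values numeric vector
#' @param labels two-level grouping (factor/character/logical)
#' @param n_perm number of permutations (default 1000)
#' @param statistic function(values, labels) -> scalar; default mean
#'   difference
#' @param seed RNG seed
#' @return object of class `perm_test`: observed, p_value, n_perm, n_extreme
#' @export
permutation_diff_test <- function(values, labels, n_perm = 1000,
                                  statistic = NULL, seed = 1) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  lv <- unique(labels)
  if (length(lv) < 2) stop("need at least 2 label levels")
  if (any(tabulate(factor(labels, levels = lv)) == 0)) {
    stop("a group has zero members")
  }
  stat <- statistic %||%
    function(v, l) mean(v[l == lv[1]]) - mean(v[l == lv[2]])
  obs <- stat(values, labels)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) stat(values, sample(labels)), 0)
  })
  k <- sum(abs(perm) >= abs(obs) - 1e-12)
  structure(list(observed = obs, p_value = (1 + k) / (1 + n_perm),
                 n_perm = n_perm, n_extreme = k),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4g, p = %.4g (N = %d)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Summary of direct-selection measures by differentiation-peak category
#'
#' For gene categories defined by overlap with differentiation peaks
#' (outside peaks = background, shared peaks, focal-lineage-specific peaks,
#' peaks with / without a sweep signature), reports piN/piS (ratio of mean
#' per-gene diversities), dN/dS (mean dN over mean dS), the mean scaled
#' selection strength and omega_a from a per-category DFE fit, the gene
#' count, and a permutation p-value against the outside-peaks background for
#' the diversity and divergence ratios. A category with zero genes is
#' reported as a missing row, not dropped.
#'
#' @param genes data.table with one row per gene: pi_n, pi_s, dn, ds,
#'   exon_len, and a list-column-free `category` assignment is NOT expected;
#'   instead pass `categories`, a named list of logical vectors over genes
#' @param categories named list of logical vectors (gene in category);
#'   must contain "outside_peaks" as the background reference
#' @param variants optional per-gene variant table (columns gene_id, class
#'   "fourfold"/"zerofold", count) to support per-category DFE fits
#' @param n haplotype sample size (required with `variants`)
#' @param n_perm permutations for the p-values (default 1000)
#' @param fit_dfe_categories also fit a DFE and omega_a per category
#'   (requires `variants`; default TRUE when variants are given)
#' @param seed RNG seed for permutations
#' @return data.table, one row per category
#' @export
peak_category_table <- function(genes, categories, variants = NULL, n = NULL,
                                n_perm = 1000,
                                fit_dfe_categories = !is.null(variants),
                                seed = 1) {
  g <- as.data.table(genes)
  if (!"outside_peaks" %in% names(categories)) {
    stop("categories must include an 'outside_peaks' background")
  }
  bg <- categories$outside_peaks
  rows <- lapply(names(categories), function(cat) {
    sel <- categories[[cat]]
    if (sum(sel) == 0) {
      return(data.table(category = cat, n_genes = 0L, pin_pis = NA_real_,
                        dnds = NA_real_, mean_nes = NA_real_,
                        omega_a = NA_real_, p_pin_pis = NA_real_,
                        p_dnds = NA_real_))
    }
    gs <- g[sel]
    pin_pis <- if (mean(gs$pi_s, na.rm = TRUE) > 0) {
      mean(gs$pi_n, na.rm = TRUE) / mean(gs$pi_s, na.rm = TRUE)
    } else NA_real_
    agg <- try(aggregate_dnds(gs), silent = TRUE)
    dnds <- if (inherits(agg, "try-error")) NA_real_ else agg$dnds
    mean_nes <- omega_a <- NA_real_
    if (isTRUE(fit_dfe_categories) && !is.null(variants) && !is.null(n)) {
      v <- as.data.table(variants)[gene_id %in% which(sel)]
      sfs_n <- tabulate(v[class == "fourfold", count], nbins = n - 1L)
      sfs_s <- tabulate(v[class == "zerofold", count], nbins = n - 1L)
      if (sum(sfs_n) > 50 && sum(sfs_s) > 50 && !is.na(dnds)) {
        ft <- try(fit_dfe(sfs_n, sfs_s, n), silent = TRUE)
        if (!inherits(ft, "try-error")) {
          mean_nes <- ft$mean
          omega_a <- adaptive_rate(ft, dnds)$omega_a
        }
      }
    }
    ## permutation p vs background (categories other than the background)
    p_pp <- p_dd <- NA_real_
    if (cat != "outside_peaks" && sum(bg & !sel) > 0) {
      pool <- which((bg & !sel) | sel)
      lab <- ifelse(sel[pool], "cat", "bg")
      pp <- try(permutation_diff_test(
        g$pi_n[pool], lab, n_perm = n_perm, seed = seed,
        statistic = function(v, l) {
          ratio <- function(m) {
            ps <- mean(g$pi_s[pool][m], na.rm = TRUE)
            if (is.na(ps) || ps <= 0) return(NA_real_)
            mean(g$pi_n[pool][m], na.rm = TRUE) / ps
          }
          ratio(l == "cat") - ratio(l == "bg")
        }), silent = TRUE)
      if (!inherits(pp, "try-error")) p_pp <- pp$p_value
      dd <- try(permutation_diff_test(
        g$dn[pool], lab, n_perm = n_perm, seed = seed + 1,
        statistic = function(v, l) {
          ratio <- function(m) {
            ds <- mean(g$ds[pool][m], na.rm = TRUE)
            if (is.na(ds) || ds <= 0) return(NA_real_)
            mean(g$dn[pool][m], na.rm = TRUE) / ds
          }
          ratio(l == "cat") - ratio(l == "bg")
        }), silent = TRUE)
      if (!inherits(dd, "try-error")) p_dd <- dd$p_value
    }
    data.table(category = cat, n_genes = sum(sel), pin_pis = pin_pis,
               dnds = dnds, mean_nes = mean_nes, omega_a = omega_a,
               p_pin_pis = p_pp, p_dnds = p_dd)
  })
  rbindlist(rows)
}
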