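## Poisson random field machinery: expected site frequency spectra under
## selection or gBGC, gamma-DFE fits with demographic nuisance parameters,
## adaptive substitution rates, and gBGC strength contrasts.

## Composite Gauss-Legendre nodes on (0,1), geometrically refined near both
## endpoints so that strongly selected integrands (mass at scale 1/|gamma|
## near x = 0) are resolved for |gamma| up to ~1e5.
prf_quadrature <- function(nodes_per_seg = 16L) {
  breaks <- c(0, 10^seq(-6, -1), 0.3, 0.5, 0.7, 0.9,
              1 - 10^seq(-2, -6), 1)
  breaks <- sort(unique(breaks))
  xs <- ws <- vector("list", length(breaks) - 1L)
  for (i in seq_len(length(breaks) - 1L)) {
    gl <- pracma::gaussLegendre(nodes_per_seg, breaks[i], breaks[i + 1L])
    xs[[i]] <- gl$x
    ws[[i]] <- gl$w
  }
  list(x = unlist(xs), w = unlist(ws))
}

.prf_env <- new.env(parent = emptyenv())

prf_nodes <- function() {
  if (is.null(.prf_env$quad)) .prf_env$quad <- prf_quadrature()
  .prf_env$quad
}

## Sojourn-time density factor H(x; gamma) of the PRF model, relative
## to theta: H(x;0) = 1/x;
## H(x;gamma) = (1 - exp(-gamma (1-x))) / (x (1-x) (1 - exp(-gamma))).
## Numerically stable for gamma in [-1e6, 700].
prf_h <- function(x, gamma) {
  if (abs(gamma) < 1e-9) return(1 / x)
  if (gamma < 0) {
    a <- -gamma
    ## ratio = exp(-a x) (1 - e^{-a(1-x)}) / (1 - e^{-a})
    ratio <- exp(-a * x) * (-expm1(-a * (1 - x))) / (-expm1(-a))
  } else {
    ratio <- (-expm1(-gamma * (1 - x))) / (-expm1(-gamma))
  }
  ratio / (x * (1 - x))
}

## Binomial sampling kernel matrix: rows i = 1..n-1, cols = quadrature nodes,
## entries C(n,i) x^i (1-x)^(n-i) * w
prf_kernel <- function(n, quad = prf_nodes()) {
  key <- paste0("kern_", n)
  if (!is.null(.prf_env[[key]])) return(.prf_env[[key]])
  i <- seq_len(n - 1L)
  lx <- log(quad$x)
  l1x <- log1p(-quad$x)
  K <- exp(outer(i, lx) + outer(n - i, l1x) + lchoose(n, i)) *
    rep(quad$w, each = n - 1L)
  .prf_env[[key]] <- K
  K
}

#' Expected site frequency spectrum under the Poisson random field model
#'
#' Expected number of sites with derived-allele count i (i = 1..n-1) in a
#' sample of n haplotypes, for mutations entering at rate theta with scaled
#' selection (or conversion bias) coefficient gamma = 4*Ne*s, optionally
#' modulated by per-frequency demographic nuisance factors r_i:
#' E[count_i] = theta * r_i * int C(n,i) x^i (1-x)^(n-i) H(x;gamma) dx,
#' where H(x;gamma) = (1-exp(-gamma(1-x))) / (x(1-x)(1-exp(-gamma))) and
#' H(x;0) = 1/x, so that the neutral expectation is theta * r_i / i.
#'
#' @param n sample size in haplotypes (>= 2)
#' @param gamma scaled coefficient 4*Ne*s (negative = deleterious,
#'   positive = favoured, 0 = neutral)
#' @param theta mutation-scale parameter (expected density of new mutations)
#' @param r per-frequency nuisance factors, length n-1 (default all 1)
#' @return numeric vector of expected counts for derived copies 1..n-1
#' @export
expected_selected_sfs <- function(n, gamma, theta = 1, r = rep(1, n - 1L)) {
  stopifnot(n >= 2, length(r) == n - 1L, all(r > 0), theta >= 0)
  if (!is.finite(gamma)) stop("gamma must be finite")
  quad <- prf_nodes()
  K <- prf_kernel(n, quad)
  ## K already contains the quadrature weights
  base <- as.vector(K %*% prf_h(quad$x, gamma))
  theta * r * base
}

## matrix of base integrals over a fixed gamma grid (columns), i = 1..n-1 rows
expected_sfs_grid <- function(n, gammas) {
  quad <- prf_nodes()
  K <- prf_kernel(n, quad)
  vapply(gammas, function(g) as.vector(K %*% prf_h(quad$x, g)),
         numeric(n - 1L))
}

## --- gamma DFE discretization -----------------------------------------------

## grid of deleterious magnitudes g = -gamma, log-spaced, with endpoint masses
dfe_grid <- function(n_support = 200L, g_min = 1e-4, g_max = 1e5) {
  g <- exp(seq(log(g_min), log(g_max), length.out = n_support))
  g
}

## integration weights for E_phi[f(g)] with g ~ Gamma(shape, mean), computed
## by trapezoid on the log grid plus the two tail masses assigned to the
## boundary points
dfe_weights <- function(g, shape, mean) {
  scale <- mean / shape
  dens <- dgamma(g, shape = shape, scale = scale)
  lg <- log(g)
  dl <- diff(lg)
  w <- numeric(length(g))
  w[-1] <- w[-1] + dl / 2
  w[-length(g)] <- w[-length(g)] + dl / 2
  w <- dens * g * w  # f(g) dg = f(g) g dlog(g)
  w[1] <- w[1] + pgamma(g[1], shape = shape, scale = scale)
  w[length(g)] <- w[length(g)] +
    pgamma(g[length(g)], shape = shape, scale = scale, lower.tail = FALSE)
  w
}

.dfe_cache <- new.env(parent = emptyenv())

## Imat[i, k]: PRF base integral at gamma = -g_grid[k], cached per n
dfe_imat <- function(n, g_grid) {
  key <- paste0("imat_", n, "_", length(g_grid))
  if (is.null(.dfe_cache[[key]])) {
    .dfe_cache[[key]] <- expected_sfs_grid(n, -g_grid)
  }
  .dfe_cache[[key]]
}

#' Fit a gamma distribution of fitness effects from neutral and selected SFS
#'
#' Maximizes a Poisson likelihood over the mutation scale of the selected
#' class, the gamma-DFE mean and shape of deleterious effects
#' (gamma = 4*Ne*s <= 0), with per-frequency nuisance factors r_i shared
#' between the neutral and selected class to absorb demography and
#' polarization artefacts. The r_i are profiled analytically at each step:
#' r_i = (neutral_i + selected_i) / (1/i + theta_s * S_i), with the neutral
#' mutation scale absorbed into r. The DFE is discretized on a log-spaced
#' grid of >= 200 support points spanning nearly-neutral to lethal.
#'
#' @param sfs_neutral observed neutral (e.g. fourfold) SFS counts, bins 1..n-1
#' @param sfs_selected observed selected (e.g. zerofold) SFS counts, bins 1..n-1
#' @param n sample size in haplotypes
#' @param n_support DFE support points (>= 200 by default)
#' @param start optional named start values (mean, shape on the 4*Ne*s scale)
#' @return object of class `dfe_fit`: mean (E[-gamma], 4*Ne*s scale), shape,
#'   theta ratio, nuisance factors r, log-likelihood, convergence info and SEs
#' @export
fit_dfe <- function(sfs_neutral, sfs_selected, n,
                    n_support = 200L, start = NULL) {
  stopifnot(length(sfs_neutral) == n - 1L, length(sfs_selected) == n - 1L)
  if (sum(sfs_neutral) == 0 || sum(sfs_selected) == 0) {
    stop("empty SFS: both neutral and selected classes need observed variants")
  }
  on <- as.numeric(sfs_neutral)
  os <- as.numeric(sfs_selected)
  i <- seq_len(n - 1L)
  g_grid <- dfe_grid(n_support)
  Imat <- dfe_imat(n, g_grid)
  neut <- 1 / i

  sel_sfs <- function(mean, shape) {
    as.vector(Imat %*% dfe_weights(g_grid, shape, mean))
  }
  negll <- function(par) {
    th_s <- exp(par[1]); m <- exp(par[2]); b <- exp(par[3])
    S <- sel_sfs(m, b)
    denom <- neut + th_s * S
    r <- (on + os) / denom
    r[r <= 0 | !is.finite(r)] <- 1e-12
    mu_n <- r * neut
    mu_s <- th_s * r * S
    ll <- sum(on * log(pmax(mu_n, 1e-300)) - mu_n) +
      sum(os * log(pmax(mu_s, 1e-300)) - mu_s)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  p0 <- c(log(sum(os) / sum(on)),
          log(start$mean %||% 100), log(start$shape %||% 0.5))
  fit <- nlminb(p0, negll,
                lower = c(-10, log(1e-3), log(0.02)),
                upper = c(10, log(1e6), log(20)))
  if (fit$convergence != 0 && !grepl("relative convergence|both X|singular",
                                     fit$message %||% "", ignore.case = TRUE)) {
    warning("DFE fit optimizer message: ", fit$message)
  }
  th_s <- exp(fit$par[1]); m <- exp(fit$par[2]); b <- exp(fit$par[3])
  S <- sel_sfs(m, b)
  r <- (on + os) / (neut + th_s * S)
  ## report r on a scale where its weighted geometric mean is 1 (theta_n
  ## absorbs the level); near-flat r means no demographic distortion
  theta_n <- exp(weighted.mean(log(pmax(r, 1e-300)), w = on + os + 1e-9))
  se <- rep(NA_real_, 3)
  H <- try(optimHess(fit$par, negll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  structure(list(
    mean = m, shape = b, theta_sel = th_s, theta_neutral = theta_n,
    r = r / theta_n, loglik = -fit$objective,
    se_log = setNames(se, c("log_theta_sel", "log_mean", "log_shape")),
    convergence = fit$convergence, message = fit$message, n = n,
    scale = "gamma = 4*Ne*s; mean reported as E[-gamma]"
  ), class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat("Gamma DFE fit (deleterious effects, 4*Ne*s scale)\n")
  cat(sprintf("  mean E[-gamma] = %.4g, shape = %.4g\n", x$mean, x$shape))
  cat(sprintf("  theta_sel/theta_neutral = %.4g, logLik = %.2f\n",
              x$theta_sel, x$loglik))
  invisible(x)
}

#' Relative fixation rate of a mutation with scaled coefficient gamma
#'
#' F(gamma) = gamma / (1 - exp(-gamma)) with F(0) = 1, the fixation
#' probability relative to a neutral mutation under semidominance.
#'
#' @param gamma scaled coefficient 4*Ne*s
#' @return numeric vector of relative fixation rates
#' @export
fixation_rate <- function(gamma) {
  out <- ifelse(abs(gamma) < 1e-8, 1, gamma / (-expm1(-gamma)))
  out
}

#' Adaptive substitution rate from a fitted DFE and observed dN/dS
#'
#' Decomposes omega = dN/dS into the expected contribution of deleterious
#' mutations omega_na = E_DFE[F(gamma)], where F(gamma) = gamma/(1-e^-gamma)
#' is the relative fixation rate, and the adaptive remainder
#' omega_a = omega - omega_na; omega_a may be negative. Also reports the
#' adaptive proportion alpha = omega_a / omega.
#'
#' @param fit a `dfe_fit` object
#' @param dnds observed dN/dS on the focal branch (GC-conservative recommended)
#' @return list with omega, omega_na, omega_a, alpha
#' @export
adaptive_rate <- function(fit, dnds) {
  if (is.null(dnds) || is.na(dnds)) stop("dN/dS input (omega) is missing")
  g <- dfe_grid()
  w <- dfe_weights(g, fit$shape, fit$mean)
  omega_na <- sum(w * fixation_rate(-g))
  list(omega = dnds, omega_na = omega_na,
       omega_a = dnds - omega_na, alpha = (dnds - omega_na) / dnds)
}

## --- gBGC -------------------------------------------------------------------

#' Fit the population-scaled strength of GC-biased gene conversion
#'
#' Fits a single coefficient B = 4*Ne*b by a joint Poisson random field
#' likelihood over the weak-to-strong (WS, gamma = +B), strong-to-weak
#' (SW, gamma = -B), and GC-conservative (gamma = 0) derived-allele
#' spectra of one species and region class. Per-frequency nuisance factors
#' r_i are shared across the three classes and anchored by the
#' GC-conservative (neutral reference) class.
#'
#' @param sfs_ws WS SFS counts, bins 1..n-1
#' @param sfs_sw SW SFS counts, bins 1..n-1
#' @param sfs_cons GC-conservative SFS counts, bins 1..n-1
#' @param n haplotype sample size
#' @return object of class `gbgc_fit` with B, SE(B), class thetas, r, logLik
#' @export
fit_gbgc <- function(sfs_ws, sfs_sw, sfs_cons, n) {
  stopifnot(length(sfs_ws) == n - 1L, length(sfs_sw) == n - 1L,
            length(sfs_cons) == n - 1L)
  if (sum(sfs_ws) == 0 || sum(sfs_sw) == 0) {
    stop("empty WS or SW class: cannot fit gBGC strength")
  }
  if (sum(sfs_cons) == 0) {
    stop("no GC-conservative variants: a neutral reference SFS is required")
  }
  ow <- as.numeric(sfs_ws); osw <- as.numeric(sfs_sw); oc <- as.numeric(sfs_cons)
  i <- seq_len(n - 1L)
  neut <- 1 / i
  negll <- function(par) {
    B <- par[1]; th_w <- exp(par[2]); th_s <- exp(par[3])
    Iw <- expected_selected_sfs(n, B)
    Is <- expected_selected_sfs(n, -B)
    denom <- neut + th_w * Iw + th_s * Is
    r <- (oc + ow + osw) / denom
    mu_c <- r * neut; mu_w <- th_w * r * Iw; mu_s <- th_s * r * Is
    ll <- sum(oc * log(pmax(mu_c, 1e-300)) - mu_c) +
      sum(ow * log(pmax(mu_w, 1e-300)) - mu_w) +
      sum(osw * log(pmax(mu_s, 1e-300)) - mu_s)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  p0 <- c(0, log(sum(ow) / sum(oc)), log(sum(osw) / sum(oc)))
  fit <- nlminb(p0, negll, lower = c(-50, -10, -10), upper = c(50, 10, 10))
  se_B <- NA_real_
  H <- try(optimHess(fit$par, negll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && V[1, 1] > 0) se_B <- sqrt(V[1, 1])
  }
  structure(list(B = fit$par[1], se_B = se_B,
                 theta_ws = exp(fit$par[2]), theta_sw = exp(fit$par[3]),
                 loglik = -fit$objective, convergence = fit$convergence, n = n),
            class = "gbgc_fit")
}

#' @export
print.gbgc_fit <- function(x, ...) {
  cat(sprintf("gBGC fit: B = %.3f (SE %.3f), logLik = %.2f\n",
              x$B, x$se_B, x$loglik))
  invisible(x)
}

#' Contrast gBGC strength between species across recombination-rate classes
#'
#' Given `gbgc_fit` objects per species (A, B) and per window conservation
#' class (conserved, divergent_A_higher, divergent_B_higher), reports
#' Delta-B = B_A - B_B per class and whether the expected ordering
#' Delta-B(divergent_A_higher) > Delta-B(conserved) > Delta-B(divergent_B_higher)
#' holds, i.e. whether the species with the higher recombination rate in
#' divergent windows also shows the stronger gBGC there.
#'
#' @param fits nested list: `fits[[species]][[class]]` of `gbgc_fit` objects,
#'   species names "A" and "B", classes "conserved", "divergent_A_higher",
#'   "divergent_B_higher"
#' @return list with the contrast table (data.table) and `ordering_ok`
#' @export
gbgc_contrast <- function(fits) {
  classes <- c("conserved", "divergent_A_higher", "divergent_B_higher")
  for (sp in c("A", "B")) {
    if (is.null(fits[[sp]])) stop("missing species ", sp, " in gBGC fits")
    missing_cl <- setdiff(classes, names(fits[[sp]]))
    if (length(missing_cl)) {
      stop("missing region class(es) for species ", sp, ": ",
           paste(missing_cl, collapse = ", "))
    }
  }
  tab <- data.table(
    class = classes,
    B_A = vapply(classes, function(cl) fits$A[[cl]]$B, 0),
    B_B = vapply(classes, function(cl) fits$B[[cl]]$B, 0),
    se_A = vapply(classes, function(cl) fits$A[[cl]]$se_B, 0),
    se_B = vapply(classes, function(cl) fits$B[[cl]]$se_B, 0)
  )
  tab[, delta_B := B_A - B_B]
  d <- setNames(tab$delta_B, tab$class)
  list(table = tab[],
       ordering_ok = d["divergent_A_higher"] > d["conserved"] &&
         d["conserved"] > d["divergent_B_higher"])
}
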