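## Seeded synthetic-data generator. Emulates the joint statistical structure
## the analysis assumes: two sister-species pairs plus an outgroup;
## autocorrelated per-species recombination landscapes with a configurable
## divergent-window fraction and macro/micro positional trends; diversity and
## differentiation landscapes coupled to recombination; sweep-distorted
## spectra near implanted sweep sites; coding variation drawn from a gamma
## DFE; and focal-branch substitutions at a chosen omega. Every component is
## a pure function of the configuration (including its seed).

#' Population-scaled mutation rate theta0 = 4 * mu * L
#'
#' @param mu per-site per-generation mutation rate (>= 0)
#' @param L effective callable length in bp (> 0)
#' @return theta0 = 4 * mu * L
#' @examples
#' scaled_mutation_rate(4.6e-9, 564393274)  # 10.38
#' @export
scaled_mutation_rate <- function(mu, L) {
  if (mu < 0) stop("mu must be non-negative")
  if (L <= 0) stop("L must be positive")
  4 * mu * L
}

#' Default chromosome specification (two macro-, two microchromosomes)
#' @return data.table with name, length (bp), class
#' @export
default_chrom_spec <- function() {
  data.table(name = c("chr1", "chr2", "chr21", "chr22"),
             length = c(10e6, 7e6, 5.6e6, 4.8e6),
             class = c("macro", "macro", "micro", "micro"))
}

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic system: a small genome of
#' macro- and microchromosomes, two species pairs (focal species A and B with
#' sisters A2 and B2) plus one haploid outgroup, recombination landscapes
#' with a configurable divergent-window fraction, diversity and
#' differentiation negatively coupled to recombination, implanted sweeps and
#' differentiation peaks, and coding variation under a gamma DFE at a chosen
#' omega. theta0 = 4 * mu * L exactly.
#'
#' @param seed master seed; every downstream draw derives from it
#' @param chrom_spec chromosome table (name, length, class)
#' @param window_bp analysis window size (default 200 kb)
#' @param mu per-site per-generation mutation rate
#' @param L effective callable length in bp (defaults to 95% of the genome)
#' @param n_dip named diploid sample sizes for species A, A2, B, B2
#' @param rho_mean genome-wide mean rho/bp
#' @param ne_true true effective population size used to scale the pedigree
#'   linkage map
#' @param divergent_fraction fraction of windows with divergent recombination
#'   rate between species A and B
#' @param divergent_shift log-scale rho perturbation applied to divergent
#'   windows in one species
#' @param rho_noise_sd log-scale species-specific noise on the shared
#'   landscape
#' @param interval_noise_sd log-normal noise on SNP-pair interval estimates
#' @param map_noise_sd log-normal noise on the pedigree map windows
#' @param coupling_strength exponent coupling per-window diversity to
#'   relative recombination rate (> 0 reproduces the linked-selection
#'   signature: less diversity, more drift where recombination is low)
#' @param snp_per_bp baseline density of segregating sites per species pair
#' @param drift_f0 baseline Balding-Nichols drift intensity within a pair
#' @param peak_fst_boost multiplier on drift intensity inside implanted peaks
#' @param peak_rho_drop log-scale reduction of rho inside implanted peaks
#' @param gbgc_b0 baseline gBGC strength scaling (4*Ne*b at rho_mean)
#' @param fix_frac fraction of sites fixed derived within the pair
#' @param out_err probability that the outgroup carries the derived allele
#' @param sweep_truth data.table (chrom, pos, alpha, species) of implanted
#'   hard sweeps
#' @param peak_truth data.table (chrom, start, end, class in shared /
#'   A_unique / B_unique) of implanted differentiation peaks
#' @param dfe_truth c(mean, shape): gamma DFE of deleterious effects on the
#'   4*Ne*s scale
#' @param omega_truth true dN/dS on the focal branches
#' @param n_genes number of protein-coding genes
#' @param theta_coding per-site mutation scale for coding SFS draws
#' @param t_focal,t_out expected synonymous divergence on the focal and
#'   outgroup branches
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       chrom_spec = default_chrom_spec(),
                       window_bp = 200000L,
                       mu = 4.6e-9,
                       L = NULL,
                       n_dip = c(A = 10L, A2 = 5L, B = 10L, B2 = 5L),
                       rho_mean = 0.037,
                       ne_true = 2e5,
                       divergent_fraction = 0.24,
                       divergent_shift = 1.2,
                       rho_noise_sd = 0.12,
                       interval_noise_sd = 0.3,
                       map_noise_sd = 0.35,
                       coupling_strength = 0.6,
                       snp_per_bp = 1 / 400,
                       drift_f0 = 0.04,
                       peak_fst_boost = 12,
                       peak_rho_drop = 1.0,
                       gbgc_b0 = 1.5,
                       fix_frac = 0.04,
                       out_err = 0.02,
                       sweep_truth = NULL,
                       peak_truth = NULL,
                       dfe_truth = c(mean = 190, shape = 0.4),
                       omega_truth = 0.2,
                       n_genes = 300L,
                       theta_coding = 0.05,
                       t_focal = 0.05,
                       t_out = 0.10) {
  cs <- as.data.table(chrom_spec)
  stopifnot(all(c("name", "length", "class") %in% names(cs)))
  if (any(cs$length < window_bp)) stop("chromosome shorter than one window")
  stopifnot(window_bp > 0, divergent_fraction >= 0, divergent_fraction <= 1)
  L <- L %||% round(0.95 * sum(cs$length))
  if (is.null(sweep_truth)) {
    sweep_truth <- data.table(
      chrom = c("chr1", "chr21", "chr2"),
      pos = c(5.0e6, 0.5e6, 3.0e6),
      alpha = c(2e-5, 2e-5, 2e-5),
      species = c("A", "A", "B"))
  }
  if (is.null(peak_truth)) {
    ## differentiation islands span several hundred kb (3-4 windows); the
    ## micro-chromosome peaks sit near the chromosome ends
    peak_truth <- data.table(
      chrom = c("chr1", "chr2", "chr21", "chr22"),
      start = c(2.4e6, 1.2e6, 0.2e6, 0.2e6),
      end = c(3.2e6, 2.0e6, 0.8e6, 0.8e6),
      class = c("shared", "A_unique", "shared", "B_unique"))
  }
  sweep_truth <- as.data.table(sweep_truth)
  for (j in seq_len(nrow(sweep_truth))) {
    len <- cs$length[cs$name == sweep_truth$chrom[j]]
    if (!length(len) || sweep_truth$pos[j] < 0 || sweep_truth$pos[j] >= len) {
      stop("sweep position outside chromosome: row ", j)
    }
  }
  cfg <- list(seed = as.integer(seed), chrom_spec = cs, window_bp = window_bp,
              mu = mu, L = L, theta0 = scaled_mutation_rate(mu, L),
              n_dip = n_dip, rho_mean = rho_mean, ne_true = ne_true,
              divergent_fraction = divergent_fraction,
              divergent_shift = divergent_shift,
              rho_noise_sd = rho_noise_sd,
              interval_noise_sd = interval_noise_sd,
              map_noise_sd = map_noise_sd,
              coupling_strength = coupling_strength,
              snp_per_bp = snp_per_bp, drift_f0 = drift_f0,
              peak_fst_boost = peak_fst_boost,
              peak_rho_drop = peak_rho_drop, gbgc_b0 = gbgc_b0,
              fix_frac = fix_frac, out_err = out_err,
              sweep_truth = sweep_truth,
              peak_truth = as.data.table(peak_truth),
              dfe_truth = dfe_truth, omega_truth = omega_truth,
              n_genes = as.integer(n_genes), theta_coding = theta_coding,
              t_focal = t_focal, t_out = t_out)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, %d chromosomes (%.1f Mb), %d kb windows\n",
              x$seed, nrow(x$chrom_spec), sum(x$chrom_spec$length) / 1e6,
              x$window_bp / 1000))
  cat(sprintf("  theta0 = 4*mu*L = %.4g; rho_mean = %g; divergent fraction %g\n",
              x$theta0, x$rho_mean, x$divergent_fraction))
  cat(sprintf("  %d sweeps, %d peaks, DFE (mean %g, shape %g), omega %g\n",
              nrow(x$sweep_truth), nrow(x$peak_truth),
              x$dfe_truth[["mean"]], x$dfe_truth[["shape"]], x$omega_truth))
  invisible(x)
}

## ---------------------------------------------------------------------------

#' Generate per-species recombination landscapes, intervals and linkage map
#'
#' Simulates a shared autocorrelated log-scale landscape on the window grid
#' with a chromosome-class positional trend (macrochromosomes: rate reduced
#' towards the centre; microchromosomes: rate reduced towards the ends),
#' implants a reduced-recombination signature at the configured
#' differentiation peaks, perturbs a Bernoulli(divergent_fraction) subset of
#' windows in one species only, and expands each species' window landscape
#' into SNP-pair intervals with jittered breakpoints so that window
#' aggregation is exercised across window boundaries. The pedigree linkage
#' map is the species-B landscape divided by 4*Ne_true (in cM/Mb) with
#' log-normal window noise.
#'
#' @param cfg a [sim_config()] object
#' @return list: windows (truth table with rho_A, rho_B, divergent label),
#'   intervals_A, intervals_B (chrom, left_pos, right_pos, rho_per_bp),
#'   linkage_map (chrom, start, end, cm_mb), ne_true
#' @export
gen_recombination_landscape <- function(cfg) {
  wt <- make_windows(cfg$chrom_spec, cfg$window_bp)
  with_seed(stage_seed(cfg$seed, 1L), {
    wt[, mid := (start + end) / 2]
    wt[, chrlen := cfg$chrom_spec$length[match(chrom, cfg$chrom_spec$name)]]
    u <- abs(2 * wt$mid / wt$chrlen - 1)  # 0 at centre, 1 at ends
    trend <- ifelse(wt$class == "macro", 1.0 * (u - 0.5), 1.0 * (0.5 - u))
    ## AR(1) shared baseline per chromosome
    base <- unlist(lapply(split(seq_len(nrow(wt)), wt$chrom)[unique(wt$chrom)],
                          function(idx) {
      k <- length(idx)
      z <- numeric(k)
      z[1] <- rnorm(1, 0, 0.5)
      for (j in seq_len(k - 1L)) z[j + 1] <- 0.7 * z[j] + rnorm(1, 0, 0.35)
      z
    }))
    lr <- log(cfg$rho_mean) + trend + base
    ## reduced recombination at implanted differentiation peaks (both species)
    pk <- cfg$peak_truth
    in_peak <- rep(FALSE, nrow(wt))
    peak_class <- rep(NA_character_, nrow(wt))
    for (j in seq_len(nrow(pk))) {
      hit <- wt$chrom == pk$chrom[j] & wt$start < pk$end[j] & wt$end > pk$start[j]
      in_peak <- in_peak | hit
      peak_class[hit] <- pk$class[j]
    }
    lr[in_peak] <- lr[in_peak] - cfg$peak_rho_drop
    ## species-specific noise and divergence perturbation
    nA <- rnorm(nrow(wt), 0, cfg$rho_noise_sd)
    nB <- rnorm(nrow(wt), 0, cfg$rho_noise_sd)
    div <- runif(nrow(wt)) < cfg$divergent_fraction
    up_in_A <- runif(nrow(wt)) < 0.5
    shift <- ifelse(runif(nrow(wt)) < 0.5, cfg$divergent_shift,
                    -cfg$divergent_shift)
    lrA <- lr + nA + ifelse(div & up_in_A, shift, 0)
    lrB <- lr + nB + ifelse(div & !up_in_A, shift, 0)
    wt[, rho_A := exp(lrA)]
    wt[, rho_B := exp(lrB)]
    ## normalize the pooled mean to rho_mean
    sc <- cfg$rho_mean / mean(c(wt$rho_A, wt$rho_B))
    wt[, `:=`(rho_A = rho_A * sc, rho_B = rho_B * sc)]
    wt[, divergent_truth := div]
    wt[, divergent_label := ifelse(!div, "conserved",
                                   ifelse((up_in_A & shift > 0) | (!up_in_A & shift < 0),
                                          "divergent_A_higher", "divergent_B_higher"))]
    wt[, peak_class_truth := peak_class]
    wt[, mid := NULL]

    expand_intervals <- function(rho_col) {
      out <- lapply(unique(wt$chrom), function(ch) {
        len <- cfg$chrom_spec$length[cfg$chrom_spec$name == ch]
        ww <- wt[chrom == ch]
        ## jittered SNP-pair breakpoints, mean spacing 2 kb
        n_iv <- ceiling(len / 2000) + 10L
        gaps <- pmax(50, round(rexp(n_iv, 1 / 2000)))
        bp <- cumsum(c(0, gaps))
        bp <- unique(pmin(bp[bp <= len], len))
        if (bp[length(bp)] < len) bp <- c(bp, len)
        l <- bp[-length(bp)]; r <- bp[-1]
        ## length-weighted mean of window rho over each interval's span
        wr <- ww[[rho_col]]
        ws <- ww$start; we <- ww$end
        iw <- findInterval(l, ws)
        same <- findInterval(r - 1, ws) == iw
        rho_iv <- numeric(length(l))
        rho_iv[same] <- wr[iw[same]]
        for (j in which(!same)) {
          ov <- pmin(we, r[j]) - pmax(ws, l[j])
          ov[ov < 0] <- 0
          rho_iv[j] <- sum(wr * ov) / sum(ov)
        }
        noise <- exp(rnorm(length(l), 0, cfg$interval_noise_sd) -
                       cfg$interval_noise_sd^2 / 2)
        data.table(chrom = ch, left_pos = l, right_pos = r,
                   rho_per_bp = rho_iv * noise)
      })
      rbindlist(out)
    }
    iv_A <- expand_intervals("rho_A")
    iv_B <- expand_intervals("rho_B")
    lm_noise <- exp(rnorm(nrow(wt), 0, cfg$map_noise_sd) -
                      cfg$map_noise_sd^2 / 2)
    linkage_map <- wt[, .(chrom, start, end,
                          cm_mb = rho_B / (4 * cfg$ne_true) * 1e8 * lm_noise)]
    list(windows = wt[], intervals_A = iv_A, intervals_B = iv_B,
         linkage_map = linkage_map, ne_true = cfg$ne_true)
  })
}

## ---------------------------------------------------------------------------

## Balding-Nichols drift of an ancestral frequency
bn_drift <- function(x0, F) {
  shape <- (1 - F) / F
  rbeta(length(x0), x0 * shape, (1 - x0) * shape)
}

## realize diploid genotypes (dosage 0/1/2) with an exact derived count
geno_from_count <- function(count, n_dip) {
  hap <- integer(2 * n_dip)
  if (count > 0) hap[sample.int(2 * n_dip, count)] <- 1L
  hap[seq_len(n_dip)] + hap[n_dip + seq_len(n_dip)]
}

#' Generate the genome-wide variant dataset
#'
#' Per-window site density and within-pair drift intensity are coupled to the
#' focal species' recombination rate (diversity higher, drift lower where
#' recombination is high); implanted differentiation peaks boost drift in the
#' affected species pair(s); near each implanted sweep, derived counts of the
#' swept species are drawn from the sweep-distorted spectrum
#' ([sweep_site_spectrum()]) of the pre-sweep segregating background at the
#' truth alpha; WS/SW variant frequencies are pushed up/down in proportion to
#' the local recombination rate of each species (gBGC); genotypes are drawn
#' under random mating; the outgroup is a single haploid sequence carrying
#' the ancestral allele at most sites.
#'
#' @param cfg a [sim_config()] object
#' @param landscape result of [gen_recombination_landscape()]
#' @return list: sites (data.table with chrom, pos0, ref, alt, anc, der,
#'   mut_class, pair), geno (named list of dosage matrices for A, A2, B, B2),
#'   out_allele (character: outgroup haploid base), mask (callable BED table)
#' @export
gen_variant_data <- function(cfg, landscape) {
  wt <- landscape$windows
  n_hap <- 2L * cfg$n_dip
  with_seed(stage_seed(cfg$seed, 2L), {
    ## callable mask: chromosomes minus a few masked gaps
    mask <- rbindlist(lapply(seq_len(nrow(cfg$chrom_spec)), function(ci) {
      len <- cfg$chrom_spec$length[ci]
      n_gap <- max(1L, round(len / 2e6))
      gs <- sort(sample.int(len - 30000L, n_gap))
      gw <- round(runif(n_gap, 5000, 20000))
      ge <- pmin(gs + gw, len)
      keep_s <- c(0, ge); keep_e <- c(gs, len)
      ok <- keep_e > keep_s
      data.table(chrom = cfg$chrom_spec$name[ci],
                 start = keep_s[ok], end = keep_e[ok])
    }))

    xg <- seq(0.02, 0.98, by = 0.02)
    xw <- (1 / xg) / sum(1 / xg)

    gen_pair <- function(pair) {
      sp1 <- pair; sp2 <- paste0(pair, "2")
      rho_col <- if (pair == "A") "rho_A" else "rho_B"
      n1 <- n_hap[[sp1]]; n2 <- n_hap[[sp2]]
      pk_classes <- if (pair == "A") c("shared", "A_unique") else c("shared", "B_unique")
      sweeps <- cfg$sweep_truth[species == sp1]
      ## pre-sweep segregating background for sweep-distorted draws
      bg0 <- c(0, 1 / seq_len(n1 - 1L), 0)
      pe_bins <- seq(0.0005, 0.9995, by = 0.001)
      q_cache <- new.env(parent = emptyenv())

      rows <- vector("list", nrow(wt))
      for (w in seq_len(nrow(wt))) {
        len <- wt$end[w] - wt$start[w]
        f_w <- pmin(pmax((wt[[rho_col]][w] / cfg$rho_mean)^cfg$coupling_strength,
                         0.25), 4)
        n_sites <- rpois(1, cfg$snp_per_bp * f_w * len)
        if (n_sites == 0) next
        pos <- wt$start[w] + sort(sample.int(len, min(n_sites, len)))
        m <- length(pos)
        anc <- sample(BASES, m, replace = TRUE)
        der <- vapply(anc, function(a) sample(setdiff(BASES, a), 1), "")
        mclass <- mutation_class(anc, der)
        x0 <- sample(xg, m, replace = TRUE, prob = xw)
        fixed <- runif(m) < cfg$fix_frac
        Fd <- cfg$drift_f0 / f_w
        if (!is.na(wt$peak_class_truth[w]) &&
            wt$peak_class_truth[w] %in% pk_classes) {
          Fd <- min(Fd * cfg$peak_fst_boost, 0.7)
        }
        p1 <- bn_drift(x0, Fd)
        p2 <- bn_drift(x0, Fd)
        ## gBGC push, proportional to each species' local recombination rate
        b1 <- cfg$gbgc_b0 * wt$rho_A[w] / cfg$rho_mean
        b2 <- cfg$gbgc_b0 * wt$rho_B[w] / cfg$rho_mean
        b_pair <- if (pair == "A") b1 else b2
        sgn <- ifelse(mclass == "WS", 1, ifelse(mclass == "SW", -1, 0))
        ## bounded logit-scale tilt towards/away from the derived allele,
        ## approximating the PRF density tilt exp(gamma * x)
        tilt <- function(p, strength) {
          mid <- p > 0 & p < 1
          p[mid] <- stats::plogis(stats::qlogis(p[mid]) + strength[mid])
          p
        }
        p1 <- tilt(p1, sgn * b_pair * 0.35)
        p2 <- tilt(p2, sgn * b_pair * 0.35)
        p1[fixed] <- 1; p2[fixed] <- 1
        g1 <- t(vapply(p1, function(p) rbinom(cfg$n_dip[[sp1]], 2, p),
                       integer(cfg$n_dip[[sp1]])))
        g2 <- t(vapply(p2, function(p) rbinom(cfg$n_dip[[sp2]], 2, p),
                       integer(cfg$n_dip[[sp2]])))
        ## sweep distortion of the focal species
        if (nrow(sweeps)) {
          for (sj in seq_len(nrow(sweeps))) {
            if (sweeps$chrom[sj] != wt$chrom[w]) next
            d <- abs(pos - sweeps$pos[sj])
            pe <- -expm1(-sweeps$alpha[sj] * d)
            aff <- which(pe < 0.999)
            for (j in aff) {
              key <- as.character(findInterval(pe[j], pe_bins))
              if (is.null(q_cache[[key]])) {
                q_cache[[key]] <- sweep_site_spectrum(
                  bg0, pe_bins[max(1L, as.integer(key))], n1)
              }
              cnt <- sample.int(n1 + 1L, 1L, prob = q_cache[[key]]) - 1L
              g1[j, ] <- geno_from_count(cnt, cfg$n_dip[[sp1]])
            }
          }
        }
        rows[[w]] <- list(chrom = wt$chrom[w], pos = pos, anc = anc, der = der,
                          mclass = mclass, g1 = g1, g2 = g2)
      }
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows) == 0) {
        return(list(
          sites = data.table(chrom = character(), pos0 = integer(),
                             anc = character(), der = character(),
                             mut_class = character()),
          g1 = matrix(0L, 0, cfg$n_dip[[sp1]]),
          g2 = matrix(0L, 0, cfg$n_dip[[sp2]])))
      }
      list(
        sites = rbindlist(lapply(rows, function(r) {
          data.table(chrom = r$chrom, pos0 = r$pos, anc = r$anc, der = r$der,
                     mut_class = r$mclass)
        })),
        g1 = do.call(rbind, lapply(rows, `[[`, "g1")),
        g2 = do.call(rbind, lapply(rows, `[[`, "g2"))
      )
    }

    pa <- gen_pair("A")
    pb <- gen_pair("B")
    pa$sites[, pair := "A"]
    pb$sites[, pair := "B"]
    ## drop pair-B sites colliding with pair-A positions
    keyA <- paste(pa$sites$chrom, pa$sites$pos0)
    dup <- paste(pb$sites$chrom, pb$sites$pos0) %in% keyA
    pb$sites <- pb$sites[!dup]; pb$g1 <- pb$g1[!dup, , drop = FALSE]
    pb$g2 <- pb$g2[!dup, , drop = FALSE]

    sites <- rbind(pa$sites, pb$sites)
    nA <- nrow(pa$sites); nB <- nrow(pb$sites)
    zero <- function(n_row, sp) matrix(0L, n_row, cfg$n_dip[[sp]])
    geno <- list(
      A = rbind(pa$g1, zero(nB, "A")),
      A2 = rbind(pa$g2, zero(nB, "A2")),
      B = rbind(zero(nA, "B"), pb$g1),
      B2 = rbind(zero(nA, "B2"), pb$g2)
    )
    ## outgroup haploid allele
    u <- runif(nrow(sites))
    out_allele <- ifelse(u < cfg$out_err, sites$der,
                         ifelse(u < cfg$out_err + 0.005,
                                vapply(seq_len(nrow(sites)), function(j) {
                                  sample(setdiff(BASES, c(sites$anc[j], sites$der[j])), 1)
                                }, ""),
                                sites$anc))
    ## order by position, drop sites with no derived allele anywhere
    o <- order(sites$chrom, sites$pos0)
    sites <- sites[o]
    for (sp in names(geno)) geno[[sp]] <- geno[[sp]][o, , drop = FALSE]
    out_allele <- out_allele[o]
    any_derived <- rowSums(do.call(cbind, geno)) > 0 | out_allele == sites$der
    ## drop sites outside the callable mask
    callable <- rep(FALSE, nrow(sites))
    for (ch in unique(mask$chrom)) {
      mi <- mask[chrom == ch]
      si <- which(sites$chrom == ch)
      iv <- findInterval(sites$pos0[si], mi$start)
      callable[si] <- iv >= 1 & sites$pos0[si] < mi$end[pmax(iv, 1L)]
    }
    keep <- any_derived & callable
    sites <- sites[keep]
    for (sp in names(geno)) geno[[sp]] <- geno[[sp]][keep, , drop = FALSE]
    out_allele <- out_allele[keep]
    ## VCF ref/alt labels: ref is the ancestral base for ~70% of sites
    ref_is_anc <- runif(nrow(sites)) < 0.7
    sites[, ref := ifelse(ref_is_anc, anc, der)]
    sites[, alt := ifelse(ref_is_anc, der, anc)]
    rownames_fix <- function(m) { dimnames(m) <- NULL; m }
    geno <- lapply(geno, rownames_fix)
    list(sites = sites[], geno = geno, out_allele = out_allele, mask = mask)
  })
}

## ---------------------------------------------------------------------------

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

## evolve a codon sequence along one branch: per-site substitution proposals
## at rate t (per synonymous opportunity), uniform over the three alternative
## bases, accepted with probability 1 (synonymous) or omega (nonsynonymous)
evolve_branch <- function(codons, t, omega) {
  seqs <- codons
  L <- length(seqs) * 3L
  n_prop <- rpois(1, t * L)
  if (n_prop == 0) return(seqs)
  at <- sample.int(L, n_prop, replace = TRUE)
  for (s in at) {
    ci <- (s - 1L) %/% 3L + 1L
    p <- (s - 1L) %% 3L + 1L
    cd <- seqs[ci]
    old <- substr(cd, p, p)
    new <- sample(setdiff(BASES, old), 1)
    mut <- cd
    substr(mut, p, p) <- new
    syn <- GENETIC_CODE_TABLE[[mut]] == GENETIC_CODE_TABLE[[cd]]
    if (syn || runif(1) < omega) seqs[ci] <- mut
  }
  seqs
}

#' Generate coding data: gene models, alignments and coding SFS
#'
#' Places non-overlapping gene models (with exon structure) and conserved
#' non-coding elements on the chromosomes; builds an ancestral coding
#' sequence per gene and evolves it along the outgroup and the two focal
#' branches at `omega_truth` (synonymous proposals accepted always,
#' nonsynonymous with probability omega); draws fourfold SFS counts around
#' the neutral Poisson random field expectation and zerofold counts around
#' the gamma-DFE expectation (via [expected_selected_sfs()]); assigns each
#' gene its window recombination rate from the landscape.
#'
#' @param cfg a [sim_config()] object
#' @param landscape result of [gen_recombination_landscape()]
#' @return list: genes (models with exon_len, rho truth, density),
#'   exons, cnes (BED-like tables), alignments (named list per gene of
#'   c(A, B, OUT) coding sequences), coding_variants (gene_id, species,
#'   class, count, mut_class), coding_sites (per-gene fourfold/zerofold
#'   callable site counts)
#' @export
gen_coding_data <- function(cfg, landscape) {
  wt <- landscape$windows
  n_hapA <- 2L * cfg$n_dip[["A"]]
  n_hapB <- 2L * cfg$n_dip[["B"]]
  with_seed(stage_seed(cfg$seed, 3L), {
    ## gene placement: random non-overlapping spans
    genes <- rbindlist(lapply(seq_len(cfg$n_genes), function(gi) {
      ci <- sample.int(nrow(cfg$chrom_spec), 1,
                       prob = cfg$chrom_spec$length)
      clen <- cfg$chrom_spec$length[ci]
      cds_len <- sample(seq(300, 1800, by = 3), 1)
      span <- cds_len * 3L
      start <- sample.int(clen - span, 1)
      n_ex <- sample(2:6, 1)
      data.table(gene_id = gi, gene = sprintf("g%04d", gi),
                 chrom = cfg$chrom_spec$name[ci],
                 start = start, end = start + span,
                 strand = sample(c("+", "-"), 1),
                 cds_len = cds_len, n_exons = n_ex)
    }))
    setorder(genes, chrom, start)
    ## drop overlapping genes (keep first)
    keep <- genes[, {
      ok <- rep(TRUE, .N)
      if (.N > 1) for (j in 2:.N) ok[j] <- start[j] >= max(end[seq_len(j - 1)][ok[seq_len(j - 1)]])
      ok
    }, by = chrom]$V1
    genes <- genes[keep]
    genes[, gene_id := seq_len(.N)]

    ## exon structure: split the cds over n_exons blocks within the span
    exons <- genes[, {
      k <- n_exons
      cuts <- sort(sample(seq(3, cds_len - 3, by = 3), k - 1))
      sizes <- diff(c(0, cuts, cds_len))
      gaps0 <- (end - start) - cds_len
      gap_each <- if (k > 1) floor(gaps0 / (k - 1)) else 0
      es <- start + cumsum(c(0, head(sizes, -1) + gap_each))
      data.table(start = es, end = es + sizes, exon = seq_len(k))
    }, by = .(gene_id, gene, chrom)]
    genes[, exon_len := cds_len]

    ## conserved non-coding elements: density varies along chromosomes
    cnes <- rbindlist(lapply(seq_len(nrow(wt)), function(w) {
      lam <- runif(1, 0, 8)
      k <- rpois(1, lam)
      if (k == 0) return(NULL)
      s <- wt$start[w] + sort(sample.int(wt$end[w] - wt$start[w] - 500, k))
      data.table(chrom = wt$chrom[w], start = s,
                 end = s + round(runif(k, 100, 400)))
    }))

    ## per-gene recombination truth: window rho at the gene midpoint
    gmid <- (genes$start + genes$end) / 2
    widx <- vapply(seq_len(nrow(genes)), function(j) {
      which(wt$chrom == genes$chrom[j] & wt$start <= gmid[j] & wt$end > gmid[j])[1]
    }, 0L)
    genes[, rho_A_truth := wt$rho_A[widx]]
    genes[, rho_B_truth := wt$rho_B[widx]]
    genes[, divergent_label_truth := wt$divergent_label[widx]]

    ## ancestral CDS, branch evolution, per-gene degeneracy
    g_del <- dfe_grid()
    sfs_shape_sel_A <- {
      w <- dfe_weights(g_del, cfg$dfe_truth[["shape"]], cfg$dfe_truth[["mean"]])
      as.vector(dfe_imat(n_hapA, g_del) %*% w)
    }
    sfs_shape_sel_B <- {
      w <- dfe_weights(g_del, cfg$dfe_truth[["shape"]], cfg$dfe_truth[["mean"]])
      as.vector(dfe_imat(n_hapB, g_del) %*% w)
    }
    neutA <- 1 / seq_len(n_hapA - 1L)
    neutB <- 1 / seq_len(n_hapB - 1L)

    alignments <- vector("list", nrow(genes))
    site_rows <- vector("list", nrow(genes))
    var_rows <- vector("list", nrow(genes))
    gc_classes <- c("SS", "WW", "WS", "SW")
    gc_prob <- c(0.15, 0.15, 0.35, 0.35)
    for (gi in seq_len(nrow(genes))) {
      ncod <- genes$cds_len[gi] / 3L
      root <- sample(SENSE_CODONS, ncod, replace = TRUE)
      anc_pair <- evolve_branch(root, cfg$t_out / 2, cfg$omega_truth)
      outg <- evolve_branch(root, cfg$t_out / 2, cfg$omega_truth)
      seqA <- evolve_branch(anc_pair, cfg$t_focal, cfg$omega_truth)
      seqB <- evolve_branch(anc_pair, cfg$t_focal, cfg$omega_truth)
      alignments[[gi]] <- c(A = paste(seqA, collapse = ""),
                            B = paste(seqB, collapse = ""),
                            OUT = paste(outg, collapse = ""))
      deg <- classify_degeneracy(paste(anc_pair, collapse = ""))
      n4 <- sum(deg == "fourfold"); n0 <- sum(deg == "zerofold")
      site_rows[[gi]] <- data.table(gene_id = gi, n_fourfold = n4,
                                    n_zerofold = n0)
      draw_sfs <- function(n_sites, shape_vec) {
        k <- rpois(length(shape_vec), cfg$theta_coding * n_sites * shape_vec)
        if (sum(k) == 0) return(NULL)
        data.table(count = rep(seq_along(shape_vec), k))
      }
      vr <- list()
      v4A <- draw_sfs(n4, neutA)
      if (!is.null(v4A)) vr <- c(vr, list(v4A[, `:=`(species = "A", class = "fourfold")]))
      v0A <- draw_sfs(n0, sfs_shape_sel_A)
      if (!is.null(v0A)) vr <- c(vr, list(v0A[, `:=`(species = "A", class = "zerofold")]))
      v4B <- draw_sfs(n4, neutB)
      if (!is.null(v4B)) vr <- c(vr, list(v4B[, `:=`(species = "B", class = "fourfold")]))
      v0B <- draw_sfs(n0, sfs_shape_sel_B)
      if (!is.null(v0B)) vr <- c(vr, list(v0B[, `:=`(species = "B", class = "zerofold")]))
      if (length(vr)) {
        vv <- rbindlist(vr)
        vv[, gene_id := gi]
        vv[, mut_class := sample(gc_classes, .N, replace = TRUE, prob = gc_prob)]
        var_rows[[gi]] <- vv
      }
    }
    names(alignments) <- genes$gene
    coding_variants <- rbindlist(var_rows)
    coding_sites <- rbindlist(site_rows)
    list(genes = genes[], exons = exons[], cnes = cnes[],
         alignments = alignments, coding_variants = coding_variants[],
         coding_sites = coding_sites[])
  })
}

#' Generate a complete in-memory synthetic dataset
#'
#' Runs [gen_recombination_landscape()], [gen_variant_data()] and
#' [gen_coding_data()] under the configuration's seed and bundles the result
#' with the truth tables needed for parameter-recovery checks.
#'
#' @param cfg a [sim_config()] object
#' @return object of class `sim_dataset`
#' @export
sim_dataset <- function(cfg) {
  landscape <- gen_recombination_landscape(cfg)
  variants <- gen_variant_data(cfg, landscape)
  coding <- gen_coding_data(cfg, landscape)
  structure(list(cfg = cfg, landscape = landscape, variants = variants,
                 coding = coding),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: seed %d, %d sites, %d genes, %d windows\n",
              x$cfg$seed, nrow(x$variants$sites), nrow(x$coding$genes),
              nrow(x$landscape$windows)))
  invisible(x)
}

#' Draw Poisson SFS counts around a PRF expectation
#'
#' Convenience generator for SFS-level recovery experiments: counts per bin
#' i = 1..n-1 are Poisson with mean theta * r_i * I_i(gamma), where I is the
#' PRF integral of [expected_selected_sfs()].
#'
#' @param n haplotype sample size
#' @param theta mutation scale
#' @param gamma scaled coefficient (0 = neutral)
#' @param r nuisance factors (default 1)
#' @param seed RNG seed
#' @return integer vector of counts, bins 1..n-1
#' @export
sim_sfs_counts <- function(n, theta, gamma = 0, r = rep(1, n - 1L), seed = 1) {
  mu <- expected_selected_sfs(n, gamma, theta, r)
  with_seed(seed, rpois(n - 1L, mu))
}
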