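## End-to-end orchestration: simulate -> polarize -> window/gene rho ->
## sweep scan -> FST peaks -> coding statistics -> DFE/omega_a -> gBGC ->
## summary grids, with a run manifest. Every stage is a pure function of its
## inputs and the master seed.

#' Run configuration for the full pipeline
#'
#' @param sim a [sim_config()] (the dataset is simulated) - loading a written
#'   dataset is supported through [read_dataset()] plus the stage functions
#' @param sweep_threshold CLR significance threshold (default 46.25,
#'   a background-selection-aware value)
#' @param peak_z_threshold smoothed ZFST peak threshold (default 2)
#' @param k_bins recombination bins for genes (default 3)
#' @param n_perm permutations for category comparisons (default 200 at desk
#'   scale)
#' @param max_flank_bp CLR scan flanking horizon cap
#' @param fit_dfe_categories fit per-category DFE/omega_a in the summary
#'   table (slower; default TRUE)
#' @return list of class `run_config`
#' @export
run_config <- function(sim = sim_config(), sweep_threshold = 46.25,
                       peak_z_threshold = 2, k_bins = 3, n_perm = 200,
                       max_flank_bp = 1e5, fit_dfe_categories = TRUE) {
  stopifnot(sweep_threshold > 0, peak_z_threshold > 0, k_bins >= 1,
            n_perm >= 1)
  structure(list(sim = sim, sweep_threshold = sweep_threshold,
                 peak_z_threshold = peak_z_threshold, k_bins = k_bins,
                 n_perm = n_perm, max_flank_bp = max_flank_bp,
                 fit_dfe_categories = fit_dfe_categories),
            class = "run_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates all stages and returns a report bundle: window table (rho per
#' species, cM/Mb, conservation labels, FST, smoothed ZFST, sweep presence,
#' peak membership), peak sets per comparison with shared/unique labels, CLR
#' scans and sweep regions per species, gene tables with bins and coding
#' statistics, DFE and omega_a fits per species, gBGC fits and the
#' conserved/divergent contrast, a correlation/regression summary grid, a
#' category summary table, and a manifest (seed, config hash, stage sizes).
#'
#' @param rcfg a [run_config()] object
#' @param quiet suppress stage messages
#' @return list of class `run_bundle`
#' @export
run_all <- function(rcfg = run_config(), quiet = FALSE) {
  if (quiet) return(suppressMessages(run_all(rcfg, quiet = FALSE)))
  cfg <- rcfg$sim
  wbp <- cfg$window_bp

  dat <- stage("simulate", sim_dataset(cfg))
  s <- dat$variants$sites
  g <- dat$variants$geno
  wt <- copy(dat$landscape$windows)
  n_hap <- vapply(g, function(m) 2L * ncol(m), 0L)

  ## --- polarization and per-species SFS ------------------------------------
  pol <- stage("polarize", {
    derA <- rowSums(g$A) + rowSums(g$A2)
    derB <- rowSums(g$B) + rowSums(g$B2)
    nA <- 2L * (ncol(g$A) + ncol(g$A2))
    nB <- 2L * (ncol(g$B) + ncol(g$B2))
    der_is_alt <- s$der == s$alt
    vt <- data.table(
      ref = s$ref, alt = s$alt,
      a_alt = ifelse(der_is_alt, derA, nA - derA),
      b_alt = ifelse(der_is_alt, derB, nB - derB),
      o_alt = as.integer(dat$variants$out_allele == s$alt))
    vt[, `:=`(a_ref = nA - a_alt, b_ref = nB - b_alt,
              o_ref = as.integer(dat$variants$out_allele == s$ref))]
    pv <- polarize_variants(vt)
    pv[, `:=`(chrom = s$chrom, pos0 = s$pos0)]
    pv
  })

  ## derived dosage per focal species on polarized sites
  spp_sfs <- stage("sfs", {
    callable_bp <- dat$variants$mask[, sum(end - start)]
    out <- list()
    for (sp in c("A", "B")) {
      der <- rowSums(g[[sp]])
      der_pol <- ifelse(pol$ancestral == s$anc, der, 2L * ncol(g[[sp]]) - der)
      use <- pol$polarized & der_pol >= 1
      out[[sp]] <- list(
        derived = der_pol, use = use,
        sfs = build_sfs(der_pol[use], n_hap[[sp]],
                        invariant_count = callable_bp - sum(use)))
    }
    out
  })

  ## --- window and gene recombination ---------------------------------------
  rec <- stage("recwin", {
    win <- wt[, .(chrom, start, end, class)]
    wr_A <- window_weighted_rho(dat$landscape$intervals_A, win)
    wr_B <- window_weighted_rho(dat$landscape$intervals_B, win)
    win5 <- make_windows(cfg$chrom_spec, 5e6)
    wr5_B <- window_weighted_rho(dat$landscape$intervals_B,
                                 win5[, .(chrom, start, end)])
    map5 <- dat$landscape$linkage_map[, {
      w5 <- win5[chrom == .BY$chrom]
      i <- findInterval(start, w5$start)
      .(start5 = w5$start[i], cm_mb = cm_mb, w = end - start)
    }, by = chrom][, .(cm_mb = sum(cm_mb * w) / sum(w)),
                   by = .(chrom, start = start5)]
    m5 <- merge(wr5_B, map5, by = c("chrom", "start"), all.x = TRUE)
    ne_hat <- estimate_genomewide_ne(m5, m5$cm_mb)
    wt[, rho_A_hat := wr_A$rho_per_bp]
    wt[, rho_B_hat := wr_B$rho_per_bp]
    wt[, cm_mb_A := convert_to_cm(rho_A_hat, ne_hat)]
    wt[, cm_mb_B := convert_to_cm(rho_B_hat, ne_hat)]
    wt[, conservation := classify_rate_conservation(rho_A_hat, rho_B_hat,
                                                    log10_transform = TRUE)]
    ## gene-level aggregation over gene spans
    genes <- copy(dat$coding$genes)
    gr_A <- window_weighted_rho(dat$landscape$intervals_A,
                                genes[, .(chrom, start, end)],
                                min_coverage = 0)
    gr_B <- window_weighted_rho(dat$landscape$intervals_B,
                                genes[, .(chrom, start, end)],
                                min_coverage = 0)
    genes[, rho_A_hat := gr_A$rho_per_bp]
    genes[, rho_B_hat := gr_B$rho_per_bp]
    genes[, conservation := classify_rate_conservation(rho_A_hat, rho_B_hat,
                                                       log10_transform = TRUE)]
    list(ne_hat = ne_hat, genes = genes)
  })
  genes <- rec$genes

  ## --- sweep scan -----------------------------------------------------------
  sweeps <- stage("sweep", {
    out <- list()
    for (sp in c("A", "B")) {
      bg <- sfs_full_spectrum(spp_sfs[[sp]]$sfs)
      use <- spp_sfs[[sp]]$use
      der <- spp_sfs[[sp]]$derived
      scans <- list(); regions <- list()
      for (ch in cfg$chrom_spec$name) {
        i <- which(s$chrom == ch & use)
        if (!length(i)) next
        sc <- clr_scan(s$pos0[i], der[i], n_hap[[sp]], bg,
                       max_flank_bp = rcfg$max_flank_bp)
        sc[, chrom := ch]
        rg <- merge_significant_sites(sc, rcfg$sweep_threshold)
        if (nrow(rg)) rg[, chrom := ch]
        scans[[ch]] <- sc; regions[[ch]] <- rg
      }
      scan <- rbindlist(scans)
      regs <- rbindlist(regions, fill = TRUE)
      out[[sp]] <- list(scan = scan, regions = regs)
      wt[, (paste0("sweep_", sp)) :=
           sweep_window_presence(regs, wt[, .(chrom, start, end)])]
      ## per-window max CLR for the regression summaries
      mx <- scan[, .(maxL = max(Lambda)),
                 by = .(chrom, win = floor(pos / wbp))]
      wt[, win__ := floor(start / wbp)]
      wt[, (paste0("clr_max_", sp)) := 0]
      wt[mx, on = c("chrom", win__ = "win"),
         (paste0("clr_max_", sp)) := i.maxL]
      wt[, win__ := NULL]
    }
    out
  })

  ## --- FST, peaks -----------------------------------------------------------
  peaks <- stage("fst_peaks", {
    pk <- list()
    for (pair in c("A", "B")) {
      fw <- window_fst(g[[pair]], g[[paste0(pair, "2")]], s$chrom, s$pos0,
                       wt[, .(chrom, start, end)])
      wt[, (paste0("fst_", pair)) := fw$fst]
      z <- ztransform_by_chrom(fw$fst, fw$chrom)
      wt[, (paste0("zfst_", pair)) := z]
      sm <- copy(fw)[, z := z][!is.na(z)]
      sm[, zs := smooth_zfst(z), by = chrom]
      wt[, (paste0("zfst_smooth_", pair)) := NA_real_]
      wt[sm, on = c("chrom", "start"), (paste0("zfst_smooth_", pair)) := i.zs]
      pk[[pair]] <- call_fst_peaks(sm, zcol = "zs",
                                   z_threshold = rcfg$peak_z_threshold)
    }
    cl <- classify_peaks(pk$A, pk$B, labels = c("A_unique", "B_unique"))
    all_pk <- rbind(cl$peaks1[, comparison := "A"],
                    cl$peaks2[, comparison := "B"])
    for (pair in c("A", "B")) {
      pkp <- all_pk[comparison == pair]
      lab <- rep(NA_character_, nrow(wt))
      memb <- rep(FALSE, nrow(wt))
      for (j in seq_len(nrow(pkp))) {
        hit <- wt$chrom == pkp$chrom[j] & wt$start < pkp$end[j] &
          wt$end > pkp$start[j]
        memb <- memb | hit
        lab[hit] <- pkp$label[j]
      }
      wt[, (paste0("peak_", pair)) := memb]
      wt[, (paste0("peak_label_", pair)) := lab]
    }
    enr <- positional_peak_enrichment(
      wt[, .(chrom, start, end, class, peak = peak_A | peak_B)],
      n_perm = max(rcfg$n_perm, 1000), seed = stage_seed(cfg$seed, 7L))
    list(peaks = all_pk, enrichment = enr)
  })

  ## --- coding statistics ----------------------------------------------------
  coding <- stage("coding", {
    cs <- dat$coding$coding_sites
    cv <- dat$coding$coding_variants
    aln <- dat$coding$alignments
    ## functional density: exon + CNE bp in the surrounding window
    fd_src <- rbind(dat$coding$exons[, .(chrom, start, end)],
                    dat$coding$cnes[, .(chrom, start, end)])
    setorder(fd_src, chrom, start)
    gmid <- (genes$start + genes$end) / 2
    fwin <- data.table(chrom = genes$chrom,
                       start = pmax(0, gmid - wbp / 2),
                       end = gmid + wbp / 2)
    genes[, functional_density := {
      ov <- vapply(seq_len(.N), function(j) {
        fs <- fd_src[chrom == fwin$chrom[j] & start < fwin$end[j] &
                       end > fwin$start[j]]
        if (!nrow(fs)) return(0)
        sum(pmin(fs$end, fwin$end[j]) - pmax(fs$start, fwin$start[j]))
      }, 0)
      ov / (fwin$end - fwin$start)
    }]
    ## substitution mapping per gene and species
    subs <- rbindlist(lapply(names(aln), function(gn) {
      a <- aln[[gn]]
      rbind(
        data.table(gene = gn, species = "A",
                   as.data.table(map_substitutions(a[["A"]], a[["B"]],
                                                   a[["OUT"]],
                                                   gc_conservative = TRUE))),
        data.table(gene = gn, species = "B",
                   as.data.table(map_substitutions(a[["B"]], a[["A"]],
                                                   a[["OUT"]],
                                                   gc_conservative = TRUE))))
    }))
    ## per-gene diversity (GC-conservative)
    pergene <- list()
    for (sp in c("A", "B")) {
      nh <- n_hap[[sp]]
      vv <- cv[species == sp]
      vv[, gc := mut_class %in% c("SS", "WW")]
      agg <- vv[, .(
        pi_n_num = sum(ifelse(class == "zerofold" & gc,
                              2 * count * (nh - count) / (nh * (nh - 1)), 0)),
        pi_s_num = sum(ifelse(class == "fourfold" & gc,
                              2 * count * (nh - count) / (nh * (nh - 1)), 0))),
        by = gene_id]
      tab <- merge(genes[, .(gene_id, gene, chrom, start, end, exon_len,
                             rho_A_hat, rho_B_hat, conservation,
                             functional_density)],
                   cs, by = "gene_id", all.x = TRUE)
      tab <- merge(tab, agg, by = "gene_id", all.x = TRUE)
      for (cc in c("pi_n_num", "pi_s_num")) set(tab, which(is.na(tab[[cc]])), cc, 0)
      tab[, pi_n := pi_n_num / pmax(n_zerofold, 1)]
      tab[, pi_s := pi_s_num / pmax(n_fourfold, 1)]
      tab <- merge(tab, subs[species == sp, .(gene, dn, ds)], by = "gene",
                   all.x = TRUE)
      rho_col <- paste0("rho_", sp, "_hat")
      ok <- !is.na(tab[[rho_col]])
      bins <- bin_genes(tab[[rho_col]][ok], tab$functional_density[ok],
                        tab$start[ok], k_bins = rcfg$k_bins)
      tab[, `:=`(rho_bin = NA_integer_, density_bin = NA_character_)]
      tab[ok, `:=`(rho_bin = bins$rho_bin, density_bin = bins$density_bin)]
      pergene[[sp]] <- tab
    }
    list(genes = pergene, dnds = lapply(pergene, aggregate_dnds))
  })

  ## --- DFE / omega_a --------------------------------------------------------
  dfe <- stage("dfe", {
    out <- list()
    for (sp in c("A", "B")) {
      nh <- n_hap[[sp]]
      vv <- dat$coding$coding_variants[species == sp]
      sfs_n <- tabulate(vv[class == "fourfold", count], nbins = nh - 1L)
      sfs_s <- tabulate(vv[class == "zerofold", count], nbins = nh - 1L)
      ft <- fit_dfe(sfs_n, sfs_s, nh)
      ar <- adaptive_rate(ft, coding$dnds[[sp]]$dnds)
      out[[sp]] <- list(fit = ft, adaptive = ar)
    }
    out
  })

  ## --- gBGC by window conservation class ------------------------------------
  gbgc <- stage("gbgc", {
    cls_of_site <- {
      key <- paste(s$chrom, floor(s$pos0 / wbp))
      wcls <- setNames(wt$conservation, paste(wt$chrom, floor(wt$start / wbp)))
      wcls[key]
    }
    fits <- list(A = list(), B = list())
    for (sp in c("A", "B")) {
      der <- spp_sfs[[sp]]$derived
      use <- spp_sfs[[sp]]$use
      nh <- n_hap[[sp]]
      for (cl in c("conserved", "divergent_A_higher", "divergent_B_higher")) {
        i <- which(use & cls_of_site == cl & !is.na(cls_of_site))
        mk <- function(classes) {
          j <- i[pol$mut_class[i] %in% classes & der[i] <= nh - 1L]
          tabulate(der[j], nbins = nh - 1L)
        }
        ft <- try(fit_gbgc(mk("WS"), mk("SW"), mk(c("SS", "WW")), nh),
                  silent = TRUE)
        if (!inherits(ft, "try-error")) fits[[sp]][[cl]] <- ft
      }
    }
    contrast <- try(gbgc_contrast(fits), silent = TRUE)
    if (inherits(contrast, "try-error")) {
      contrast <- list(table = NULL, ordering_ok = NA)
    }
    list(fits = fits, contrast = contrast)
  })

  ## --- summary grids --------------------------------------------------------
  summaries <- stage("stats", {
    grid <- list()
    for (sp in c("A", "B")) {
      rho <- wt[[paste0("rho_", sp, "_hat")]]
      fst <- wt[[paste0("fst_", sp)]]
      cons <- wt$conservation == "conserved"
      grid[[paste0("fst_rho_", sp)]] <-
        correlate(rho, fst, method = "spearman")
      grid[[paste0("fst_rho_cons_", sp)]] <-
        correlate(rho[cons], fst[cons], method = "spearman")
      grid[[paste0("sweep_rho_", sp)]] <- tryCatch(
        logistic_sweep_model(wt[[paste0("sweep_", sp)]], rho),
        error = function(e) NULL)
      other <- if (sp == "A") "B" else "A"
      grid[[paste0("fst_rho_cross_", sp)]] <-
        correlate(wt[[paste0("rho_", other, "_hat")]], fst,
                  method = "spearman")
    }
    ## category table per species
    cats <- list(); cat_tables <- list()
    for (sp in c("A", "B")) {
      gt <- coding$genes[[sp]]
      pkcol <- paste0("peak_", sp)
      lblcol <- paste0("peak_label_", sp)
      swcols <- c("sweep_A", "sweep_B")[match(sp, c("A", "B"))]
      gwin <- vapply(seq_len(nrow(gt)), function(j) {
        w <- which(wt$chrom == gt$chrom[j] & wt$start < gt$end[j] &
                     wt$end > gt$start[j])
        if (!length(w)) NA_integer_ else w[1]
      }, 0L)
      in_peak <- !is.na(gwin) & wt[[pkcol]][gwin]
      lbl <- wt[[lblcol]][gwin]
      sw <- !is.na(gwin) & wt[[swcols]][gwin]
      categories <- list(
        outside_peaks = !in_peak,
        shared_peaks = in_peak & !is.na(lbl) & lbl == "shared",
        lineage_specific_peaks = in_peak & !is.na(lbl) &
          lbl == paste0(sp, "_unique"),
        peaks_with_sweep = in_peak & sw,
        peaks_without_sweep = in_peak & !sw)
      cat_tables[[sp]] <- peak_category_table(
        gt, categories,
        variants = dat$coding$coding_variants[species == sp],
        n = n_hap[[sp]], n_perm = rcfg$n_perm,
        fit_dfe_categories = rcfg$fit_dfe_categories,
        seed = stage_seed(cfg$seed, 9L))
      cats[[sp]] <- categories
    }
    list(grid = grid, categories = cat_tables)
  })

  manifest <- list(
    seed = cfg$seed,
    config_hash = config_hash(unclass(cfg)),
    n_sites = nrow(s), n_windows = nrow(wt), n_genes = nrow(genes),
    ne_hat = rec$ne_hat,
    package_version = tryCatch(as.character(utils::packageVersion("recsel")),
                               error = function(e) NA_character_))

  structure(list(windows = wt[], peaks = peaks$peaks,
                 peak_enrichment = peaks$enrichment,
                 sweeps = sweeps, genes = coding$genes,
                 dnds = coding$dnds, dfe = dfe, gbgc = gbgc,
                 summaries = summaries, polarized = pol,
                 sfs = spp_sfs, ne_hat = rec$ne_hat,
                 manifest = manifest),
            class = "run_bundle")
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("run_bundle: seed %d, %d windows, %d genes, %d sites\n",
              x$manifest$seed, x$manifest$n_windows, x$manifest$n_genes,
              x$manifest$n_sites))
  cat(sprintf("  Ne_hat = %.0f; peaks: %d (%d shared); divergent windows: %.1f%%\n",
              x$ne_hat, nrow(x$peaks), sum(x$peaks$label == "shared"),
              100 * mean(x$windows$conservation != "conserved", na.rm = TRUE)))
  for (sp in c("A", "B")) {
    ar <- x$dfe[[sp]]$adaptive
    cat(sprintf("  species %s: dN/dS = %.3f, omega_a = %.3f, sweep regions: %d\n",
                sp, ar$omega, ar$omega_a, nrow(x$sweeps[[sp]]$regions)))
  }
  invisible(x)
}

#' Write the report bundle to a directory
#'
#' Emits the window table, peak BED, sweep-region BED and scan TSV per
#' species, gene tables, fit summaries (JSON) and the manifest (YAML).
#'
#' @param bundle a `run_bundle` from [run_all()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(bundle$windows, file.path(dir, "windows.tsv"))
  write_tsv(bundle$peaks, file.path(dir, "peaks.tsv"))
  write_tsv(bundle$peak_enrichment, file.path(dir, "peak_enrichment.tsv"))
  for (sp in c("A", "B")) {
    write_tsv(bundle$sweeps[[sp]]$scan, file.path(dir, sprintf("clr_scan_%s.tsv", sp)))
    write_tsv(bundle$sweeps[[sp]]$regions,
              file.path(dir, sprintf("sweep_regions_%s.tsv", sp)))
    write_tsv(bundle$genes[[sp]], file.path(dir, sprintf("genes_%s.tsv", sp)))
    write_tsv(bundle$summaries$categories[[sp]],
              file.path(dir, sprintf("categories_%s.tsv", sp)))
  }
  fits <- list(
    dfe = lapply(bundle$dfe, function(x) {
      c(x$fit[c("mean", "shape", "theta_sel", "loglik", "convergence")],
        x$adaptive)
    }),
    gbgc = lapply(bundle$gbgc$fits, function(sp_fits) {
      lapply(sp_fits, function(f) f[c("B", "se_B", "loglik")])
    }),
    gbgc_contrast = list(
      table = as.data.frame(bundle$gbgc$contrast$table),
      ordering_ok = bundle$gbgc$contrast$ordering_ok),
    grid = lapply(bundle$summaries$grid, function(x) {
      if (inherits(x, "logistic_fit")) unclass(x) else x
    }),
    ne_hat = bundle$ne_hat)
  jsonlite::write_json(fits, file.path(dir, "fits.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
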