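## Site degeneracy classification, GC-conservative piN/piS, parsimony-based
## focal-branch substitution mapping, dN/dS aggregation and gene binning.

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

BASES <- c("A", "C", "G", "T")

## degeneracy of every codon x position: "fourfold", "zerofold" or "other"
degeneracy_table <- local({
  codons <- names(GENETIC_CODE_TABLE)
  tab <- matrix("other", length(codons), 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    aa <- GENETIC_CODE_TABLE[[cd]]
    for (p in 1:3) {
      alts <- BASES[BASES != substr(cd, p, p)]
      syn <- vapply(alts, function(b) {
        mut <- cd
        substr(mut, p, p) <- b
        GENETIC_CODE_TABLE[[mut]] == aa
      }, TRUE)
      tab[cd, p] <- if (all(syn)) "fourfold" else if (!any(syn)) "zerofold" else "other"
    }
  }
  tab
})

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                ""))
}

#' Classify coding sites by degeneracy
#'
#' A site is fourfold degenerate iff all three alternative bases are
#' synonymous, zerofold iff none is, and "other" otherwise. Sequences on the
#' minus strand are reverse-complemented first, so classification is
#' invariant under the strand convention. Incomplete terminal codons are
#' classed "other".
#'
#' @param cds coding sequence (character scalar, 5'->3' in codon frame on the
#'   given strand)
#' @param strand "+" or "-" (default "+")
#' @return character vector of classes per position of the input sequence
#'   (in input orientation)
#' @export
classify_degeneracy <- function(cds, strand = "+") {
  s <- toupper(cds)
  if (strand == "-") s <- revcomp(s)
  n <- nchar(s)
  out <- rep("other", n)
  n_full <- (n %/% 3) * 3
  if (n_full >= 3) {
    codons <- substring(s, seq(1, n_full, 3), seq(3, n_full, 3))
    known <- codons %in% rownames(degeneracy_table)
    cls <- matrix("other", length(codons), 3)
    cls[known, ] <- degeneracy_table[codons[known], , drop = FALSE]
    out[seq_len(n_full)] <- as.vector(t(cls))
  }
  if (strand == "-") out <- rev(out)
  out
}

#' Nucleotide diversity from polarized variants and callable-site tallies
#'
#' pi = sum over variants of 2 p (1-p) n/(n-1), divided by the number of
#' callable sites of the class; with `gc_conservative = TRUE` the numerator
#' is restricted to strong-strong (C/G) and weak-weak (A/T) variants while
#' the denominator is unchanged.
#'
#' @param derived_count derived copies per variant of the class
#' @param n haplotype sample size
#' @param callable_bp callable sites of the class (> 0)
#' @param gc_conservative_flag logical per variant (used when
#'   `gc_conservative = TRUE`)
#' @param gc_conservative restrict to GC-conservative variants
#' @return per-site nucleotide diversity
#' @export
diversity_by_class <- function(derived_count, n, callable_bp,
                               gc_conservative_flag = NULL,
                               gc_conservative = FALSE) {
  if (is.na(callable_bp) || callable_bp <= 0) stop("zero callable-site denominator")
  j <- derived_count
  if (gc_conservative) {
    if (is.null(gc_conservative_flag)) stop("gc_conservative_flag required")
    j <- j[gc_conservative_flag]
  }
  if (length(j) == 0) return(0)
  sum(2 * j * (n - j) / (n * (n - 1))) / callable_bp
}

#' Map substitutions to the focal branch by outgroup parsimony
#'
#' Given aligned coding sequences of the focal species (major-allele
#' consensus), a sister clade and an outgroup, a substitution is assigned to
#' the focal branch iff the focal base differs while the other two sequences
#' agree; sites where all three differ are skipped. Substitutions are
#' classified synonymous/nonsynonymous by single-base codon comparison
#' against the ancestral codon (per-position majority base), and
#' GC-conservative iff the base pair is A<->T or C<->G. Mutational
#' opportunities are counted per ancestral codon: each site contributes its
#' synonymous/nonsynonymous fraction of the three possible changes (or, with
#' `gc_conservative = TRUE`, only its single GC-conservative change).
#'
#' @param focal,sister,outgroup aligned coding sequences (equal length,
#'   multiple of 3, same strand/frame); gaps ("-") and Ns are skipped
#' @param gc_conservative restrict counts and opportunities to
#'   GC-conservative changes
#' @return list: dn, ds (per-site rates), n_subs, s_subs, n_sites, s_sites
#' @export
map_substitutions <- function(focal, sister, outgroup,
                              gc_conservative = FALSE) {
  f <- strsplit(toupper(focal), "")[[1]]
  s <- strsplit(toupper(sister), "")[[1]]
  o <- strsplit(toupper(outgroup), "")[[1]]
  L <- length(f)
  if (length(s) != L || length(o) != L) stop("sequences must be aligned")
  n_full <- (L %/% 3) * 3
  n_subs <- s_subs <- 0L
  n_sites <- s_sites <- 0
  gc_pair <- function(x, y) {
    (x %in% c("A", "T") && y %in% c("A", "T")) ||
      (x %in% c("C", "G") && y %in% c("C", "G"))
  }
  for (c0 in seq(1, n_full, by = 3)) {
    idx <- c0:(c0 + 2)
    fb <- f[idx]; sb <- s[idx]; ob <- o[idx]
    if (any(!fb %in% BASES) || any(!sb %in% BASES) || any(!ob %in% BASES)) next
    ## ancestral base per position: the base shared by >= 2 of the three
    anc <- character(3)
    skip <- FALSE
    for (p in 1:3) {
      bs <- c(fb[p], sb[p], ob[p])
      tb <- table(bs)
      if (max(tb) == 1) { skip <- TRUE; break }  # all three differ
      anc[p] <- names(tb)[which.max(tb)]
    }
    if (skip) next
    anc_codon <- paste(anc, collapse = "")
    if (!anc_codon %in% rownames(degeneracy_table)) next
    aa_anc <- GENETIC_CODE_TABLE[[anc_codon]]
    ## opportunities from the ancestral codon
    for (p in 1:3) {
      if (gc_conservative) {
        alt <- chartr("ACGT", "TGCA", anc[p])  # the single GC-conservative change
        mut <- anc_codon; substr(mut, p, p) <- alt
        if (GENETIC_CODE_TABLE[[mut]] == aa_anc) {
          s_sites <- s_sites + 1
        } else {
          n_sites <- n_sites + 1
        }
      } else {
        alts <- BASES[BASES != anc[p]]
        syn <- vapply(alts, function(bb) {
          mut <- anc_codon; substr(mut, p, p) <- bb
          GENETIC_CODE_TABLE[[mut]] == aa_anc
        }, TRUE)
        s_sites <- s_sites + sum(syn) / 3
        n_sites <- n_sites + sum(!syn) / 3
      }
    }
    ## focal-branch substitutions: focal differs, sister and outgroup agree
    for (p in 1:3) {
      if (fb[p] != anc[p] && sb[p] == ob[p] && sb[p] == anc[p]) {
        if (gc_conservative && !gc_pair(anc[p], fb[p])) next
        mut <- anc_codon; substr(mut, p, p) <- fb[p]
        if (GENETIC_CODE_TABLE[[mut]] == aa_anc) {
          s_subs <- s_subs + 1L
        } else {
          n_subs <- n_subs + 1L
        }
      }
    }
  }
  list(dn = if (n_sites > 0) n_subs / n_sites else NA_real_,
       ds = if (s_sites > 0) s_subs / s_sites else NA_real_,
       n_subs = n_subs, s_subs = s_subs,
       n_sites = n_sites, s_sites = s_sites)
}

#' Aggregate dN/dS across genes
#'
#' Genes with summed exon length below `min_exon_bp` are excluded; the
#' summary is mean(dN) / mean(dS) over the remaining genes, which stabilizes
#' the ratio for genes with few substitutions. NA with an explicit flag when
#' mean dS is 0.
#'
#' @param genes data.table with columns dn, ds and exon_len
#' @param min_exon_bp exclusion threshold on summed exon length (default 200)
#' @return list: dnds, n_genes, mean_dn, mean_ds, defined (FALSE if dS = 0)
#' @export
aggregate_dnds <- function(genes, min_exon_bp = 200) {
  g <- as.data.table(genes)[exon_len >= min_exon_bp & !is.na(dn) & !is.na(ds)]
  if (nrow(g) == 0) stop("no genes left after the exon-length exclusion")
  mdn <- mean(g$dn); mds <- mean(g$ds)
  list(dnds = if (mds > 0) mdn / mds else NA_real_,
       n_genes = nrow(g), mean_dn = mdn, mean_ds = mds, defined = mds > 0)
}

#' Assign genes to recombination-rate and functional-density bins
#'
#' Genes are ranked by recombination rate (ties broken by genomic position
#' for determinism) and split into `k_bins` equal-count bins; within each
#' bin, genes are split at the median functional density (the fraction of
#' functional bp - exons and conserved non-coding elements - in the
#' surrounding window) into low/high density halves, again breaking ties by
#' position, so a constant density still yields a ceiling(n/2)/floor(n/2)
#' split.
#'
#' @param rho per-gene recombination rate
#' @param functional_density per-gene functional density
#' @param pos genomic position per gene (tie-break)
#' @param k_bins number of recombination bins (default 3)
#' @return data.table with rho_bin (1 = lowest) and density_bin ("low"/"high")
#' @export
bin_genes <- function(rho, functional_density, pos, k_bins = 3) {
  n <- length(rho)
  if (n < k_bins) stop("fewer genes than bins")
  stopifnot(length(functional_density) == n, length(pos) == n)
  ord <- order(rho, pos)
  rho_bin <- integer(n)
  rho_bin[ord] <- ceiling(seq_len(n) * k_bins / n)
  density_bin <- character(n)
  for (b in seq_len(k_bins)) {
    idx <- which(rho_bin == b)
    o2 <- idx[order(functional_density[idx], pos[idx])]
    n_low <- ceiling(length(o2) / 2)
    density_bin[o2] <- rep(c("low", "high"),
                           c(n_low, length(o2) - n_low))
  }
  data.table(rho_bin = rho_bin, density_bin = density_bin)
}
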