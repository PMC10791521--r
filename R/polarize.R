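## Ancestral-state assignment by the three-group fixation rule, callable-site
## accounting, and unfolded site frequency spectra.

STRONG_BASES <- c("C", "G")
WEAK_BASES <- c("A", "T")

## mutation class of an ancestral -> derived base change
mutation_class <- function(anc, der) {
  anc_s <- anc %in% STRONG_BASES
  der_s <- der %in% STRONG_BASES
  ifelse(anc_s & der_s, "SS",
         ifelse(!anc_s & !der_s, "WW",
                ifelse(!anc_s & der_s, "WS", "SW")))
}

#' Polarize biallelic variants by the three-group fixation rule
#'
#' Groups are (1) the first species pair, (2) the second species pair and
#' (3) the outgroup. A group is "fixed" for an allele iff it has at least one
#' called allele and all its called alleles are identical; a group with no
#' called alleles (or a heterozygous haploid outgroup call) cannot vote.
#' Whenever any two of the three groups are fixed for the same allele, that
#' allele is assigned as the ancestral state; otherwise the site is left
#' unpolarized.
#'
#' @param variants data.frame/data.table with columns `ref`, `alt` and, per
#'   group g in (a, b, o): `g_ref` and `g_alt` = called allele counts for the
#'   ref and alt allele in that group
#' @return data.table with ancestral/derived alleles, `polarized` flag,
#'   mutation class (WS/SW/SS/WW) and GC-conservative flag (class SS or WW)
#' @export
polarize_variants <- function(variants) {
  v <- as.data.table(variants)
  need <- c("ref", "alt", "a_ref", "a_alt", "b_ref", "b_alt", "o_ref", "o_alt")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tot <- v$a_ref + v$a_alt + v$b_ref + v$b_alt + v$o_ref + v$o_alt
  if (any(tot == 0)) stop("site(s) with zero called alleles in every group")

  fixed_allele <- function(nref, nalt) {
    ## returns "ref", "alt" or NA (not fixed / no calls)
    ifelse(nref > 0 & nalt == 0, "ref",
           ifelse(nalt > 0 & nref == 0, "alt", NA_character_))
  }
  fa <- fixed_allele(v$a_ref, v$a_alt)
  fb <- fixed_allele(v$b_ref, v$b_alt)
  fo <- fixed_allele(v$o_ref, v$o_alt)
  votes_ref <- (!is.na(fa) & fa == "ref") + (!is.na(fb) & fb == "ref") +
    (!is.na(fo) & fo == "ref")
  votes_alt <- (!is.na(fa) & fa == "alt") + (!is.na(fb) & fb == "alt") +
    (!is.na(fo) & fo == "alt")
  anc <- ifelse(votes_ref >= 2, "ref", ifelse(votes_alt >= 2, "alt", NA))
  out <- copy(v)
  out[, polarized := !is.na(anc)]
  out[, ancestral := ifelse(anc == "ref", ref, alt)]
  out[, derived := ifelse(anc == "ref", alt, ref)]
  out[, mut_class := ifelse(polarized, mutation_class(ancestral, derived),
                            NA_character_)]
  out[, gc_conservative := polarized & mut_class %in% c("SS", "WW")]
  out[]
}

#' Tally callable sites per site class
#'
#' Denominators for diversity statistics: the number of callable bp falling
#' in each site class, computed as the intersection of the callable mask with
#' the class intervals, plus the number of polarized variants per class.
#'
#' @param mask data.table of callable intervals (chrom, start, end), 0-based
#'   half-open, sorted and non-overlapping per chromosome
#' @param class_intervals named list of interval tables (chrom, start, end),
#'   one per site class; a class named "all" covering everything is implied
#' @param variants optional polarized variant table with chrom, pos0 and a
#'   `class` column to count per class
#' @return data.table with class, callable_bp, n_variants
#' @export
tally_site_classes <- function(mask, class_intervals = list(), variants = NULL) {
  mask <- as.data.table(mask)
  check_disjoint_sorted(mask, "callable mask")
  classes <- names(class_intervals)
  res <- data.table(class = c("all", classes),
                    callable_bp = c(mask[, sum(end - start)],
                                    vapply(classes, function(cl) {
                                      ci <- as.data.table(class_intervals[[cl]])
                                      sum(interval_overlap_bp(mask, ci))
                                    }, 0)))
  res[, n_variants := 0L]
  if (!is.null(variants)) {
    v <- as.data.table(variants)
    res[class == "all", n_variants := nrow(v)]
    if ("class" %in% names(v)) {
      cnt <- v[, .N, by = class]
      res[cnt, on = "class", n_variants := i.N]
    }
  }
  res[]
}

#' Build an unfolded site frequency spectrum
#'
#' Bins 1..n-1 count polarized variants by their derived-allele copy number;
#' unpolarized sites contribute to no bin. The invariant-site count (derived
#' copy number 0, from the callable-site tally) and the fixed-derived count
#' (copy number n) are carried separately so callers can include them when a
#' spectrum over 0..n is needed (e.g. a sweep-scan background).
#'
#' @param derived_count integer vector of derived copies per polarized variant
#' @param n haplotype sample size
#' @param invariant_count number of callable invariant sites (bin 0)
#' @return object of class `sfs`: list(n, bins (1..n-1), invariant, fixed)
#' @export
build_sfs <- function(derived_count, n, invariant_count = 0) {
  derived_count <- derived_count[!is.na(derived_count)]
  if (length(derived_count) && (min(derived_count) < 0 || max(derived_count) > n)) {
    stop("derived counts must lie in [0, n]")
  }
  bins <- tabulate(derived_count[derived_count >= 1 & derived_count <= n - 1],
                   nbins = n - 1L)
  structure(list(n = n, bins = bins,
                 invariant = invariant_count + sum(derived_count == 0),
                 fixed = sum(derived_count == n)),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("unfolded SFS: n = %d haplotypes, %d segregating, %g invariant, %d fixed\n",
              x$n, sum(x$bins), x$invariant, x$fixed))
  invisible(x)
}

#' Spectrum over derived copies 0..n from an `sfs` object
#'
#' @param sfs an `sfs` object
#' @param include_invariant include the invariant class as bin 0 (default TRUE)
#' @param include_fixed include fixed-derived sites as bin n (default TRUE)
#' @return numeric vector of length n+1 (counts; bins switched off are 0)
#' @export
sfs_full_spectrum <- function(sfs, include_invariant = TRUE,
                              include_fixed = TRUE) {
  c(if (include_invariant) sfs$invariant else 0,
    sfs$bins,
    if (include_fixed) sfs$fixed else 0)
}
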