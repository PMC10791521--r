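## File-format boundary: VCF 4.2 (via vcfR on the read side), BED (0-based
## half-open), TSV tables with headers, FASTA (Biostrings), YAML manifest.
## All in-memory coordinates are 0-based half-open; VCF POS is 1-based and
## converted only here.

write_tsv <- function(dt, path) {
  fwrite(as.data.table(dt), path, sep = "\t", quote = FALSE, na = "NA")
}

read_tsv <- function(path) fread(path, sep = "\t", na.strings = "NA")

write_bed <- function(dt, path, extra_cols = character()) {
  d <- as.data.table(dt)[, c("chrom", "start", "end", extra_cols), with = FALSE]
  fwrite(d, path, sep = "\t", quote = FALSE, col.names = FALSE)
}

read_bed <- function(path, extra_cols = character()) {
  d <- fread(path, sep = "\t", header = FALSE)
  setnames(d, c("chrom", "start", "end", extra_cols)[seq_len(ncol(d))])
  d
}

## genotype dosage matrix -> VCF GT strings vs the ALT allele
gt_strings <- function(dosage_alt) {
  m <- matrix("./.", nrow(dosage_alt), ncol(dosage_alt))
  m[dosage_alt == 0L] <- "0/0"
  m[dosage_alt == 1L] <- "0/1"
  m[dosage_alt == 2L] <- "1/1"
  m
}

#' Write a minimal VCF 4.2 with diploid GT fields
#'
#' @param sites data.table with chrom, pos0, ref, alt (pos0 is 0-based and
#'   written as POS = pos0 + 1)
#' @param geno dosage matrix vs the derived allele is NOT expected here: pass
#'   dosages of the ALT allele (0/1/2, NA = missing); for a haploid sample
#'   pass a one-column matrix with values 0/1 written as haploid GT
#' @param sample_names column names for the samples
#' @param path output path
#' @param contigs data.table with name, length for ##contig headers
#' @param haploid write single-allele GT (for the outgroup)
#' @export
write_vcf <- function(sites, geno, sample_names, path, contigs,
                      haploid = FALSE) {
  stopifnot(nrow(sites) == nrow(geno), ncol(geno) == length(sample_names))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contigs$name,
                   as.integer(contigs$length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  if (haploid) {
    gm <- matrix(as.character(geno), nrow(geno), ncol(geno))
    gm[is.na(geno)] <- "."
  } else {
    gm <- gt_strings(geno)
  }
  body <- data.table(CHROM = sites$chrom, POS = sites$pos0 + 1L, ID = ".",
                     REF = sites$ref, ALT = sites$alt, QUAL = ".",
                     FILTER = "PASS", INFO = ".", FORMAT = "GT")
  body <- cbind(body, as.data.table(gm))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  fwrite(body, path, sep = "\t", quote = FALSE, col.names = FALSE,
         append = TRUE)
  invisible(path)
}

#' Read a VCF into sites plus ALT-dosage genotypes
#'
#' Uses vcfR; biallelic SNVs only. Returns 0-based positions and a dosage
#' matrix of the ALT allele (0/1/2 diploid, 0/1 haploid, NA missing).
#'
#' @param path VCF path
#' @return list(sites = data.table(chrom, pos0, ref, alt), dosage = matrix)
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(v))
  gt <- vcfR::extract.gt(v, element = "GT")
  first <- substr(gt, 1, 1)
  second_sep <- substr(gt, 2, 2)
  second <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  hap <- second_sep == "" | is.na(second_sep)
  d1 <- suppressWarnings(as.integer(first))
  d2 <- suppressWarnings(as.integer(second))
  dos[hap] <- d1[hap]
  dos[!hap] <- d1[!hap] + d2[!hap]
  colnames(dos) <- colnames(gt)
  list(sites = data.table(chrom = fix$CHROM, pos0 = as.integer(fix$POS) - 1L,
                          ref = fix$REF, alt = fix$ALT),
       dosage = dos)
}

#' Write a synthetic dataset to a directory
#'
#' Emits every artifact of a [sim_dataset()] under one directory in standard
#' text formats: VCFs per species group and outgroup, a callable-mask BED,
#' per-species recombination-interval TSVs, the pedigree linkage-map TSV,
#' gene/exon/CNE BEDs, a codon-alignment multi-FASTA, per-gene coding
#' variant/site TSVs, truth tables and a YAML manifest with the seed and a
#' content hash of the configuration.
#'
#' @param dat a `sim_dataset` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dat, dir) {
  need <- c("cfg", "landscape", "variants", "coding")
  miss <- need[!need %in% names(dat)]
  if (length(miss)) {
    stop("dataset is missing component(s): ", paste(miss, collapse = ", "))
  }
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  cfg <- dat$cfg
  contigs <- cfg$chrom_spec
  sites <- dat$variants$sites
  ## ALT dosage = derived dosage if alt == der else flipped
  alt_is_der <- sites$alt == sites$der
  to_alt <- function(m) {
    out <- m
    out[!alt_is_der, ] <- 2L - out[!alt_is_der, , drop = FALSE]
    out
  }
  gA <- cbind(to_alt(dat$variants$geno$A), to_alt(dat$variants$geno$A2))
  gB <- cbind(to_alt(dat$variants$geno$B), to_alt(dat$variants$geno$B2))
  write_vcf(sites, gA,
            c(sprintf("A_%02d", seq_len(ncol(dat$variants$geno$A))),
              sprintf("A2_%02d", seq_len(ncol(dat$variants$geno$A2)))),
            file.path(dir, "groupA.vcf"), contigs)
  write_vcf(sites, gB,
            c(sprintf("B_%02d", seq_len(ncol(dat$variants$geno$B))),
              sprintf("B2_%02d", seq_len(ncol(dat$variants$geno$B2)))),
            file.path(dir, "groupB.vcf"), contigs)
  out_alt <- as.integer(dat$variants$out_allele == sites$alt)
  out_alt[!dat$variants$out_allele %in% c(sites$ref, sites$alt)] <- NA_integer_
  ## third-allele outgroup calls are encoded missing
  third <- dat$variants$out_allele != sites$ref &
    dat$variants$out_allele != sites$alt
  out_alt[third] <- NA_integer_
  write_vcf(sites, matrix(out_alt, ncol = 1), "OUT_01",
            file.path(dir, "outgroup.vcf"), contigs, haploid = TRUE)

  write_bed(dat$variants$mask, file.path(dir, "callable.bed"))
  write_tsv(dat$landscape$intervals_A, file.path(dir, "rho_A.tsv"))
  write_tsv(dat$landscape$intervals_B, file.path(dir, "rho_B.tsv"))
  write_tsv(dat$landscape$linkage_map, file.path(dir, "linkage_map.tsv"))
  write_bed(dat$coding$genes, file.path(dir, "genes.bed"),
            extra_cols = c("gene", "strand"))
  write_bed(dat$coding$exons, file.path(dir, "exons.bed"),
            extra_cols = "gene")
  write_bed(dat$coding$cnes, file.path(dir, "cnes.bed"))
  aln <- dat$coding$alignments
  seqs <- unlist(lapply(names(aln), function(g) {
    setNames(aln[[g]], paste0(g, "|", names(aln[[g]])))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              file.path(dir, "alignments.fasta"))
  write_tsv(dat$coding$coding_variants, file.path(dir, "coding_variants.tsv"))
  write_tsv(dat$coding$coding_sites, file.path(dir, "coding_sites.tsv"))
  write_tsv(dat$coding$genes, file.path(dir, "genes_truth.tsv"))
  write_tsv(dat$landscape$windows, file.path(dir, "windows_truth.tsv"))
  write_tsv(cfg$sweep_truth, file.path(dir, "sweeps_truth.tsv"))
  write_tsv(cfg$peak_truth, file.path(dir, "peaks_truth.tsv"))
  manifest <- list(
    seed = cfg$seed,
    config_hash = config_hash(unclass(cfg)),
    window_bp = cfg$window_bp, theta0 = cfg$theta0,
    n_sites = nrow(sites), n_genes = nrow(dat$coding$genes),
    files = c("groupA.vcf", "groupB.vcf", "outgroup.vcf", "callable.bed",
              "rho_A.tsv", "rho_B.tsv", "linkage_map.tsv", "genes.bed",
              "exons.bed", "cnes.bed", "alignments.fasta",
              "coding_variants.tsv", "coding_sites.tsv", "genes_truth.tsv",
              "windows_truth.tsv", "sweeps_truth.tsv", "peaks_truth.tsv"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a written dataset back into memory
#'
#' @param dir directory produced by [write_dataset()]
#' @return list with manifest, sites/dosage per VCF, mask, rho intervals,
#'   linkage map, gene tables, alignments and truth tables
#' @export
read_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  missing_files <- manifest$files[!file.exists(file.path(dir, manifest$files))]
  if (length(missing_files)) {
    stop("dataset is missing file(s): ", paste(missing_files, collapse = ", "))
  }
  aln_set <- Biostrings::readDNAStringSet(file.path(dir, "alignments.fasta"))
  aln_chr <- as.character(aln_set)
  parts <- strsplit(names(aln_chr), "|", fixed = TRUE)
  aln <- split(setNames(aln_chr, vapply(parts, `[`, "", 2)),
               vapply(parts, `[`, "", 1))
  list(manifest = manifest,
       groupA = read_vcf_dosage(file.path(dir, "groupA.vcf")),
       groupB = read_vcf_dosage(file.path(dir, "groupB.vcf")),
       outgroup = read_vcf_dosage(file.path(dir, "outgroup.vcf")),
       mask = read_bed(file.path(dir, "callable.bed")),
       rho_A = read_tsv(file.path(dir, "rho_A.tsv")),
       rho_B = read_tsv(file.path(dir, "rho_B.tsv")),
       linkage_map = read_tsv(file.path(dir, "linkage_map.tsv")),
       genes = read_tsv(file.path(dir, "genes_truth.tsv")),
       exons = read_bed(file.path(dir, "exons.bed"), extra_cols = "gene"),
       cnes = read_bed(file.path(dir, "cnes.bed")),
       alignments = aln,
       coding_variants = read_tsv(file.path(dir, "coding_variants.tsv")),
       coding_sites = read_tsv(file.path(dir, "coding_sites.tsv")),
       windows_truth = read_tsv(file.path(dir, "windows_truth.tsv")),
       sweeps_truth = read_tsv(file.path(dir, "sweeps_truth.tsv")),
       peaks_truth = read_tsv(file.path(dir, "peaks_truth.tsv")))
}
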