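## Internal helpers shared across modules.
## Coordinate convention: 0-based half-open [start, end) everywhere in memory;
## conversion to 1-based happens only at the VCF boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a master seed
#'
#' Deterministic integer hash used to give every stochastic stage of the
#' pipeline its own stream while remaining a pure function of the master seed.
#' Kept strictly below 2^31 so it is always a valid R integer seed.
#'
#' @param seed master seed (integer-like scalar)
#' @param k stage offset (integer-like scalar)
#' @return an integer in [0, 2^31 - 2]
#' @export
stage_seed <- function(seed, k = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + 97 * (as.numeric(k) + 1)
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647L), code)
}

## assert that intervals in dt (cols start, end) are sorted and non-overlapping
## within each chromosome
check_disjoint_sorted <- function(dt, what = "intervals",
                                  start_col = "start", end_col = "end") {
  dt <- as.data.table(dt)
  s_all <- dt[[start_col]]
  e_all <- dt[[end_col]]
  bad <- dt[, {
    s <- s_all[.I]; e <- e_all[.I]
    any(e <= s) || is.unsorted(s) || any(s[-1] < e[-length(e)])
  }, by = chrom]$V1
  if (any(bad)) {
    stop(sprintf("%s must be sorted, non-empty and non-overlapping within each chromosome", what))
  }
  invisible(TRUE)
}

## total bp of intersection of two disjoint interval sets (data.tables with
## chrom/start/end), returned per 'by' interval of `targets` as a vector
interval_overlap_bp <- function(src, targets) {
  src <- as.data.table(src)[, .(chrom, start, end)]
  tg <- as.data.table(targets)[, .(chrom, start, end)]
  tg[, idx__ := .I]
  setkey(src, chrom, start, end)
  ov <- foverlaps(tg, src, by.x = c("chrom", "start", "end"), nomatch = NULL)
  ov[, overlap_bp := pmin(end, i.end) - pmax(start, i.start)]
  res <- ov[overlap_bp > 0, .(bp = sum(overlap_bp)), by = idx__]
  out <- numeric(nrow(tg))
  out[res$idx__] <- res$bp
  out
}

## fixed windows tiling each chromosome from 0; trailing partial windows kept
#' Tile chromosomes with fixed windows
#'
#' Windows start at coordinate 0 and the trailing partial window is kept with
#' its true (shorter) length. Coordinates are 0-based half-open.
#'
#' @param chrom_spec data.frame with columns `name`, `length` (bp) and
#'   optionally `class` (e.g. macro/micro)
#' @param window_bp window size in bp
#' @return data.table with chrom, start, end, window index and chromosome class
#' @export
make_windows <- function(chrom_spec, window_bp = 200000L) {
  stopifnot(window_bp > 0)
  cs <- as.data.table(chrom_spec)
  if (!"class" %in% names(cs)) cs[, class := NA_character_]
  out <- cs[, {
    s <- seq(0L, max(0L, length - 1L), by = as.integer(window_bp))
    .(start = s, end = pmin(s + as.integer(window_bp), length), class = class)
  }, by = .(chrom = name)]
  out[, window := seq_len(.N) - 1L, by = chrom]
  out[]
}

## simple deterministic hash of an R object (content hash for manifests)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  ## serialize version 2 for stability across sessions
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
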