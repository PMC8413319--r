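# Exclusion of genomic regions anchored at sentinel variants (e.g. the
# smoking-behavior loci removed at +/- 500 kb in confounding-sensitivity
# passes). Coordinates are 1-based and inclusive on both ends; interval
# arithmetic is delegated to GenomicRanges.

#' Read a sentinel-variant list
#'
#' @param path TSV/whitespace-delimited file with header columns snp_id (or
#'   SNP), chrom (or CHR) and bp (or BP).
#' @param provenance free-text source label.
#' @return object of class `sentinels`: data.frame with columns `snp_id`,
#'   `chrom`, `bp`.
#' @export
read_sentinels <- function(path, provenance = path) {
  con <- open_input(path)
  on.exit(close(con))
  raw <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE)
  lc <- tolower(names(raw))
  pick <- function(alts) {
    i <- which(lc %in% alts)[1]
    if (is.na(i)) stop("sentinel file lacks a ", alts[1], " column", call. = FALSE)
    raw[[i]]
  }
  sentinel_list(data.frame(snp_id = as.character(pick(c("snp_id", "snp", "rsid"))),
                           chrom = as.character(pick(c("chrom", "chr"))),
                           bp = as.integer(pick(c("bp", "pos"))),
                           stringsAsFactors = FALSE),
                provenance = provenance)
}

#' Construct a sentinel-variant list
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `bp` (bp >= 1).
#' @param provenance free-text source label.
#' @return object of class `sentinels`.
#' @export
sentinel_list <- function(df, provenance = "") {
  stopifnot(all(c("snp_id", "chrom", "bp") %in% names(df)))
  if (any(df$bp < 1)) stop("sentinel positions must be >= 1", call. = FALSE)
  df <- df[snp_order(df$chrom, df$bp), c("snp_id", "chrom", "bp"), drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("sentinels", "data.frame"))
}

#' Build merged exclusion regions around sentinel variants
#'
#' One region per sentinel, [bp - flank_kb*1000, bp + flank_kb*1000],
#' clamped below at 1; overlapping or book-ended regions on the same
#' chromosome are merged.
#'
#' @param sentinels a [sentinel_list] (or data.frame with `chrom`, `bp`).
#' @param flank_kb flank in kilobases on each side (default 500).
#' @return object of class `genomic_regions`: data.frame with columns
#'   `chrom`, `start`, `end` (1-based, inclusive), sorted and disjoint.
#' @export
build_exclusion_regions <- function(sentinels, flank_kb = 500) {
  if (flank_kb < 0) stop("flank_kb must be >= 0", call. = FALSE)
  flank <- flank_kb * 1000
  gr <- GenomicRanges::GRanges(
    seqnames = sentinels$chrom,
    ranges = IRanges::IRanges(start = pmax(1, sentinels$bp - flank),
                              end = sentinels$bp + flank))
  gr <- GenomicRanges::reduce(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  df <- df[snp_order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("genomic_regions", "data.frame"))
}

#' Remove SNPs falling inside exclusion regions
#'
#' A SNP is removed when some region matches its chromosome and
#' start <= bp <= end (both bounds inclusive). Sentinels are matched by
#' coordinates, not identifiers, so the filter is agnostic to SNP naming.
#' SNPs with unknown coordinates are retained.
#'
#' @param x a [sumstats] table.
#' @param regions a [build_exclusion_regions()] result (or data.frame with
#'   `chrom`, `start`, `end`).
#' @return list with `table` (filtered [sumstats]) and `removed` (count).
#' @export
apply_exclusion <- function(x, regions) {
  if (!nrow(regions) || !nrow(x))
    return(list(table = x, removed = 0L))
  known <- which(!is.na(x$chrom) & !is.na(x$bp))
  hit <- integer(0)
  if (length(known)) {
    snps <- GenomicRanges::GRanges(
      seqnames = x$chrom[known],
      ranges = IRanges::IRanges(start = x$bp[known], width = 1L))
    reg <- GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(start = regions$start, end = regions$end))
    hits <- GenomicRanges::countOverlaps(snps, reg)
    hit <- known[hits > 0L]
  }
  removed <- length(hit)
  out <- if (removed) x[-hit, , drop = FALSE] else x
  rownames(out) <- NULL
  list(table = out, removed = removed)
}

#' Export exclusion regions as BED
#'
#' BED is 0-based half-open; the 1-based inclusive regions are converted at
#' this boundary (start - 1, end unchanged) and the file header notes it.
#'
#' @param regions a `genomic_regions` data.frame.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  con <- open_output(path)
  on.exit(close(con))
  writeLines(paste("# BED 0-based half-open; converted from 1-based",
                   "inclusive exclusion regions"), con)
  utils::write.table(data.frame(regions$chrom, regions$start - 1L, regions$end),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
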