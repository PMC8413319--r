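# LD scores: per-SNP sums of squared allelic correlations over a physical
# window, computed from a reference genotype panel or read from the
# CHR/SNP/BP/L2 table dialect.

#' Construct a reference genotype panel
#'
#' @param genotypes numeric matrix of allele dosages in [0, 2], individuals
#'   in rows and SNPs in columns.
#' @param snp_id,chrom,bp per-SNP metadata aligned to the columns.
#' @return object of class `ref_panel`. SNPs with zero dosage variance are
#'   rejected (their correlation with anything is undefined); metadata is
#'   sorted by (chromosome, position) with columns reordered to match.
#' @export
reference_panel <- function(genotypes, snp_id, chrom, bp) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (length(snp_id) != m || length(chrom) != m || length(bp) != m)
    stop("SNP metadata length does not match genotype columns", call. = FALSE)
  if (min(genotypes) < 0 || max(genotypes) > 2)
    stop("dosages must lie in [0, 2]", call. = FALSE)
  v <- apply(genotypes, 2L, stats::var)
  if (any(v == 0))
    stop(sum(v == 0), " monomorphic SNPs in the panel; remove them first",
         call. = FALSE)
  ord <- snp_order(chrom, bp)
  structure(list(genotypes = genotypes[, ord, drop = FALSE],
                 snp_id = as.character(snp_id)[ord],
                 chrom = as.character(chrom)[ord],
                 bp = as.integer(bp)[ord],
                 n_ref = nrow(genotypes)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("Reference panel: ", x$n_ref, " individuals x ", length(x$snp_id),
      " SNPs on ", length(unique(x$chrom)), " chromosomes\n", sep = "")
  invisible(x)
}

#' Construct an LD score table
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `bp`, `l2`.
#' @param m_ref reference SNP count M underlying the table; must be at
#'   least the number of rows. M, not the regression SNP count, scales the
#'   regression slope to heritability.
#' @return object of class `ldscores`.
#' @export
ld_scores <- function(df, m_ref = nrow(df)) {
  req <- c("snp_id", "chrom", "bp", "l2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$l2)) || any(df$l2 <= 0))
    stop("LD scores must be positive and finite", call. = FALSE)
  if (m_ref < nrow(df))
    stop("m_ref cannot be smaller than the number of scored SNPs", call. = FALSE)
  df <- df[snp_order(df$chrom, df$bp), req, drop = FALSE]
  rownames(df) <- NULL
  structure(df, m_ref = as.numeric(m_ref), class = c("ldscores", "data.frame"))
}

#' @export
print.ldscores <- function(x, ...) {
  cat("LD scores: ", nrow(x), " SNPs, M = ", attr(x, "m_ref"),
      ", mean l2 = ", round(mean(x$l2), 3), "\n", sep = "")
  invisible(x)
}

#' Compute LD scores from a reference panel
#'
#' For SNP j the LD score is the sum over all SNPs k on the same chromosome
#' within `window_kb` kilobases (including j itself) of the bias-adjusted
#' squared correlation r2_adj = r2 - (1 - r2) / (n_ref - 2), where r is the
#' sample correlation of dosages. The self term contributes exactly 1 and
#' is never adjusted. Negative adjusted cross terms are retained so the sum
#' stays unbiased; scores can therefore dip slightly below 1 for isolated
#' SNPs but are floored at a tiny positive value to preserve the positivity
#' invariant.
#'
#' @param panel a [reference_panel].
#' @param window_kb physical half-window in kilobases (default 1000, i.e.
#'   +/- 1 Mb).
#' @param chunk_size internal column chunking for the correlation products.
#' @return an [ld_scores] table with `m_ref` equal to the panel SNP count.
#' @export
compute_ld_scores <- function(panel, window_kb = 1000, chunk_size = 1000L) {
  if (!inherits(panel, "ref_panel")) stop("panel must be a reference_panel")
  if (window_kb <= 0) stop("window_kb must be positive", call. = FALSE)
  n <- panel$n_ref
  if (n < 3L) stop("need at least 3 reference individuals", call. = FALSE)
  window_bp <- window_kb * 1000
  m <- length(panel$snp_id)
  l2 <- numeric(m)
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    X <- scale(panel$genotypes[, idx, drop = FALSE])
    bp <- panel$bp[idx]
    mc <- length(idx)
    for (lo in seq(1L, mc, by = chunk_size)) {
      hi <- min(lo + chunk_size - 1L, mc)
      r <- crossprod(X[, lo:hi, drop = FALSE], X) / (n - 1)
      r2 <- r * r
      adj <- r2 - (1 - r2) / (n - 2)
      inwin <- abs(outer(bp[lo:hi], bp, "-")) <= window_bp
      adj[!inwin] <- 0
      # self term: unadjusted, exactly 1
      for (i in seq_len(hi - lo + 1L)) adj[i, lo + i - 1L] <- 1
      l2[idx[lo:hi]] <- rowSums(adj)
    }
  }
  ld_scores(data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                       bp = panel$bp, l2 = pmax(l2, 1e-8),
                       stringsAsFactors = FALSE),
            m_ref = m)
}

#' Read an LD score table
#'
#' Expects a delimited file with header columns CHR, SNP, BP, L2
#' (case-insensitive). The reference SNP count M is taken from `m_ref` if
#' given, else from a companion count file (`m_file`, or the input path
#' with its `.ldscore[.gz]` suffix replaced by `.M` when such a file
#' exists), else it defaults to the row count.
#'
#' @param path ldscore file path (".gz" transparent).
#' @param m_file optional path of a one-number SNP-count file.
#' @param m_ref optional explicit M.
#' @return an [ld_scores] table.
#' @export
load_ld_scores <- function(path, m_file = NULL, m_ref = NULL) {
  con <- open_input(path)
  on.exit(close(con))
  raw <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  lc <- tolower(names(raw))
  pick <- function(nm) {
    i <- match(nm, lc)
    if (is.na(i)) stop("LD score file lacks a ", toupper(nm), " column: ",
                       path, call. = FALSE)
    raw[[i]]
  }
  l2_raw <- pick("l2")
  l2 <- suppressWarnings(as.numeric(l2_raw))
  if (anyNA(l2)) {
    bad <- which(is.na(l2))[1L]
    stop("non-numeric L2 value '", l2_raw[bad], "' at data row ", bad,
         " of ", path, call. = FALSE)
  }
  if (is.null(m_ref)) {
    if (is.null(m_file)) {
      cand <- sub("\\.ldscore(\\.gz)?$", ".M", path)
      if (cand != path && file.exists(cand)) m_file <- cand
    }
    m_ref <- if (!is.null(m_file)) as.numeric(readLines(m_file, n = 1L))
             else nrow(raw)
  }
  ld_scores(data.frame(snp_id = as.character(pick("snp")),
                       chrom = as.character(pick("chr")),
                       bp = as.integer(pick("bp")), l2 = l2,
                       stringsAsFactors = FALSE),
            m_ref = m_ref)
}

#' Write an LD score table and its SNP-count companion
#'
#' Writes `<prefix>.l2.ldscore` (tab-delimited CHR SNP BP L2) and
#' `<prefix>.l2.M` holding the reference SNP count.
#'
#' @param x an [ld_scores] table.
#' @param prefix output path prefix.
#' @param gzip write the score table gzip-compressed.
#' @return the ldscore file path, invisibly.
#' @export
write_ld_scores <- function(x, prefix, gzip = FALSE) {
  path <- paste0(prefix, ".l2.ldscore", if (gzip) ".gz" else "")
  df <- data.frame(CHR = x$chrom, SNP = x$snp_id, BP = x$bp,
                   L2 = sprintf("%.17g", x$l2), stringsAsFactors = FALSE)
  con <- open_output(path)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  writeLines(sprintf("%.17g", attr(x, "m_ref")), paste0(prefix, ".l2.M"))
  invisible(path)
}
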