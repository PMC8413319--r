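# GWAS summary statistics: reading, validation, filtering, pairwise
# harmonization. One table = one trait, one row per SNP.

.sumstats_aliases <- list(
  snp_id = c("snp", "snp_id", "snpid", "rsid", "markername", "id"),
  chrom  = c("chr", "chrom", "chromosome"),
  bp     = c("bp", "pos", "position", "base_pair"),
  a1     = c("a1", "effect_allele", "allele1"),
  a2     = c("a2", "other_allele", "allele2", "allele0"),
  z      = c("z", "zscore", "z_score"),
  beta   = c("beta", "b", "effect", "log_odds"),
  se     = c("se", "stderr", "standard_error"),
  n      = c("n", "nobs", "sample_size", "neff"),
  maf    = c("maf", "frq", "freq", "eaf", "af"),
  info   = c("info", "info_score", "imputation_quality")
)

.resolve_columns <- function(header, column_map) {
  lc <- tolower(header)
  out <- list()
  for (field in names(.sumstats_aliases)) {
    src <- NULL
    if (!is.null(column_map) && field %in% names(column_map)) {
      src <- column_map[[field]]
      if (!src %in% header)
        stop("column_map names '", src, "' for field '", field,
             "' but the file has no such column", call. = FALSE)
    } else {
      hit <- which(lc %in% .sumstats_aliases[[field]])
      if (length(hit)) src <- header[hit[1L]]
    }
    if (!is.null(src)) out[[field]] <- src
  }
  out
}

#' Construct a summary-statistics table
#'
#' Low-level constructor used by [read_sumstats()] and the simulator. Rows
#' are per-SNP association records for one trait; the table is sorted by
#' (chromosome, position) and SNP identifiers must be unique.
#'
#' @param df data.frame with columns `snp_id`, `a1`, `a2`, `z`, `n` and
#'   optionally `chrom`, `bp`, `maf`, `info`. Alleles must be single
#'   characters in A/C/G/T with `a1 != a2`; `maf`, when present, must lie in
#'   (0, 0.5]; `n` must be positive. `chrom`/`bp` may be `NA` (e.g. tables
#'   read from the minimal SNP/A1/A2/Z/N dialect); positional operations
#'   then rely on an LD score table to supply coordinates.
#' @param trait_id character label for the trait.
#' @param provenance free-text source label.
#' @return object of class `sumstats` (a data.frame with attributes
#'   `trait_id` and `provenance`).
#' @export
sumstats <- function(df, trait_id, provenance = "") {
  req <- c("snp_id", "a1", "a2", "z", "n")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"chrom" %in% names(df)) df$chrom <- NA_character_
  if (!"bp" %in% names(df)) df$bp <- NA_integer_
  if (!"maf" %in% names(df)) df$maf <- NA_real_
  if (!"info" %in% names(df)) df$info <- NA_real_
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$bp <- as.integer(df$bp)
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id values; drop them before construction", call. = FALSE)
  bad <- !(df$a1 %in% c("A", "C", "G", "T")) | !(df$a2 %in% c("A", "C", "G", "T")) |
    df$a1 == df$a2
  if (any(bad))
    stop(sum(bad), " rows have invalid or identical alleles", call. = FALSE)
  if (any(!is.na(df$maf) & (df$maf <= 0 | df$maf > 0.5)))
    stop("maf values must lie in (0, 0.5]", call. = FALSE)
  if (any(df$n <= 0))
    stop("n must be positive", call. = FALSE)
  df <- df[snp_order(df$chrom, df$bp),
           c("snp_id", "chrom", "bp", "a1", "a2", "z", "n", "maf", "info"),
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, trait_id = as.character(trait_id),
            provenance = as.character(provenance),
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for trait '", attr(x, "trait_id"), "'\n", sep = "")
  cat("  ", nrow(x), " SNPs; mean N = ", round(mean(x$n), 1), "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a whitespace- or tab-delimited file with a header. Common column
#' names (including the minimal SNP/A1/A2/Z/N dialect used by LD score
#' regression tools) are auto-recognized; `column_map` overrides the
#' auto-mapping. When a Z column is absent, Z is computed as beta / se.
#' Rows with missing required fields, invalid alleles or se = 0 are dropped
#' and counted; all copies of a duplicated SNP identifier are dropped
#' because its identity is ambiguous.
#'
#' @param path file path (".gz" transparent).
#' @param trait_id label for the trait.
#' @param column_map optional named character vector mapping field names
#'   (`snp_id`, `chrom`, `bp`, `a1`, `a2`, `z`, `beta`, `se`, `n`, `maf`,
#'   `info`) to column names in the file.
#' @param n scalar study sample size, broadcast when the file lacks an N
#'   column.
#' @param provenance free-text source label (defaults to the path).
#' @return a [sumstats] table. Attribute `read_audit` records counts of
#'   rows dropped at each step (`n_rows`, `n_dropped_missing`,
#'   `n_dropped_se_zero`, `n_dropped_bad_alleles`, `n_dropped_duplicates`).
#' @export
read_sumstats <- function(path, trait_id, column_map = NULL, n = NULL,
                          provenance = path) {
  con <- open_input(path)
  on.exit(close(con))
  raw <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!nrow(raw)) stop("empty summary-statistics file: ", path, call. = FALSE)
  cols <- .resolve_columns(names(raw), column_map)
  for (field in c("snp_id", "a1", "a2"))
    if (is.null(cols[[field]]))
      stop("cannot resolve required column '", field, "' in ", path, call. = FALSE)
  if (is.null(cols$z) && (is.null(cols$beta) || is.null(cols$se)))
    stop("need either a Z column or both beta and se columns in ", path,
         call. = FALSE)
  if (is.null(cols$n) && is.null(n))
    stop("no N column and no scalar n supplied for ", path, call. = FALSE)

  df <- data.frame(snp_id = as.character(raw[[cols$snp_id]]),
                   a1 = toupper(as.character(raw[[cols$a1]])),
                   a2 = toupper(as.character(raw[[cols$a2]])),
                   stringsAsFactors = FALSE)
  df$chrom <- if (!is.null(cols$chrom)) as.character(raw[[cols$chrom]]) else NA_character_
  df$bp <- if (!is.null(cols$bp)) as.integer(raw[[cols$bp]]) else NA_integer_
  n_se_zero <- 0L
  if (!is.null(cols$z)) {
    df$z <- as.numeric(raw[[cols$z]])
  } else {
    beta <- as.numeric(raw[[cols$beta]])
    se <- as.numeric(raw[[cols$se]])
    zero <- !is.na(se) & se == 0
    n_se_zero <- sum(zero)
    se[zero] <- NA_real_
    df$z <- beta / se
  }
  df$n <- if (!is.null(cols$n)) as.numeric(raw[[cols$n]]) else as.numeric(n)
  freq <- if (!is.null(cols$maf)) as.numeric(raw[[cols$maf]]) else NA_real_
  df$maf <- pmin(freq, 1 - freq)  # fold allele frequencies onto (0, 0.5]
  df$info <- if (!is.null(cols$info)) as.numeric(raw[[cols$info]]) else NA_real_

  n_rows <- nrow(df)
  ok <- !is.na(df$snp_id) & df$snp_id != "" & !is.na(df$z) & !is.na(df$n) & df$n > 0
  n_missing <- sum(!ok) - n_se_zero
  df <- df[ok, , drop = FALSE]
  bad_allele <- !(df$a1 %in% c("A", "C", "G", "T")) |
    !(df$a2 %in% c("A", "C", "G", "T")) | df$a1 == df$a2
  n_bad <- sum(bad_allele)
  df <- df[!bad_allele, , drop = FALSE]
  dup <- df$snp_id %in% df$snp_id[duplicated(df$snp_id)]
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  if (!nrow(df)) stop("no usable rows after validation in ", path, call. = FALSE)

  out <- sumstats(df, trait_id = trait_id, provenance = provenance)
  attr(out, "read_audit") <- list(n_rows = n_rows,
                                  n_dropped_missing = n_missing,
                                  n_dropped_se_zero = n_se_zero,
                                  n_dropped_bad_alleles = n_bad,
                                  n_dropped_duplicates = n_dup)
  out
}

#' Write summary statistics in the minimal SNP/A1/A2/Z/N dialect
#'
#' Chromosome, position, MAF and INFO columns are appended when present so
#' that tables written by this package round-trip losslessly.
#'
#' @param x a [sumstats] table.
#' @param path output path (".gz" transparent).
#' @export
write_sumstats <- function(x, path) {
  df <- data.frame(SNP = x$snp_id, A1 = x$a1, A2 = x$a2,
                   Z = sprintf("%.17g", x$z), N = sprintf("%.17g", x$n),
                   stringsAsFactors = FALSE)
  if (any(!is.na(x$chrom))) { df$CHR <- x$chrom; df$BP <- x$bp }
  if (any(!is.na(x$maf)))  df$MAF <- sprintf("%.17g", x$maf)
  if (any(!is.na(x$info))) df$INFO <- sprintf("%.17g", x$info)
  con <- open_output(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Retains autosomal SNPs with minor allele frequency strictly greater than
#' `maf_min` and imputation INFO strictly greater than `info_min` (strict
#' inequalities, matching the convention "greater than 0.01" / "greater
#' than 0.90"), optionally restricted to a SNP whitelist such as a
#' well-imputed reference panel list. Rows lacking MAF or INFO while the
#' corresponding threshold is active are dropped under
#' `missing_policy = "drop"` (the conservative default) or kept under
#' `"keep"`. Rows with unknown chromosome are not subject to the autosome
#' filter.
#'
#' @param x a [sumstats] table.
#' @param maf_min minor-allele-frequency threshold (strict), or `NULL` to
#'   disable. Default 0.01.
#' @param info_min INFO threshold (strict), or `NULL` to disable.
#'   Default 0.90.
#' @param snplist optional character vector of SNP ids to retain.
#' @param missing_policy `"drop"` or `"keep"` for rows missing maf/info.
#' @return list with elements `table` (filtered [sumstats]) and `audit`
#'   (counts `n_input`, `n_after_autosome`, `n_after_maf`, `n_after_info`,
#'   `n_after_snplist`, `n_dropped_duplicates` — duplicates are removed at
#'   read time, so the last is 0 here and carried for completeness).
#' @export
filter_snps <- function(x, maf_min = 0.01, info_min = 0.90, snplist = NULL,
                        missing_policy = c("drop", "keep")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.null(maf_min) && (maf_min < 0 || maf_min > 1))
    stop("maf_min must lie in [0, 1]", call. = FALSE)
  if (!is.null(info_min) && (info_min < 0 || info_min > 1))
    stop("info_min must lie in [0, 1]", call. = FALSE)
  n_input <- nrow(x)
  keep <- is.na(x$chrom) | x$chrom %in% as.character(1:22)
  x <- x[keep, , drop = FALSE]
  n_autosome <- nrow(x)
  if (!is.null(maf_min)) {
    ok <- if (missing_policy == "drop") !is.na(x$maf) & x$maf > maf_min
          else is.na(x$maf) | x$maf > maf_min
    x <- x[ok, , drop = FALSE]
  }
  n_maf <- nrow(x)
  if (!is.null(info_min)) {
    ok <- if (missing_policy == "drop") !is.na(x$info) & x$info > info_min
          else is.na(x$info) | x$info > info_min
    x <- x[ok, , drop = FALSE]
  }
  n_info <- nrow(x)
  if (!is.null(snplist)) x <- x[x$snp_id %in% snplist, , drop = FALSE]
  n_snplist <- nrow(x)
  rownames(x) <- NULL
  list(table = x,
       audit = list(n_input = n_input, n_after_autosome = n_autosome,
                    n_after_maf = n_maf, n_after_info = n_info,
                    n_after_snplist = n_snplist, n_dropped_duplicates = 0L))
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Allele-align two summary-statistics tables
#'
#' Intersects two tables on SNP id and aligns trait-2 Z scores to trait 1's
#' effect allele: when trait 2 reports swapped alleles the Z sign is
#' flipped; strand-complement reports (e.g. A/G vs T/C) are reconciled by
#' complementing before comparison. Strand-ambiguous SNPs (A/T or C/G, in
#' either table) are dropped because a strand flip is indistinguishable
#' from an allele swap; irreconcilable allele pairs are dropped too. Both
#' drop counts are recorded.
#'
#' @param a,b [sumstats] tables (already quality-filtered).
#' @return object of class `merged_pair`: a data.frame with columns
#'   `snp_id`, `chrom`, `bp`, `z1`, `z2`, `n1`, `n2`, sorted by
#'   (chromosome, position), with attributes `trait_ids`, `n_ambiguous`,
#'   `n_mismatch`.
#' @export
harmonize_pair <- function(a, b) {
  ia <- match(b$snp_id, a$snp_id)
  keep_b <- which(!is.na(ia))
  if (!length(keep_b))
    stop("no shared SNPs between traits '", attr(a, "trait_id"), "' and '",
         attr(b, "trait_id"), "'", call. = FALSE)
  A <- a[ia[keep_b], , drop = FALSE]
  B <- b[keep_b, , drop = FALSE]

  amb <- .complement[A$a1] == A$a2 | .complement[B$a1] == B$a2
  same <- A$a1 == B$a1 & A$a2 == B$a2
  swap <- A$a1 == B$a2 & A$a2 == B$a1
  csame <- A$a1 == .complement[B$a1] & A$a2 == .complement[B$a2]
  cswap <- A$a1 == .complement[B$a2] & A$a2 == .complement[B$a1]
  match_ok <- (same | swap | csame | cswap) & !amb
  flip <- (swap | cswap) & match_ok

  n_ambiguous <- sum(amb)
  n_mismatch <- sum(!(same | swap | csame | cswap))
  A <- A[match_ok, , drop = FALSE]
  B <- B[match_ok, , drop = FALSE]
  if (!nrow(A))
    stop("no reconcilable SNPs between traits '", attr(a, "trait_id"),
         "' and '", attr(b, "trait_id"), "'", call. = FALSE)
  z2 <- ifelse(flip[match_ok], -B$z, B$z)

  chrom <- ifelse(is.na(A$chrom), B$chrom, A$chrom)
  bp <- ifelse(is.na(A$bp), B$bp, A$bp)
  out <- data.frame(snp_id = A$snp_id, chrom = chrom, bp = bp,
                    z1 = A$z, z2 = z2, n1 = A$n, n2 = B$n,
                    stringsAsFactors = FALSE)
  out <- out[snp_order(out$chrom, out$bp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_ids = c(attr(a, "trait_id"), attr(b, "trait_id")),
            n_ambiguous = n_ambiguous, n_mismatch = n_mismatch,
            class = c("merged_pair", "data.frame"))
}

#' @export
print.merged_pair <- function(x, ...) {
  ids <- attr(x, "trait_ids")
  cat("Harmonized SNP set: '", ids[1], "' x '", ids[2], "'\n", sep = "")
  cat("  ", nrow(x), " shared SNPs (", attr(x, "n_ambiguous"),
      " strand-ambiguous and ", attr(x, "n_mismatch"),
      " irreconcilable dropped)\n", sep = "")
  invisible(x)
}
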