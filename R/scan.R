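# Multi-trait scan driver: every trait x outcome stratum x pass
# (all SNPs / smoking-region-excluded), with family-wise Bonferroni
# control over the total comparison count.

#' Define a cross-trait scan
#'
#' @param traits named list of [sumstats] tables (or a character vector of
#'   trait ids when only the design arithmetic is needed).
#' @param outcomes named list of [sumstats] tables (or character ids), e.g.
#'   overall disease risk plus histological or exposure strata.
#' @param passes subset of `c("all", "smoking_excluded")`.
#' @param alpha family-wise error rate in (0, 1). Default 0.05.
#' @return object of class `scan_design`.
#' @export
scan_design <- function(traits, outcomes,
                        passes = c("all", "smoking_excluded"), alpha = 0.05) {
  passes <- match.arg(passes, several.ok = TRUE)
  if (!length(traits) || !length(outcomes))
    stop("need at least one trait and one outcome", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  label <- function(x, prefix) {
    if (is.character(x)) { nm <- x; x <- as.list(x); names(x) <- nm; return(x) }
    if (is.null(names(x)))
      names(x) <- vapply(seq_along(x), function(i)
        attr(x[[i]], "trait_id") %||% paste0(prefix, i), character(1))
    x
  }
  structure(list(traits = label(traits, "trait"),
                 outcomes = label(outcomes, "outcome"),
                 passes = passes, alpha = alpha),
            class = "scan_design")
}

#' Comparison counts for a scan design
#'
#' @param design a [scan_design].
#' @return list with `n_tests_per_pass` (traits x outcomes) and `n_total`
#'   (x number of passes). With 347 traits, 6 outcome strata and both
#'   passes this gives 2082 tests per pass and 4164 comparisons in total.
#' @export
count_comparisons <- function(design) {
  per_pass <- length(design$traits) * length(design$outcomes)
  list(n_tests_per_pass = per_pass,
       n_total = per_pass * length(design$passes))
}

#' Bonferroni significance cutoff
#'
#' @param alpha family-wise error rate.
#' @param n_total total number of comparisons (>= 1).
#' @return list with `cutoff` = alpha / n_total and `neglog10` =
#'   -log10(cutoff).
#' @export
bonferroni_threshold <- function(alpha, n_total) {
  if (n_total < 1) stop("n_total must be >= 1", call. = FALSE)
  cutoff <- alpha / n_total
  list(cutoff = cutoff, neglog10 = -log10(cutoff))
}

.scan_na_row <- function() {
  list(n_snps = NA_integer_, gencov = NA_real_, gencov_se = NA_real_,
       rg = NA_real_, rg_se = NA_real_, z_stat = NA_real_, p = NA_real_,
       intercept12 = NA_real_, intercept12_se = NA_real_,
       h2_trait = NA_real_, h2_trait_se = NA_real_,
       h2_outcome = NA_real_, h2_outcome_se = NA_real_)
}

#' Run the full cross-trait scan
#'
#' For every (trait, outcome, pass) triple: apply region exclusion when the
#' pass demands it, harmonize the pair, estimate the genetic correlation,
#' and flag Bonferroni significance against alpha / n_total with n_total
#' the comparison count across all enabled passes. Outcome (and trait)
#' heritability is estimated once per (table, pass) and reused across
#' pairs. A failing pair yields a flagged row, never an aborted scan, so
#' the comparison count stays auditable.
#'
#' @param design a [scan_design] whose traits/outcomes are [sumstats].
#' @param ld an [ld_scores] table.
#' @param sentinels a [sentinel_list] (required when the design includes
#'   the `smoking_excluded` pass).
#' @param cfg an [ldsr_config].
#' @param flank_kb flank for [build_exclusion_regions()]. Default 500.
#' @return object of class `ldsc_scan`: data.frame with one row per
#'   comparison in deterministic (trait, outcome, pass) order and
#'   attributes `alpha`, `n_tests_per_pass`, `n_total`, `cutoff`.
#' @export
run_scan <- function(design, ld, sentinels = NULL, cfg = ldsr_config(),
                     flank_kb = 500) {
  counts <- count_comparisons(design)
  cutoff <- bonferroni_threshold(design$alpha, counts$n_total)$cutoff
  regions <- NULL
  if ("smoking_excluded" %in% design$passes) {
    if (is.null(sentinels))
      stop("smoking_excluded pass requested but no sentinels given", call. = FALSE)
    regions <- build_exclusion_regions(sentinels, flank_kb = flank_kb)
  }
  prep <- function(tbl, pass) {
    if (pass == "smoking_excluded") apply_exclusion(tbl, regions)$table else tbl
  }
  safe_h2 <- function(tbl) {
    tryCatch(estimate_h2(tbl, ld, cfg), error = function(e) NULL)
  }
  # one h2 fit per (table, pass), reused across pairs
  h2_cache <- list()
  for (pass in design$passes) {
    for (nm in names(design$traits))
      h2_cache[[paste("t", nm, pass)]] <- safe_h2(prep(design$traits[[nm]], pass))
    for (nm in names(design$outcomes))
      h2_cache[[paste("o", nm, pass)]] <- safe_h2(prep(design$outcomes[[nm]], pass))
  }

  rows <- vector("list", counts$n_total)
  k <- 0L
  for (tnm in names(design$traits)) {
    for (onm in names(design$outcomes)) {
      for (pass in design$passes) {
        k <- k + 1L
        row <- .scan_na_row()
        note <- "ok"
        fit <- tryCatch({
          pair <- harmonize_pair(prep(design$traits[[tnm]], pass),
                                 prep(design$outcomes[[onm]], pass))
          estimate_rg(pair, ld, cfg)
        }, error = function(e) conditionMessage(e))
        if (is.character(fit)) {
          note <- paste("failed:", fit)
        } else {
          row[c("n_snps", "gencov", "gencov_se", "rg", "rg_se", "z_stat",
                "p", "intercept12", "intercept12_se")] <-
            fit[c("n_snps", "gencov", "gencov_se", "rg", "rg_se", "z_stat",
                  "p", "intercept12", "intercept12_se")]
          if (fit$flag != "ok") note <- fit$flag
        }
        ht <- h2_cache[[paste("t", tnm, pass)]]
        ho <- h2_cache[[paste("o", onm, pass)]]
        if (!is.null(ht)) { row$h2_trait <- ht$h2; row$h2_trait_se <- ht$h2_se }
        if (!is.null(ho)) { row$h2_outcome <- ho$h2; row$h2_outcome_se <- ho$h2_se }
        rows[[k]] <- data.frame(trait_id = tnm, outcome_id = onm,
                                pass = pass, row,
                                significant = !is.na(row$p) && row$p < cutoff,
                                note = note, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, alpha = design$alpha,
            n_tests_per_pass = counts$n_tests_per_pass,
            n_total = counts$n_total, cutoff = cutoff,
            class = c("ldsc_scan", "data.frame"))
}

#' @export
print.ldsc_scan <- function(x, ...) {
  cat("Cross-trait scan: ", nrow(x), " comparisons, Bonferroni cutoff ",
      format(attr(x, "cutoff"), digits = 3), " (alpha = ", attr(x, "alpha"),
      ", -log10 = ", round(-log10(attr(x, "cutoff")), 2), ")\n", sep = "")
  cat("  significant: ", sum(x$significant, na.rm = TRUE), "\n", sep = "")
  print(utils::head(as.data.frame(x)[, c("trait_id", "outcome_id", "pass",
                                         "rg", "rg_se", "p", "significant")],
                    10L))
  invisible(x)
}

.scan_numeric_cols <- c("n_snps", "gencov", "gencov_se", "rg", "rg_se",
                        "z_stat", "p", "intercept12", "intercept12_se",
                        "h2_trait", "h2_trait_se", "h2_outcome",
                        "h2_outcome_se")

#' Write scan results as TSV
#'
#' Fixed column order, full double precision (17 significant digits, so
#' p-values like 1.33e-16 survive a round-trip), and a machine-readable
#' header line carrying alpha and the comparison counts.
#'
#' @param rows an `ldsc_scan` result.
#' @param path output path.
#' @export
write_scan_results <- function(rows, path) {
  if (!nrow(rows)) stop("no rows to write", call. = FALSE)
  con <- open_output(path)
  on.exit(close(con))
  writeLines(sprintf("#ldsc_scan alpha=%.17g n_tests_per_pass=%d n_total=%d cutoff=%.17g",
                     attr(rows, "alpha"), attr(rows, "n_tests_per_pass"),
                     attr(rows, "n_total"), attr(rows, "cutoff")), con)
  df <- as.data.frame(rows)
  for (cl in .scan_numeric_cols)
    df[[cl]] <- ifelse(is.na(df[[cl]]), "NA", sprintf("%.17g", df[[cl]]))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a scan results file
#'
#' @param path a file written by [write_scan_results()].
#' @return an `ldsc_scan` data.frame equal field-for-field to what was
#'   written.
#' @export
read_scan_results <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  if (!startsWith(header, "#ldsc_scan"))
    stop("not a scan results file: ", path, call. = FALSE)
  kv <- strsplit(strsplit(header, " ")[[1]][-1], "=")
  meta <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                          vapply(kv, `[`, "", 1L))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (cl in .scan_numeric_cols) df[[cl]] <- as.numeric(df[[cl]])
  df$n_snps <- as.integer(df$n_snps)
  df$significant <- as.logical(df$significant)
  structure(df, alpha = unname(meta["alpha"]),
            n_tests_per_pass = as.integer(meta["n_tests_per_pass"]),
            n_total = as.integer(meta["n_total"]),
            cutoff = unname(meta["cutoff"]),
            class = c("ldsc_scan", "data.frame"))
}
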