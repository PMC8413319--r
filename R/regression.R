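# LD score regression estimators.
#
# Univariate model:  E[z_j^2]      = intercept + (N h2 / M) l_j
# Cross-trait model: E[z1_j z2_j]  = intercept12 + (sqrt(N1 N2) rho_g / M) l_j
#
# The intercept absorbs genomic inflation (stratification, cryptic
# relatedness) in the univariate fit and shared-sample covariance
# rho * Ns / sqrt(N1 N2) in the cross-trait fit. Uncertainty comes from a
# delete-one-block jackknife over contiguous genomic blocks.

#' Configuration for LD score regression fits
#'
#' @param n_blocks jackknife block count B (contiguous blocks in genome
#'   order, sizes differing by at most one). Default 200.
#' @param max_weight_iters number of re-weighting passes after the initial
#'   unweighted fit. Default 2.
#' @param intercept_free fit the intercept (default) or constrain it
#'   (univariate: 1; cross-trait: `cross_intercept`).
#' @param m_override optional M replacing the LD score table's reference
#'   SNP count.
#' @param min_snps minimum SNP overlap required between summary statistics
#'   and LD scores. Default 200.
#' @param n_convention how per-SNP sample sizes enter the slope-to-estimate
#'   conversion: their mean (default) or their max.
#' @param cross_intercept constrained value of the cross-trait intercept
#'   when `intercept_free = FALSE`.
#' @return object of class `ldsr_config`.
#' @export
ldsr_config <- function(n_blocks = 200L, max_weight_iters = 2L,
                        intercept_free = TRUE, m_override = NULL,
                        min_snps = 200L, n_convention = c("mean", "max"),
                        cross_intercept = 0) {
  n_convention <- match.arg(n_convention)
  if (n_blocks < 2L) stop("n_blocks must be >= 2", call. = FALSE)
  if (max_weight_iters < 0L) stop("max_weight_iters must be >= 0", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 max_weight_iters = as.integer(max_weight_iters),
                 intercept_free = isTRUE(intercept_free),
                 m_override = m_override,
                 min_snps = as.integer(min_snps),
                 n_convention = n_convention,
                 cross_intercept = cross_intercept),
            class = "ldsr_config")
}

#' Weighted least squares of y on x
#'
#' Solves the weighted normal equations for a straight-line fit. With
#' `intercept_free = FALSE` the intercept is held at `intercept_value` and
#' only the slope is estimated.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param w positive weights.
#' @param intercept_free estimate the intercept?
#' @param intercept_value constrained intercept when not free.
#' @return list with elements `slope` and `intercept`.
#' @export
fit_weighted_ldsr <- function(x, y, w, intercept_free = TRUE,
                              intercept_value = 0) {
  n <- length(x)
  if (length(y) != n || length(w) != n)
    stop("x, y, w must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(w <= 0) || any(!is.finite(w)))
    stop("weights must be positive and finite", call. = FALSE)
  if (stats::var(x) == 0)
    stop("regressor has zero variance; slope undefined", call. = FALSE)
  if (intercept_free) {
    sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
    swxx <- sum(w * x * x); swxy <- sum(w * x * y)
    det <- sw * swxx - swx * swx
    slope <- (sw * swxy - swx * swy) / det
    intercept <- (swy * swxx - swx * swxy) / det
  } else {
    yc <- y - intercept_value
    slope <- sum(w * x * yc) / sum(w * x * x)
    intercept <- intercept_value
  }
  list(slope = slope, intercept = intercept)
}

#' Block jackknife estimate and standard error
#'
#' Deletes `n_blocks` contiguous blocks of rows one at a time (block sizes
#' differ by at most one), recomputes the statistic on each complement, and
#' returns the full-sample estimate with
#' se = sqrt((B-1)/B * sum((theta_(-b) - mean(theta_(-.)))^2)).
#' Rows are assumed already ordered (for LD score regression: genome order,
#' so that blocks respect local LD dependence).
#'
#' @param values numeric vector or matrix of per-observation contributions.
#' @param statistic function of a subset of `values` returning a scalar (or
#'   a fixed-length numeric vector; SEs are then per component).
#' @param n_blocks number of blocks B (>= 2, <= number of observations).
#' @return list with `estimate`, `se`, `n_blocks`, and the matrix of
#'   leave-one-block-out replicates (`replicates`).
#' @export
block_jackknife <- function(values, statistic, n_blocks = 200L) {
  take <- function(idx) if (is.matrix(values)) values[idx, , drop = FALSE] else values[idx]
  n <- if (is.matrix(values)) nrow(values) else length(values)
  ids <- block_ids(n, n_blocks)
  full <- statistic(take(seq_len(n)))
  reps <- vapply(seq_len(n_blocks),
                 function(b) as.numeric(statistic(take(which(ids != b)))),
                 numeric(length(full)))
  reps <- if (length(full) == 1L) matrix(reps, ncol = 1L) else t(reps)
  center <- colMeans(reps)
  se <- sqrt((n_blocks - 1) / n_blocks *
               colSums((reps - rep(center, each = n_blocks))^2))
  names(se) <- names(full)
  list(estimate = full, se = se, n_blocks = n_blocks, replicates = reps)
}

# ---- internal machinery ------------------------------------------------

.nbar <- function(n, convention) if (convention == "max") max(n) else mean(n)

# one regression pass for the three LDSR fits run in lockstep:
# z1^2 on l2, z2^2 on l2, z1*z2 on l2. Marginal weight terms
# v_k = 1 + n_k h2_k l2 / M use the h2 estimates of the *previous* pass
# (first pass: from the unweighted fits). The cross fit uses 1/(l2 v1 v2),
# the marginal fits 1/(l2 v^2); when z1 and z2 coincide the three fits are
# then numerically identical, so gencov == h2 and rg(A, A) == 1.
.ldsr_triple <- function(z1, z2, n1, n2, l2, M, cfg) {
  y11 <- z1 * z1; y22 <- z2 * z2; y12 <- z1 * z2
  N1 <- .nbar(n1, cfg$n_convention)
  N2 <- .nbar(n2, cfg$n_convention)
  w0 <- rep(1, length(l2))
  fit <- function(y, w, cross) {
    fit_weighted_ldsr(l2, y, w, intercept_free = cfg$intercept_free,
                      intercept_value = if (cross) cfg$cross_intercept else 1)
  }
  f11 <- fit(y11, w0, FALSE); f22 <- fit(y22, w0, FALSE); f12 <- fit(y12, w0, TRUE)
  l2f <- pmax(l2, 1)
  w11 <- w22 <- w12 <- w0
  for (it in seq_len(cfg$max_weight_iters)) {
    h1 <- clamp(f11$slope * M / N1, 0, 1)
    h2 <- clamp(f22$slope * M / N2, 0, 1)
    v1 <- 1 + n1 * h1 * l2 / M
    v2 <- 1 + n2 * h2 * l2 / M
    w11 <- 1 / (l2f * v1 * v1)
    w22 <- 1 / (l2f * v2 * v2)
    w12 <- 1 / (l2f * v1 * v2)
    f11 <- fit(y11, w11, FALSE)
    f22 <- fit(y22, w22, FALSE)
    f12 <- fit(y12, w12, TRUE)
  }
  list(f11 = f11, f22 = f22, f12 = f12,
       w11 = w11, w22 = w22, w12 = w12, N1 = N1, N2 = N2)
}

# join a sumstats-like frame to LD scores by snp_id; chrom/bp are taken
# from the LD score table (the authoritative SNP universe)
.join_ld <- function(df, ld, cfg) {
  i <- match(ld$snp_id, df$snp_id)
  keep <- which(!is.na(i))
  out <- cbind(ld[keep, c("snp_id", "chrom", "bp", "l2")],
               df[i[keep], setdiff(names(df), c("snp_id", "chrom", "bp")),
                  drop = FALSE])
  if (nrow(out) < cfg$min_snps)
    stop("only ", nrow(out), " SNPs overlap the LD score table (floor ",
         cfg$min_snps, ")", call. = FALSE)
  rownames(out) <- NULL
  out
}

.resolve_m <- function(ld, cfg) {
  M <- cfg$m_override %||% attr(ld, "m_ref")
  if (is.null(M) || M <= 0) stop("non-positive M", call. = FALSE)
  M
}

# ---- heritability ------------------------------------------------------

#' Estimate SNP heritability by LD score regression
#'
#' Regresses squared Z scores on LD scores with iteratively updated
#' heteroskedasticity-and-overcounting weights 1/(l2 * v^2),
#' v = 1 + N h2 l2 / M, then converts the slope to observed-scale
#' heritability h2 = slope * M / N. Standard errors for h2 and the
#' intercept come from a delete-one-block jackknife (weights held fixed
#' across replicates).
#'
#' @param ss a [sumstats] table.
#' @param ld an [ld_scores] table covering the SNP universe; M defaults to
#'   its reference SNP count.
#' @param cfg an [ldsr_config].
#' @return object of class `ldsc_h2` with components `h2`, `h2_se`,
#'   `intercept`, `intercept_se`, `mean_chi2`, `m_used`, `n_snps`, `n_bar`,
#'   `trait_id`, `config`.
#' @export
estimate_h2 <- function(ss, ld, cfg = ldsr_config()) {
  M <- .resolve_m(ld, cfg)
  d <- .join_ld(as.data.frame(ss), ld, cfg)
  tri <- .ldsr_triple(d$z, d$z, d$n, d$n, d$l2, M, cfg)
  slope_to_h2 <- function(idx) {
    f <- fit_weighted_ldsr(d$l2[idx], d$z[idx]^2, tri$w11[idx],
                           intercept_free = cfg$intercept_free,
                           intercept_value = 1)
    c(h2 = f$slope * M / .nbar(d$n[idx], cfg$n_convention),
      intercept = f$intercept)
  }
  jk <- block_jackknife(seq_len(nrow(d)), slope_to_h2,
                        n_blocks = min(cfg$n_blocks, nrow(d)))
  structure(list(h2 = tri$f11$slope * M / tri$N1,
                 h2_se = unname(jk$se["h2"]),
                 intercept = tri$f11$intercept,
                 intercept_se = unname(jk$se["intercept"]),
                 mean_chi2 = mean(d$z^2),
                 m_used = M, n_snps = nrow(d), n_bar = tri$N1,
                 trait_id = attr(ss, "trait_id") %||% "trait",
                 config = cfg),
            class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, digits = 4, ...) {
  cat("LD score regression: SNP heritability (observed scale)\n")
  cat("  trait:     ", x$trait_id, "\n", sep = "")
  cat("  h2:        ", format(x$h2, digits = digits), " (SE ",
      format(x$h2_se, digits = digits), ")\n", sep = "")
  cat("  intercept: ", format(x$intercept, digits = digits), " (SE ",
      format(x$intercept_se, digits = digits), ")\n", sep = "")
  cat("  mean chi2: ", format(x$mean_chi2, digits = digits),
      "   SNPs: ", x$n_snps, "   M: ", x$m_used, "\n", sep = "")
  invisible(x)
}

#' @export
coef.ldsc_h2 <- function(object, ...) {
  c(h2 = object$h2, intercept = object$intercept)
}

#' @export
confint.ldsc_h2 <- function(object, parm = c("h2", "intercept"),
                            level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  q <- stats::qnorm(1 - (1 - level) / 2)
  est <- c(h2 = object$h2, intercept = object$intercept)[parm]
  se <- c(h2 = object$h2_se, intercept = object$intercept_se)[parm]
  out <- cbind(est - q * se, est + q * se)
  dimnames(out) <- list(parm, sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.ldsc_h2 <- function(object, ...) object

# ---- genetic correlation ----------------------------------------------

#' Estimate cross-trait genetic covariance and correlation
#'
#' Regresses the product of the two traits' Z scores on LD scores; the
#' slope scales to the genetic covariance rho_g = slope * M / sqrt(N1 N2),
#' and the genetic correlation is rg = rho_g / sqrt(h2_1 h2_2) with the two
#' marginal heritabilities estimated on the same merged SNP set. The
#' cross-trait intercept absorbs shared-sample covariance (expectation
#' rho * Ns / sqrt(N1 N2)). The jackknife re-does the full ratio — both
#' marginal slopes and the cross slope — per leave-one-block-out replicate,
#' and the p-value is two-sided normal on rg / rg_se. When either marginal
#' heritability is non-positive rg is undefined: the object is flagged, the
#' genetic covariance is still reported.
#'
#' @param pair a [merged_pair] from [harmonize_pair()].
#' @param ld an [ld_scores] table.
#' @param cfg an [ldsr_config].
#' @return object of class `ldsc_rg` with components `gencov`, `gencov_se`,
#'   `rg`, `rg_se`, `z_stat`, `p`, `intercept12`, `intercept12_se`, `h2_1`,
#'   `h2_1_se`, `h2_2`, `h2_2_se`, `mean_chi2_1`, `mean_chi2_2`, `m_used`,
#'   `n_snps`, `trait_ids`, `flag` ("ok" or "rg_undefined"), `config`.
#' @export
estimate_rg <- function(pair, ld, cfg = ldsr_config()) {
  M <- .resolve_m(ld, cfg)
  d <- .join_ld(as.data.frame(pair), ld, cfg)
  tri <- .ldsr_triple(d$z1, d$z2, d$n1, d$n2, d$l2, M, cfg)
  h2_1 <- tri$f11$slope * M / tri$N1
  h2_2 <- tri$f22$slope * M / tri$N2
  gencov <- tri$f12$slope * M / sqrt(tri$N1 * tri$N2)
  defined <- h2_1 > 0 && h2_2 > 0
  rg <- if (defined) gencov / sqrt(h2_1 * h2_2) else NA_real_

  stat <- function(idx) {
    fit <- function(y, w, cross) fit_weighted_ldsr(
      d$l2[idx], y[idx], w[idx], intercept_free = cfg$intercept_free,
      intercept_value = if (cross) cfg$cross_intercept else 1)
    f11 <- fit(d$z1^2, tri$w11, FALSE)
    f22 <- fit(d$z2^2, tri$w22, FALSE)
    f12 <- fit(d$z1 * d$z2, tri$w12, TRUE)
    N1 <- .nbar(d$n1[idx], cfg$n_convention)
    N2 <- .nbar(d$n2[idx], cfg$n_convention)
    h1 <- f11$slope * M / N1
    h2 <- f22$slope * M / N2
    g <- f12$slope * M / sqrt(N1 * N2)
    c(gencov = g, intercept12 = f12$intercept, h2_1 = h1, h2_2 = h2,
      rg = if (h1 > 0 && h2 > 0) g / sqrt(h1 * h2) else NA_real_)
  }
  jk <- block_jackknife(seq_len(nrow(d)), stat,
                        n_blocks = min(cfg$n_blocks, nrow(d)))
  rg_reps_ok <- all(is.finite(jk$replicates[, 5L]))
  rg_se <- if (defined && rg_reps_ok) unname(jk$se["rg"]) else NA_real_
  z_stat <- if (!is.na(rg_se) && rg_se > 0) rg / rg_se else NA_real_
  p <- if (!is.na(z_stat)) 2 * stats::pnorm(-abs(z_stat)) else NA_real_
  flag <- if (!defined) "rg_undefined"
          else if (!rg_reps_ok) "rg_jackknife_unstable" else "ok"

  structure(list(gencov = gencov, gencov_se = unname(jk$se["gencov"]),
                 rg = rg, rg_se = rg_se, z_stat = z_stat, p = p,
                 intercept12 = tri$f12$intercept,
                 intercept12_se = unname(jk$se["intercept12"]),
                 h2_1 = h2_1, h2_1_se = unname(jk$se["h2_1"]),
                 h2_2 = h2_2, h2_2_se = unname(jk$se["h2_2"]),
                 mean_chi2_1 = mean(d$z1^2), mean_chi2_2 = mean(d$z2^2),
                 m_used = M, n_snps = nrow(d),
                 trait_ids = attr(pair, "trait_ids") %||% c("trait1", "trait2"),
                 flag = flag, config = cfg),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, digits = 4, ...) {
  cat("Cross-trait LD score regression\n")
  cat("  traits:      '", x$trait_ids[1], "' x '", x$trait_ids[2], "'\n", sep = "")
  cat("  gencov:      ", format(x$gencov, digits = digits), " (SE ",
      format(x$gencov_se, digits = digits), ")\n", sep = "")
  cat("  rg:          ", format(x$rg, digits = digits), " (SE ",
      format(x$rg_se, digits = digits), "), p = ",
      format(x$p, digits = 3), "\n", sep = "")
  cat("  intercept12: ", format(x$intercept12, digits = digits), " (SE ",
      format(x$intercept12_se, digits = digits), ")\n", sep = "")
  cat("  h2 (1, 2):   ", format(x$h2_1, digits = digits), ", ",
      format(x$h2_2, digits = digits), "   SNPs: ", x$n_snps, "\n", sep = "")
  if (x$flag != "ok") cat("  flag:        ", x$flag, "\n", sep = "")
  if (!is.na(x$rg) && abs(x$rg) > 1)
    cat("  note: |rg| > 1 (reported as computed, not clamped)\n")
  invisible(x)
}

#' @export
coef.ldsc_rg <- function(object, ...) {
  c(gencov = object$gencov, rg = object$rg, intercept12 = object$intercept12,
    h2_1 = object$h2_1, h2_2 = object$h2_2)
}

#' @export
confint.ldsc_rg <- function(object, parm = "rg", level = 0.95, ...) {
  parm <- match.arg(parm, c("rg", "gencov", "intercept12"), several.ok = TRUE)
  q <- stats::qnorm(1 - (1 - level) / 2)
  est <- c(rg = object$rg, gencov = object$gencov,
           intercept12 = object$intercept12)[parm]
  se <- c(rg = object$rg_se, gencov = object$gencov_se,
          intercept12 = object$intercept12_se)[parm]
  out <- cbind(est - q * se, est + q * se)
  dimnames(out) <- list(parm, sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.ldsc_rg <- function(object, ...) object
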