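# Synthetic study generator: block-LD genotypes, bivariate infinitesimal
# polygenic effects, two-cohort GWAS with optional sample overlap and
# population-stratification confounding. Everything is a pure function of
# (config, seed) so fixtures are reproducible bit for bit.

#' Simulation configuration
#'
#' Defaults are desk-scale study conditions: 5000 SNPs in 25-SNP LD blocks
#' spread over 22 autosomes at 1 kb spacing, two cohorts of 2000, true
#' heritabilities 0.25 and a true genetic correlation of -0.40 (the scale
#' of the strongest correlations seen in phenome-wide lung-cancer scans).
#'
#' @param m SNP count.
#' @param n1,n2 cohort sizes.
#' @param n_overlap individuals shared between the cohorts
#'   (0 <= n_overlap <= min(n1, n2)).
#' @param h2_1,h2_2 true observed-scale heritabilities in [0, 1).
#' @param rg_true true genetic correlation in [-1, 1].
#' @param rho_pheno total phenotypic correlation between the two traits for
#'   overlapping individuals; drives the cross-trait intercept
#'   rho * Ns / sqrt(N1 N2).
#' @param block_size SNPs per LD block.
#' @param block_rho upper bound of the within-block adjacent-SNP latent
#'   AR(1) correlation, in [0, 1). Each block draws its own correlation as
#'   block_rho * sqrt(U), U uniform — a draw skewed toward tight LD —
#'   emulating the genome's mix of tight and loose LD blocks; this
#'   heterogeneity in LD scores is what gives the regression leverage to
#'   separate slope from intercept. Dosage-scale LD is attenuated relative
#'   to the latent value by the liability thresholding.
#' @param maf_range uniform sampling range for per-SNP minor allele
#'   frequencies, a subset of (0, 0.5].
#' @param confound_f Balding-Nichols style divergence (Fst) between two
#'   equal-sized subpopulations; 0 disables confounding.
#' @param pheno_shift phenotypic mean offset (residual-SD units) added to
#'   subpopulation 2 for both traits when `confound_f > 0`.
#' @param n_ref individuals in the held-out LD reference panel.
#' @param seed integer seed; every generator below is deterministic in
#'   (config, seed).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(m = 5000L, n1 = 2000L, n2 = 2000L, n_overlap = 0L,
                       h2_1 = 0.25, h2_2 = 0.25, rg_true = -0.40,
                       rho_pheno = 0, block_size = 25L, block_rho = 0.98,
                       maf_range = c(0.05, 0.5), confound_f = 0,
                       pheno_shift = 0.25, n_ref = 1000L, seed = 1L) {
  if (n_overlap > min(n1, n2) || n_overlap < 0)
    stop("n_overlap must lie in [0, min(n1, n2)]", call. = FALSE)
  if (h2_1 < 0 || h2_1 >= 1 || h2_2 < 0 || h2_2 >= 1)
    stop("heritabilities must lie in [0, 1)", call. = FALSE)
  if (abs(rg_true) > 1) stop("|rg_true| must be <= 1", call. = FALSE)
  if (block_rho < 0 || block_rho >= 1)
    stop("block_rho must lie in [0, 1)", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be (low, high) within (0, 0.5]", call. = FALSE)
  if (confound_f < 0) stop("confound_f must be >= 0", call. = FALSE)
  structure(list(m = as.integer(m), n1 = as.integer(n1), n2 = as.integer(n2),
                 n_overlap = as.integer(n_overlap), h2_1 = h2_1, h2_2 = h2_2,
                 rg_true = rg_true, rho_pheno = rho_pheno,
                 block_size = as.integer(block_size), block_rho = block_rho,
                 maf_range = maf_range, confound_f = confound_f,
                 pheno_shift = pheno_shift, n_ref = as.integer(n_ref),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' SNP universe implied by a simulation configuration
#'
#' Draws the fixed per-SNP quantities every cohort of a study shares: block
#' assignment, chromosome layout (contiguous runs of blocks over autosomes
#' 1..22, SNPs at 1 kb spacing), minor allele frequencies, and — when
#' confounding is on — the two subpopulation allele frequencies drawn
#' Balding-Nichols style around each MAF with variance
#' confound_f * p * (1 - p).
#'
#' @param cfg a [sim_config].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return object of class `snp_universe`.
#' @export
sim_universe <- function(cfg, seed = cfg$seed) {
  m <- cfg$m
  nb <- ceiling(m / cfg$block_size)
  block <- rep(seq_len(nb), each = cfg$block_size)[seq_len(m)]
  n_chrom <- min(22L, nb)
  chrom_of_block <- ceiling(seq_len(nb) * n_chrom / nb)
  chrom <- as.character(chrom_of_block[block])
  bp <- integer(m)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    bp[i] <- seq_along(i) * 1000L
  }
  with_seed(seed, {
    rho_block <- cfg$block_rho * sqrt(stats::runif(nb))
    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    sub_p <- NULL
    if (cfg$confound_f > 0) {
      f <- cfg$confound_f
      a <- maf * (1 - f) / f
      b <- (1 - maf) * (1 - f) / f
      sub_p <- cbind(stats::rbeta(m, a, b), stats::rbeta(m, a, b))
      sub_p <- clamp(sub_p, 1e-4, 1 - 1e-4)
    }
    structure(list(m = m, snp_id = paste0("rs", seq_len(m)), chrom = chrom,
                   bp = bp, block = block, maf = maf, sub_p = sub_p,
                   rho_block = rho_block),
              class = "snp_universe")
  })
}

# latent AR(1) Gaussians thresholded per SNP: one haplotype draw.
# qmat: (n_subpop x m) matrix of per-SNP normal quantile thresholds;
# subpop: length-n assignment into its rows. Thresholding is done column
# by column to avoid materializing an n x m threshold matrix.
.sim_haplotype <- function(n, universe, qmat, subpop) {
  m <- universe$m
  z <- matrix(stats::rnorm(n * m), n, m)
  blk <- universe$block
  rho <- universe$rho_block
  if (m > 1L) {
    for (j in 2:m) if (blk[j] == blk[j - 1L] && rho[blk[j]] > 0) {
      r <- rho[blk[j]]
      z[, j] <- r * z[, j - 1L] + sqrt(1 - r^2) * z[, j]
    }
  }
  if (nrow(qmat) == 1L) {
    for (j in seq_len(m)) z[, j] <- z[, j] < qmat[1L, j]
  } else {
    for (j in seq_len(m)) z[, j] <- z[, j] < qmat[subpop, j]
  }
  z
}

#' Simulate an LD-structured genotype panel
#'
#' Within each block, latent Gaussian vectors with first-order
#' autoregressive correlation are thresholded at the quantile implied by
#' each SNP's allele frequency; two haplotype draws per individual are
#' summed to dosages in \{0, 1, 2\}. Blocks are mutually independent. Under
#' confounding, individuals alternate between two subpopulations with
#' diverged allele frequencies. Monomorphic columns (possible at small n)
#' are redrawn.
#'
#' @param cfg a [sim_config].
#' @param n number of individuals (>= 3).
#' @param universe optional precomputed [sim_universe()] (so several
#'   cohorts can share one SNP universe).
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return list with `panel` (a [reference_panel]) and `subpop` (integer
#'   vector of subpopulation labels, all 1 without confounding).
#' @export
simulate_genotypes <- function(cfg, n, universe = NULL, seed = cfg$seed) {
  if (n < 3L) stop("need at least 3 individuals", call. = FALSE)
  if (is.null(universe)) universe <- sim_universe(cfg)
  m <- universe$m
  with_seed(seed, {
    confounded <- !is.null(universe$sub_p)
    subpop <- if (confounded) rep_len(c(1L, 2L), n) else rep(1L, n)
    qmat <- if (confounded) t(stats::qnorm(universe$sub_p))
            else matrix(stats::qnorm(universe$maf), nrow = 1L)
    G <- .sim_haplotype(n, universe, qmat, subpop) +
         .sim_haplotype(n, universe, qmat, subpop)
    # redraw monomorphic columns (rare; keeps the panel invariant valid)
    for (tries in 1:10) {
      mono <- which(col_vars(G) == 0)
      if (!length(mono)) break
      for (j in mono) {
        zj <- stats::rnorm(2L * n)
        thj <- if (confounded) qmat[subpop, j] else rep(qmat[1L, j], n)
        G[, j] <- as.numeric(zj[seq_len(n)] < thj) +
          as.numeric(zj[n + seq_len(n)] < thj)
      }
    }
    list(panel = reference_panel(G, universe$snp_id, universe$chrom, universe$bp),
         subpop = subpop)
  })
}

# column variances without extra copies
col_vars <- function(x) {
  n <- nrow(x)
  (colSums(x * x) - n * colMeans(x)^2) / (n - 1)
}

#' Draw per-SNP effect sizes for two traits
#'
#' Infinitesimal model: every SNP is causal, with
#' (beta1_j, beta2_j) iid bivariate normal, variances h2_k / m and
#' covariance rg_true * sqrt(h2_1 h2_2) / m, on the standardized-genotype
#' scale.
#'
#' @param cfg a [sim_config].
#' @param seed RNG seed.
#' @return m x 2 matrix of effect sizes.
#' @export
simulate_effect_sizes <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    e1 <- stats::rnorm(cfg$m)
    e2 <- stats::rnorm(cfg$m)
    b1 <- sqrt(cfg$h2_1 / cfg$m) * e1
    shared <- cfg$rg_true * e1 + sqrt(1 - cfg$rg_true^2) * e2
    b2 <- sqrt(cfg$h2_2 / cfg$m) * shared
    cbind(beta1 = b1, beta2 = b2)
  })
}

# marginal per-SNP GWAS: z = betahat / se from simple linear regression
.gwas_z <- function(G, y) {
  n <- nrow(G)
  xc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  xtx <- colSums(xc * xc)
  xty <- drop(crossprod(xc, yc))
  beta <- xty / xtx
  sse <- pmax(sum(yc * yc) - beta * xty, 0)
  se <- sqrt(sse / (n - 2) / xtx)
  beta / se
}

.folded_freq <- function(G) {
  f <- colMeans(G) / 2
  pmin(pmax(pmin(f, 1 - f), 1e-6), 0.5)
}

#' Simulate a two-cohort GWAS study
#'
#' Generates genotypes for n1 + n2 - n_overlap individuals sharing one SNP
#' universe, phenotypes y_k = X_std beta_k + eps with residual variance
#' 1 - h2_k, and per-SNP marginal-regression summary statistics for each
#' cohort (cohort 1 analyzed for trait 1, cohort 2 for trait 2; overlapping
#' individuals contribute to both). Residuals of overlapping individuals
#' are correlated so that the total phenotypic correlation equals
#' `rho_pheno`. Under confounding, subpopulation 2 receives a mean shift of
#' `pheno_shift` on both traits. A held-out reference panel of `n_ref`
#' individuals is drawn from the same universe.
#'
#' @param cfg a [sim_config].
#' @param universe optional shared [sim_universe()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param include_panel draw the held-out reference panel (default). Set to
#'   FALSE in replicate loops that reuse one panel across studies.
#' @return list with [sumstats] tables `sumstats1`, `sumstats2`, the
#'   held-out `panel` (`NULL` when `include_panel = FALSE`), the
#'   `universe`, and `truth` (the config echoed).
#' @export
simulate_summary_stats <- function(cfg, universe = NULL, seed = cfg$seed,
                                   include_panel = TRUE) {
  if (is.null(universe)) universe <- sim_universe(cfg, seed = seed)
  n_tot <- cfg$n1 + cfg$n2 - cfg$n_overlap
  idx1 <- seq_len(cfg$n1)
  idx2 <- seq.int(n_tot - cfg$n2 + 1L, n_tot)
  shared <- intersect(idx1, idx2)

  geno <- simulate_genotypes(cfg, n_tot, universe = universe, seed = seed + 1L)
  G <- geno$panel$genotypes
  ord <- match(universe$snp_id, geno$panel$snp_id)  # back to universe order
  G <- G[, ord, drop = FALSE]

  with_seed(seed + 2L, {
    beta <- simulate_effect_sizes(cfg, seed = seed + 3L)
    Xs <- scale(G)
    gval <- Xs %*% beta
    r1 <- sqrt(1 - cfg$h2_1)
    r2 <- sqrt(1 - cfg$h2_2)
    e1 <- stats::rnorm(n_tot)
    e2 <- stats::rnorm(n_tot)
    if (length(shared) && (r1 > 0 && r2 > 0)) {
      rho_e <- (cfg$rho_pheno - cfg$rg_true * sqrt(cfg$h2_1 * cfg$h2_2)) /
        (r1 * r2)
      if (abs(rho_e) > 1)
        stop("rho_pheno unattainable given h2 and rg_true", call. = FALSE)
      e2[shared] <- rho_e * e1[shared] + sqrt(1 - rho_e^2) * e2[shared]
    }
    y1 <- gval[, 1L] + r1 * e1
    y2 <- gval[, 2L] + r2 * e2
    if (cfg$confound_f > 0) {
      shift <- cfg$pheno_shift * (geno$subpop == 2L)
      y1 <- y1 + shift
      y2 <- y2 + shift
    }

    mk <- function(idx, y, n_cohort, id) {
      Gc <- G[idx, , drop = FALSE]
      keep <- which(col_vars(Gc) > 0)
      sumstats(data.frame(snp_id = universe$snp_id[keep],
                          chrom = universe$chrom[keep],
                          bp = universe$bp[keep],
                          a1 = "A", a2 = "G",
                          z = .gwas_z(Gc[, keep, drop = FALSE], y[idx]),
                          n = n_cohort,
                          maf = .folded_freq(Gc[, keep, drop = FALSE]),
                          info = 1.0, stringsAsFactors = FALSE),
               trait_id = id, provenance = "synthetic")
    }
    ss1 <- mk(idx1, y1, cfg$n1, "trait1")
    ss2 <- mk(idx2, y2, cfg$n2, "trait2")
    panel <- if (include_panel)
      simulate_genotypes(cfg, cfg$n_ref, universe = universe,
                         seed = seed + 4L)$panel
    list(sumstats1 = ss1, sumstats2 = ss2, panel = panel,
         universe = universe, truth = cfg)
  })
}

#' Generate a complete multi-trait study fixture
#'
#' Builds one shared SNP universe, draws effect sizes for all traits and
#' outcomes jointly from the covariance implied by the planted rg matrix
#' (traits and outcomes mutually uncorrelated apart from the planted
#' trait-outcome entries), simulates an independent GWAS cohort per table,
#' a held-out LD reference panel, and a stand-in sentinel list anchored at
#' the centers of a fraction of LD blocks so that region exclusion
#' measurably shrinks the SNP set. The flank that matches one block is
#' floor(block_size / 2) kb and is recorded in the output.
#'
#' @param cfg a [sim_config]; `h2_1` is used for every trait, `h2_2` for
#'   every outcome.
#' @param rg_matrix numeric matrix (traits x outcomes) of planted genetic
#'   correlations; the implied joint covariance must be positive definite.
#' @param sentinel_frac fraction of LD blocks anchored by a sentinel.
#' @param seed RNG seed.
#' @return object of class `study_fixture`: list with named lists `traits`
#'   and `outcomes` of [sumstats], `panel`, `sentinels`, `flank_kb`,
#'   `universe`, `truth`.
#' @export
generate_study_fixture <- function(cfg, rg_matrix = matrix(c(-0.4, 0, 0, 0), 2, 2),
                                   sentinel_frac = 0.1, seed = cfg$seed) {
  nt <- nrow(rg_matrix)
  no <- ncol(rg_matrix)
  k <- nt + no
  Sigma <- diag(k)
  Sigma[seq_len(nt), nt + seq_len(no)] <- rg_matrix
  Sigma[nt + seq_len(no), seq_len(nt)] <- t(rg_matrix)
  ch <- tryCatch(chol(Sigma), error = function(e)
    stop("planted rg matrix implies a non-positive-definite covariance",
         call. = FALSE))
  h2 <- c(rep(cfg$h2_1, nt), rep(cfg$h2_2, no))

  universe <- sim_universe(cfg, seed = seed)
  beta <- with_seed(seed + 10L, {
    E <- matrix(stats::rnorm(cfg$m * k), cfg$m, k) %*% ch
    sweep(E, 2L, sqrt(h2 / cfg$m), `*`)
  })

  one_gwas <- function(col, n_cohort, id, sd_seed) {
    geno <- simulate_genotypes(cfg, n_cohort, universe = universe, seed = sd_seed)
    G <- geno$panel$genotypes[, match(universe$snp_id, geno$panel$snp_id),
                              drop = FALSE]
    with_seed(sd_seed + 1L, {
      y <- drop(scale(G) %*% beta[, col]) +
        sqrt(1 - h2[col]) * stats::rnorm(n_cohort)
      if (cfg$confound_f > 0)
        y <- y + cfg$pheno_shift * (geno$subpop == 2L)
      sumstats(data.frame(snp_id = universe$snp_id, chrom = universe$chrom,
                          bp = universe$bp, a1 = "A", a2 = "G",
                          z = .gwas_z(G, y), n = n_cohort,
                          maf = .folded_freq(G), info = 1.0,
                          stringsAsFactors = FALSE),
               trait_id = id, provenance = "synthetic fixture")
    })
  }
  traits <- outcomes <- list()
  for (i in seq_len(nt))
    traits[[paste0("trait", i)]] <- one_gwas(i, cfg$n1, paste0("trait", i),
                                             seed + 100L + 2L * i)
  for (j in seq_len(no))
    outcomes[[paste0("outcome", j)]] <- one_gwas(nt + j, cfg$n2,
                                                 paste0("outcome", j),
                                                 seed + 200L + 2L * j)

  panel <- simulate_genotypes(cfg, cfg$n_ref, universe = universe,
                              seed = seed + 300L)$panel
  nb <- max(universe$block)
  n_sent <- max(1L, round(sentinel_frac * nb))
  sent_blocks <- with_seed(seed + 400L, sort(sample.int(nb, n_sent)))
  anchor <- vapply(sent_blocks, function(b) {
    i <- which(universe$block == b)
    i[ceiling(length(i) / 2)]
  }, integer(1))
  sentinels <- sentinel_list(data.frame(snp_id = universe$snp_id[anchor],
                                        chrom = universe$chrom[anchor],
                                        bp = universe$bp[anchor],
                                        stringsAsFactors = FALSE),
                             provenance = "synthetic sentinel stand-ins")
  structure(list(traits = traits, outcomes = outcomes, panel = panel,
                 sentinels = sentinels,
                 flank_kb = floor(cfg$block_size / 2),
                 universe = universe,
                 truth = list(config = cfg, rg_matrix = rg_matrix,
                              sentinel_blocks = sent_blocks)),
            class = "study_fixture")
}
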