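test_that("generation is a pure function of (config, seed)", {
  cfg <- sim_config(m = 200L, block_size = 10L, seed = 5L)
  g1 <- simulate_genotypes(cfg, 50L)
  g2 <- simulate_genotypes(cfg, 50L)
  expect_identical(g1$panel$genotypes, g2$panel$genotypes)

  s1 <- simulate_summary_stats(sim_config(m = 300L, n1 = 200L, n2 = 200L, seed = 9L))
  s2 <- simulate_summary_stats(sim_config(m = 300L, n1 = 200L, n2 = 200L, seed = 9L))
  expect_identical(s1$sumstats1$z, s2$sumstats1$z)
  expect_identical(s1$sumstats2$z, s2$sumstats2$z)

  s3 <- simulate_summary_stats(sim_config(m = 300L, n1 = 200L, n2 = 200L, seed = 10L))
  expect_false(identical(s1$sumstats1$z, s3$sumstats1$z))
})

test_that("dosages honour the drawn allele frequencies and LD switches off", {
  cfg <- sim_config(m = 400L, block_rho = 0, seed = 21L)
  uni <- sim_universe(cfg)
  panel <- simulate_genotypes(cfg, 2000L, universe = uni)$panel
  freq <- colMeans(panel$genotypes) / 2
  dev <- abs(freq - uni$maf)
  # binomial concentration at 2n = 4000 draws per SNP
  expect_lt(unname(quantile(dev, 0.99)), 0.03)
  expect_lt(max(dev), 0.04)

  # independent SNPs: off-diagonal dosage correlation is pure noise
  r <- cor(panel$genotypes[, 1:100])
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
})

test_that("within-block LD is present and blocks are independent", {
  cfg <- sim_config(m = 200L, block_size = 25L, block_rho = 0.95, seed = 33L)
  uni <- sim_universe(cfg)
  panel <- simulate_genotypes(cfg, 1500L, universe = uni)$panel
  r <- cor(panel$genotypes)
  same_block <- outer(uni$block, uni$block, "==") & upper.tri(r)
  adjacent <- abs(outer(seq_len(200), seq_len(200), "-")) == 1 & same_block
  cross_block <- !outer(uni$block, uni$block, "==") & upper.tri(r)
  expect_gt(mean(abs(r[adjacent])), 0.2)
  expect_lt(mean(abs(r[cross_block])), 0.05)
})

test_that("effect sizes match the bivariate polygenic model", {
  cfg <- sim_config(m = 5000L, h2_1 = 0.3, h2_2 = 0.2, rg_true = 0, seed = 2L)
  b <- simulate_effect_sizes(cfg)
  expect_lt(abs(cfg$m * var(b[, 1]) - 0.3) / 0.3, 0.10)
  expect_lt(abs(cfg$m * var(b[, 2]) - 0.2) / 0.2, 0.10)
  expect_lt(abs(cor(b[, 1], b[, 2])), 0.04)

  # perfect correlation degenerates to a deterministic rescaling
  cfg1 <- sim_config(m = 100L, h2_1 = 0.4, h2_2 = 0.1, rg_true = 1, seed = 3L)
  b1 <- simulate_effect_sizes(cfg1)
  expect_equal(b1[, 2], sqrt(0.1 / 0.4) * b1[, 1], tolerance = 1e-12)

  cfg2 <- sim_config(m = 5000L, rg_true = -0.4, seed = 4L)
  b2 <- simulate_effect_sizes(cfg2)
  expect_lt(abs(cor(b2[, 1], b2[, 2]) + 0.4), 0.04)
})

test_that("null traits give unit mean chi-square", {
  cfg <- sim_config(m = 3000L, n1 = 2000L, n2 = 2000L, h2_1 = 0, h2_2 = 0,
                    rg_true = 0, seed = 6L)
  sim <- simulate_summary_stats(cfg)
  expect_gt(mean(sim$sumstats1$z^2), 0.93)
  expect_lt(mean(sim$sumstats1$z^2), 1.07)
})

test_that("population stratification inflates chi-square uniformly", {
  cfg <- sim_config(m = 2000L, n1 = 2000L, n2 = 2000L, h2_1 = 0, h2_2 = 0,
                    rg_true = 0, confound_f = 0.02, pheno_shift = 0.2,
                    seed = 14L)
  sim <- simulate_summary_stats(cfg)
  expect_gt(mean(sim$sumstats1$z^2), 1.1)
})

test_that("full sample overlap induces the expected cross-trait product mean", {
  cfg <- sim_config(m = 3000L, n1 = 1500L, n2 = 1500L, n_overlap = 1500L,
                    h2_1 = 0.25, h2_2 = 0.25, rg_true = 0, rho_pheno = 0.5,
                    block_rho = 0, seed = 15L)
  sim <- simulate_summary_stats(cfg)
  p <- harmonize_pair(sim$sumstats1, sim$sumstats2)
  # E[z1 z2] = rho * Ns / sqrt(N1 N2) = 0.5 under full overlap, l2 = 1
  expect_lt(abs(mean(p$z1 * p$z2) - 0.5), 0.08)
})

test_that("configs validate overlap, heritability and MAF ranges", {
  expect_error(sim_config(n1 = 100, n2 = 100, n_overlap = 150), "n_overlap")
  expect_error(sim_config(h2_1 = 1), "heritabilities")
  expect_error(sim_config(rg_true = 1.5), "rg_true")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), "maf_range")
  expect_error(sim_config(block_rho = 1), "block_rho")
  # unattainable phenotypic correlation given h2 and rg
  cfg <- sim_config(m = 200L, n1 = 100L, n2 = 100L, n_overlap = 100L,
                    h2_1 = 0.9, h2_2 = 0.9, rg_true = -1, rho_pheno = 0.9,
                    seed = 1L)
  expect_error(simulate_summary_stats(cfg), "unattainable")
})

test_that("study fixtures bundle traits, outcomes, panel, sentinels and truth", {
  sf <- scan_fixture()
  fx <- sf$fx
  expect_length(fx$traits, 2L)
  expect_length(fx$outcomes, 2L)
  expect_s3_class(fx$panel, "ref_panel")
  expect_s3_class(fx$sentinels, "sentinels")
  expect_equal(fx$truth$rg_matrix[1, 1], -0.5)

  # sentinel stand-ins anchor ~10% of blocks, so exclusion removes ~10% of SNPs
  r <- build_exclusion_regions(fx$sentinels, flank_kb = fx$flank_kb)
  out <- apply_exclusion(fx$traits$trait1, r)
  frac <- out$removed / nrow(fx$traits$trait1)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.15)
})

test_that("averaged rg over replicate studies approaches the planted value", {
  # replicate GWAS cohorts and effect draws under one SNP universe and one
  # reference LD table, as a fixed reference panel serves all traits in
  # practice; Monte-Carlo allowance on top of the 0.05 bias band
  cfg <- sim_config(seed = 2468L)    # defaults: h2 = 0.25, rg_true = -0.4
  uni <- sim_universe(cfg)
  panel <- simulate_genotypes(cfg, cfg$n_ref, universe = uni, seed = 8888L)$panel
  ld <- compute_ld_scores(panel)
  rc <- ldsr_config(n_blocks = 100L)
  out <- t(sapply(1:50, function(r) {
    sim <- simulate_summary_stats(cfg, universe = uni, seed = 3000L + r * 11L,
                                  include_panel = FALSE)
    f <- estimate_rg(harmonize_pair(sim$sumstats1, sim$sumstats2), ld, rc)
    c(rg = f$rg, h2_1 = f$h2_1)
  }))
  ok <- !is.na(out[, "rg"])
  expect_gte(sum(ok), 45)
  mc_se <- sd(out[ok, "rg"]) / sqrt(sum(ok))
  expect_lt(abs(mean(out[ok, "rg"]) - cfg$rg_true), 0.05 + 2 * mc_se)
  expect_lt(abs(mean(out[, "h2_1"]) - cfg$h2_1), 0.05)
})
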