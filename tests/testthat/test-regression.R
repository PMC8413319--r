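test_that("weighted fit reproduces exact lines and the lm() oracle", {
  x <- 1:10
  y <- 2 * x + 1
  f <- fit_weighted_ldsr(x, y, rep(1, 10))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)

  # constrained intercept
  fc <- fit_weighted_ldsr(x, y, rep(1, 10), intercept_free = FALSE,
                          intercept_value = 1)
  expect_equal(fc$slope, 2)
  expect_equal(fc$intercept, 1)

  # random instances with arbitrary positive weights vs the independent
  # weighted-least-squares oracle in stats::lm
  set.seed(101)
  for (rep in 1:5) {
    x <- rnorm(30)
    y <- 0.5 * x - 2 + rnorm(30)
    w <- rexp(30) + 0.1
    f <- fit_weighted_ldsr(x, y, w)
    o <- stats::lm(y ~ x, weights = w)
    expect_equal(f$slope, unname(coef(o)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(o)[1]), tolerance = 1e-10)
  }
})

test_that("degenerate weighted fits raise estimation errors", {
  expect_error(fit_weighted_ldsr(rep(1, 5), 1:5, rep(1, 5)), "zero variance")
  expect_error(fit_weighted_ldsr(1:5, 1:5, c(-1, 1, 1, 1, 1)), "positive")
  expect_error(fit_weighted_ldsr(1:2, 1:2, 1:2), "3 points")
})

test_that("block jackknife SE of a mean tracks the closed form", {
  # statistic = mean of iid draws; closed-form SE = sd / sqrt(n)
  set.seed(7)
  ratios <- replicate(100, {
    x <- rnorm(500)
    jk <- block_jackknife(x, mean, n_blocks = 50)
    jk$se / (sd(x) / sqrt(500))
  })
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("jackknife edge cases: constant input and block-count validation", {
  jk <- block_jackknife(rep(3.5, 100), mean, n_blocks = 10)
  expect_equal(jk$se, 0)
  expect_equal(jk$estimate, 3.5)

  # statistic blind to the deleted block
  jk2 <- block_jackknife(rnorm(100), function(x) 42, n_blocks = 10)
  expect_equal(jk2$se, 0)

  expect_error(block_jackknife(1:5, mean, n_blocks = 10), "blocks")
  expect_error(block_jackknife(1:5, mean, n_blocks = 1), "n_blocks")
})

test_that("h2 slope-to-estimate scaling and flat-chi2 behaviour are exact", {
  # constant z^2 regardless of l2: slope 0, h2 0
  ss <- toy_sumstats(z = rep(1, 6))
  ld <- toy_ld(ss, l2 = c(1, 2, 3, 4, 5, 6))
  cfg <- ldsr_config(n_blocks = 3, min_snps = 3, max_weight_iters = 0)
  fit <- estimate_h2(ss, ld, cfg)
  expect_equal(fit$h2, 0)
  expect_equal(fit$intercept, 1)

  # hand-planted linear relation: z_j^2 = 1 + slope * l_j with
  # slope = 2e-4, M = 1e7, N = 50000 -> h2 = slope * M / N = 0.04
  l2 <- seq(1, 10, length.out = 8)
  z2 <- 1 + 2e-4 * l2
  ss2 <- toy_sumstats(snp_id = paste0("rs", 1:8), chrom = rep("1", 8),
                      bp = seq(1000L, 8000L, 1000L), a1 = rep("A", 8),
                      a2 = rep("G", 8), z = sqrt(z2), n = rep(50000, 8),
                      maf = rep(0.2, 8), info = rep(1, 8))
  ld2 <- toy_ld(ss2, l2 = l2, m_ref = 1e7)
  cfg2 <- ldsr_config(n_blocks = 4, min_snps = 3, max_weight_iters = 0)
  fit2 <- estimate_h2(ss2, ld2, cfg2)
  expect_equal(fit2$h2, 0.04, tolerance = 1e-10)
  expect_equal(fit2$intercept, 1, tolerance = 1e-10)
  expect_equal(fit2$m_used, 1e7)
})

test_that("h2 estimation enforces the SNP-overlap floor and positive M", {
  ss <- toy_sumstats()
  ld <- toy_ld(ss)
  expect_error(estimate_h2(ss, ld, ldsr_config()), "floor")
  expect_error(estimate_h2(ss, ld, ldsr_config(min_snps = 3, m_override = -5)),
               "M")
})

test_that("h2 estimate recovers simulated truth within 2 jackknife SEs", {
  st <- small_study()
  fit <- estimate_h2(st$sim$sumstats1, st$ld, st$rc)
  expect_lt(abs(fit$h2 - st$cfg$h2_1), 2 * fit$h2_se)
  expect_gt(fit$mean_chi2, 1)  # polygenic signal inflates chi2
})

test_that("self-pair genetic correlation is exactly 1", {
  st <- small_study()
  pair <- harmonize_pair(st$sim$sumstats1, st$sim$sumstats1)
  fit <- estimate_rg(pair, st$ld, st$rc)
  expect_equal(fit$rg, 1, tolerance = 1e-12)
  expect_equal(fit$gencov, fit$h2_1, tolerance = 1e-12)
  expect_equal(fit$h2_1, fit$h2_2, tolerance = 1e-15)
})

test_that("rg is sign-equivariant under z2 negation with unchanged p-value", {
  st <- small_study()
  pair <- harmonize_pair(st$sim$sumstats1, st$sim$sumstats2)
  fit <- estimate_rg(pair, st$ld, st$rc)

  neg <- pair
  neg$z2 <- -neg$z2
  fitn <- estimate_rg(neg, st$ld, st$rc)
  expect_equal(fitn$rg, -fit$rg)
  expect_equal(fitn$gencov, -fit$gencov)
  expect_equal(fitn$intercept12, -fit$intercept12)
  expect_equal(fitn$rg_se, fit$rg_se)
  expect_equal(fitn$p, fit$p)
  expect_equal(fitn$h2_1, fit$h2_1)
})

test_that("rg estimation is symmetric in the trait order", {
  st <- small_study()
  p12 <- harmonize_pair(st$sim$sumstats1, st$sim$sumstats2)
  p21 <- harmonize_pair(st$sim$sumstats2, st$sim$sumstats1)
  f12 <- estimate_rg(p12, st$ld, st$rc)
  f21 <- estimate_rg(p21, st$ld, st$rc)
  expect_equal(f12$gencov, f21$gencov, tolerance = 1e-12)
  expect_equal(f12$rg, f21$rg, tolerance = 1e-12)
  expect_equal(f12$p, f21$p, tolerance = 1e-9)
  expect_equal(f12$h2_1, f21$h2_2, tolerance = 1e-12)
})

test_that("non-positive marginal heritability flags rg as undefined, not an error", {
  # z^2 decreasing in l2 forces a negative h2 slope for trait 2
  l2 <- seq(1, 10, length.out = 300)
  set.seed(13)
  z1 <- rnorm(300, sd = sqrt(1 + 0.1 * l2))
  z2 <- sqrt(pmax(2 - 0.15 * l2, 0.05)) * sign(rnorm(300))
  df <- data.frame(snp_id = paste0("rs", 1:300), chrom = "1",
                   bp = seq_len(300) * 1000L, z1 = z1, z2 = z2,
                   n1 = 1000, n2 = 1000)
  pair <- structure(df, trait_ids = c("a", "b"),
                    class = c("merged_pair", "data.frame"))
  ld <- ld_scores(data.frame(snp_id = df$snp_id, chrom = df$chrom,
                             bp = df$bp, l2 = l2))
  fit <- estimate_rg(pair, ld, ldsr_config(n_blocks = 20, min_snps = 50))
  expect_equal(fit$flag, "rg_undefined")
  expect_true(is.na(fit$rg))
  expect_false(is.na(fit$gencov))
})

test_that("estimates expose standard modelling methods", {
  st <- small_study()
  fit <- estimate_h2(st$sim$sumstats1, st$ld, st$rc)
  expect_named(coef(fit), c("h2", "intercept"))
  ci <- confint(fit)
  expect_true(ci["h2", 1] < fit$h2 && fit$h2 < ci["h2", 2])
  expect_output(print(fit), "heritability")

  pair <- harmonize_pair(st$sim$sumstats1, st$sim$sumstats2)
  rfit <- estimate_rg(pair, st$ld, st$rc)
  expect_named(coef(rfit), c("gencov", "rg", "intercept12", "h2_1", "h2_2"))
  expect_output(print(rfit), "rg")
})
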