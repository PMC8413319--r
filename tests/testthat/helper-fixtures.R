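# Shared fixture builders (everything generated in code, no data files).

# tiny hand-written sumstats table
toy_sumstats <- function(trait_id = "toy",
                         snp_id = paste0("rs", 1:6),
                         chrom = rep("1", 6),
                         bp = seq(1000L, 6000L, by = 1000L),
                         a1 = rep("A", 6), a2 = rep("G", 6),
                         z = c(1.2, -0.5, 2.0, 0.3, -1.1, 0.8),
                         n = rep(1000, 6),
                         maf = rep(0.2, 6), info = rep(1, 6)) {
  sumstats(data.frame(snp_id = snp_id, chrom = chrom, bp = bp, a1 = a1,
                      a2 = a2, z = z, n = n, maf = maf, info = info,
                      stringsAsFactors = FALSE),
           trait_id = trait_id)
}

# flat unit LD scores matching a sumstats table
toy_ld <- function(ss, l2 = NULL, m_ref = nrow(ss)) {
  ld_scores(data.frame(snp_id = ss$snp_id, chrom = ss$chrom, bp = ss$bp,
                       l2 = l2 %||% rep(1, nrow(ss)),
                       stringsAsFactors = FALSE),
            m_ref = m_ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated study shared by several test files (computed once)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_study <- function() {
  cached("small_study", {
    cfg <- sim_config(m = 1200L, n1 = 800L, n2 = 800L, h2_1 = 0.4,
                      h2_2 = 0.4, rg_true = -0.5, n_ref = 600L, seed = 42L)
    sim <- simulate_summary_stats(cfg)
    ld <- compute_ld_scores(sim$panel)
    list(cfg = cfg, sim = sim, ld = ld,
         rc = ldsr_config(n_blocks = 40L, min_snps = 50L))
  })
}

# shared 2-trait x 2-outcome fixture with a planted rg pattern:
# trait1-outcome1 rg = -0.5, every other pair 0
scan_fixture <- function() {
  cached("scan_fixture", {
    cfg <- sim_config(m = 1500L, n1 = 1200L, n2 = 1200L, h2_1 = 0.4,
                      h2_2 = 0.4, n_ref = 600L, seed = 77L)
    fx <- generate_study_fixture(cfg, rg_matrix = matrix(c(-0.5, 0, 0, 0), 2, 2),
                                 sentinel_frac = 0.1)
    ld <- compute_ld_scores(fx$panel)
    list(cfg = cfg, fx = fx, ld = ld,
         rc = ldsr_config(n_blocks = 40L, min_snps = 50L))
  })
}

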