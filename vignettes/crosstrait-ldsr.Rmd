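---
title: "Cross-trait LD score regression: model, implementation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait LD score regression: model, implementation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstraitr)
```

## The model

LD score regression (LDSR) estimates SNP heritability and cross-trait
genetic correlation from GWAS summary statistics alone. Under a polygenic
model in which every SNP carries an infinitesimal standardized effect, the
expected association strength of SNP $j$ grows with how much polygenic
signal it tags — its LD score
$\ell_j = \sum_k r^2_{jk}$, the sum of squared allelic correlations with
all SNPs in a surrounding window (including itself). For a trait measured
on $N$ individuals with $M$ SNPs in the reference universe,

$$\mathrm{E}[z_j^2] = 1 + Na + \frac{N h^2}{M}\,\ell_j ,$$

so a weighted regression of squared Z scores on $\ell_j$ has slope
$N h^2 / M$, and its intercept $1 + Na$ absorbs genomic inflation from
population stratification or cryptic relatedness — confounding shifts
every $z_j^2$ regardless of $\ell_j$, while true polygenic signal grows
with $\ell_j$. For two traits,

$$\mathrm{E}[z_{1j} z_{2j}] = \frac{\rho N_s}{\sqrt{N_1 N_2}} +
  \frac{\sqrt{N_1 N_2}\,\rho_g}{M}\,\ell_j ,$$

where $\rho_g$ is the genetic covariance, $N_s$ the number of overlapping
samples and $\rho$ the total phenotypic correlation among them: shared
samples move the intercept, never the slope. The genetic correlation is
$r_g = \rho_g / \sqrt{h^2_1 h^2_2}$. `estimate_h2()` and `estimate_rg()`
fit exactly these two regressions.

## Estimation details

**Weights.** Both regressions are heteroskedasticity-and-overcounting
weighted. After an initial unweighted pass, each of `max_weight_iters`
(default 2) passes sets $v_{kj} = 1 + N_k \hat h^2_k \ell_j / M$ from the
previous pass's marginal heritability fits (clamped to $[0,1]$ for weight
purposes only) and uses $1/(\tilde\ell_j v_{1j} v_{2j})$ for the
cross-trait fit and $1/(\tilde\ell_j v_{kj}^2)$ for the marginal fits,
with $\tilde\ell_j = \max(\ell_j, 1)$ flooring reciprocal weights. The two
marginal fits and the cross fit run in lockstep passes: when the two Z
vectors coincide the three regressions are numerically identical, which is
why a trait paired with itself returns $r_g = 1$ to machine precision
rather than approximately.

**Slope conversion.** $\hat h^2 = \text{slope} \cdot M / \bar N$ and
$\hat\rho_g = \text{slope} \cdot M / \sqrt{\bar N_1 \bar N_2}$, with
$\bar N$ the mean per-SNP sample size (a max-$N$ convention is available).
$M$ defaults to the LD score table's reference SNP count, not the
regression SNP count, because the slope-to-heritability scaling must match
the universe over which the LD scores were accumulated; it is overridable.

**Uncertainty.** Standard errors come from a delete-one-block jackknife
over `n_blocks` (default 200) contiguous blocks in genome order, with
block sizes differing by at most one and regression weights held fixed
across replicates. The $r_g$ jackknife re-does the full ratio — both
marginal slopes and the cross slope — in every leave-one-block-out
replicate, so the standard error reflects the denominator's noise too.
P-values are two-sided normal on $r_g / \mathrm{se}(r_g)$; no small-sample
t correction is applied since the default block count is large. Estimates
of $r_g$ outside $[-1, 1]$ are reported as computed and flagged, never
clamped: near-boundary truth legitimately overshoots. When a marginal
heritability estimate is non-positive, $r_g$ is undefined; the fit is
flagged (`rg_undefined`) and the genetic covariance is still reported.

## Harmonization and quality control

`read_sumstats()` accepts delimited text with a header, auto-recognizing
common column names including the minimal SNP/A1/A2/Z/N dialect; Z is
computed as beta/se when absent, rows with se = 0 are dropped and counted,
and every copy of a duplicated SNP identifier is removed because its
identity (and hence its LD score join) is ambiguous. `filter_snps()`
retains autosomal SNPs with MAF strictly above 0.01 and INFO strictly
above 0.90 by default — strict inequalities matching the usual "greater
than" phrasing — optionally restricted to a whitelist of well-imputed
variants; rows missing MAF or INFO while a threshold is active are dropped
(configurable). `harmonize_pair()` aligns the second trait's Z to the
first trait's effect allele, flipping signs for swapped alleles and
reconciling strand-complement reports; A/T and C/G SNPs are always
dropped, since for them a strand flip is indistinguishable from an allele
swap. These two rules — drop-all duplicates and drop strand-ambiguous —
are standard harmonization practice; the alternatives (keep-first,
frequency-based disambiguation) trade silent sign errors for a handful of
extra SNPs.

## Region exclusion

`build_exclusion_regions()` places an interval of ±`flank_kb` (default
500 kb) around each sentinel variant of an association list — for
lung-cancer work, the 467 smoking-behavior sentinels — merging overlapping
or book-ended intervals, and `apply_exclusion()` removes every SNP whose
coordinate falls inside any region. Bounds are 1-based and inclusive on
both ends; a SNP exactly 500,000 bp from a sentinel is removed. Matching
is by coordinates rather than identifiers so the filter is independent of
SNP naming. BED export converts to 0-based half-open at the file boundary.

## The scan

`run_scan()` drives every trait × outcome stratum × pass combination,
where the two passes analyze all SNPs and the sentinel-excluded set. The
Bonferroni denominator is the total comparison count across both passes —
with 347 traits and 6 outcome strata, 2082 tests per pass and 4164
comparisons, giving the familiar 0.05/4164 ≈ 1.2 × 10⁻⁵ cutoff
(−log₁₀ ≈ 4.92). Outcome and trait heritabilities are estimated once per
(table, pass) and reused. A failing pair (e.g. non-positive heritability)
produces a flagged row rather than aborting, so the comparison count
stays auditable; significance flags are stored alongside p and the cutoff
so they can be recomputed from the file.

## The synthetic generator

`simulate_summary_stats()` and `generate_study_fixture()` emulate the
study's inputs at desk scale: 5000 SNPs in 25-SNP LD blocks laid over 22
autosomes at 1 kb spacing, cohorts of 2000, a held-out reference panel of
1000 for LD scores. Within a block, latent Gaussians with first-order
autoregressive correlation are thresholded at each SNP's allele-frequency
quantile, twice per individual, giving dosages in {0, 1, 2}. Each block
draws its own AR correlation as `block_rho`·√U (U uniform, default
ceiling 0.98): the resulting mix of tight and loose blocks spreads the LD
score distribution, which is what identifies the regression slope against
the intercept — a homogeneous-LD genome is nearly degenerate for LDSR at
this scale. Effect sizes follow the infinitesimal model, bivariate normal
with variances $h^2_k/m$ and covariance $r_g\sqrt{h^2_1 h^2_2}/m$, because
that is the model under which the LDSR expectation holds exactly.
Overlapping cohort members share genotypes and receive residuals
correlated so the total phenotypic correlation equals `rho_pheno`.
Confounding draws two subpopulations' allele frequencies Balding–Nichols
style with divergence `confound_f` and shifts subpopulation 2's phenotype
mean by `pheno_shift` (default 0.25 residual SD) on both traits —
inflation that is flat in $\ell_j$ and therefore lands in the intercept.

Quantitative phenotypes stand in for the case-control outcome: LDSR
operates identically on observed-scale Z scores, and liability-scale
conversion is out of scope. What the generator does *not* emulate:
real-genome LD (no long-range structure, no MAF–LD coupling),
chromosome-scale SNP density, case-control ascertainment, cryptic
relatedness. Passing tests therefore demonstrate the estimator's internal
consistency under its own model assumptions, not robustness to every
violation found in real data.

## Numerical choices and problem sizes

LD scores use a ±1000 kb physical window (the common 1 cM ≈ 1 Mb
convention; no genetic-map ingestion) and the unbiased adjustment
$\tilde r^2 = \hat r^2 - (1 - \hat r^2)/(n_{ref} - 2)$ on every cross
term, never the self term; negative adjusted terms are retained so sums
stay unbiased, and scores are floored at a tiny positive value.
Monomorphic panel SNPs are rejected at construction. The SNP-overlap floor
for estimation defaults to 200. The test suite runs recovery at
m = 5000, n = 2000 with 100 jackknife blocks (50-SNP blocks, two LD blocks
each, so blocks exceed the LD correlation length) and calibration at
m = 3000, n = 1000 with 60 blocks over 200 replicates; replicate loops
share one SNP universe and one reference LD score table, mirroring how a
single European reference panel serves all traits in practice.

## Known limitations

* $\hat r_g$ is a ratio; with desk-scale power ($\hat h^2$ relative error
  near 50%), Jensen-type inflation of $|\hat r_g|$ of order 0.1 appears
  when averaging across independently redrawn SNP universes and reference
  panels, even though $\hat\rho_g$ and $\hat h^2$ are unbiased and the
  jackknife intervals retain close-to-nominal coverage. Averaged over
  replicate cohorts under a fixed universe and reference — the situation a
  real analysis is in — $\hat r_g$ centers on the planted value, and that
  is the design the estimand-consistency test uses. At biobank scale the
  distinction is negligible.
* The 2082-tests-per-pass design treats outcome strata as independent
  although real strata share controls; the package reports, but does not
  correct for, that dependence.
* No liability-scale heritability conversion, no annotation-partitioned
  LD scores, no cM windows, no genotype-level QC.

## A word on scope

The package reproduces the *form* of a phenome-wide cross-trait scan —
heritability, genetic correlation, standard error and p-value per
trait/outcome/pass with Bonferroni flags — on synthetic studies with known
truth. The restricted consortium and biobank inputs behind published
lung-cancer scans are deliberately not required, and their headline
estimates are not asserted anywhere in the test suite.
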