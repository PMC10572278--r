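# mrshare

Tools for asking whether two complex diseases share *causal* genetic risk,
using nothing but published GWAS summary statistics and gene lists. The
motivating application is the pair Sjögren's Disease (SjD) and Systemic
Lupus Erythematosus (SLE) — two autoimmune diseases with extensive
clinical and serologic overlap — but every function is generic over any
exposure/outcome trait pair.

Three complementary analyses are provided:

1. **Gene-list overlap enrichment.** Given two lists of predicted causal
   genes drawn from a common background of `N` genes (e.g. a whole-proteome
   interaction network), the observed overlap `k` between a query list of
   `n` genes and a subject list of `K` genes is tested against the
   hypergeometric null: expected overlap `nK/N`, fold enrichment
   `k/(nK/N)`, and the inclusive upper tail `P(X ≥ k)` computed in log
   space so deep tails never underflow.

2. **Genomic risk-interval overlap enrichment.** Associated variants are
   merged into loci (adjacent variants within 250 kb), each locus is
   represented by the 500 kb window centered on its lead variant, and the
   number of query windows touching any subject window is tested against
   the same hypergeometric null with the genome divided into 500 kb blocks
   as the background (3,298,912,062 bp / 500 kb ≈ 6598 blocks).

3. **Two-sample Mendelian randomization.** With per-variant exposure
   effects γ̂ⱼ (se σ_γⱼ) and outcome effects Γ̂ⱼ (se σ_Γⱼ) harmonized to a
   common effect allele, the per-variant Wald ratio β̂ⱼ = Γ̂ⱼ/γ̂ⱼ estimates
   the causal effect β_XY. The suite combines them four ways:
   - **IVW**: weighted regression of Γ̂ on γ̂ through the origin, weights
     1/σ_Γ², with a multiplicative random-effects standard error by
     default;
   - **MR-Egger**: the same regression with an intercept (estimated
     directional pleiotropy) after orienting all γ̂ⱼ > 0; slope = causal
     effect under the InSIDE assumption;
   - **weighted median**: inverse-variance weighted median of the ratios,
     consistent when ≥50% of the weight is valid;
   - **weighted mode**: mode of the weighted kernel density of the ratios.
   Plus Cochran's Q heterogeneity for IVW and Egger, the Egger intercept
   test, leave-one-out and single-variant sensitivity tables, and
   funnel/scatter tables ready for plotting. Upstream of estimation:
   genome-wide significance filtering (p < 5×10⁻⁸), an explicit
   exclusion-list mechanism for relevance QC, allele harmonization with
   palindromic-variant policies (drop, or infer by MAF < 0.3), and greedy
   LD clumping.

A synthetic-data module generates paired two-sample GWAS tables with known
causal structure (true effect, pleiotropy, InSIDE violations, winner's
curse selection, palindrome/strand/swap presentation) and gene/locus lists
with known overlap, so the entire pipeline runs and is tested fully
offline.

## Worked example

```r
library(mrshare)

# Gene-list enrichment at published list sizes: 23 query genes vs the
# 54-gene monogenic subject network on a 19,303-gene background, overlap 3
hypergeom_enrichment(k = 3, n = 23, K = 54, N = 19303)
#>       k     n     K     N expected  fold   p_upper log_p
#>       3    23    54 19303   0.0643  46.6 0.0000352 -10.3

# The expected overlap (0.06), fold (~46) and upper-tail p (3.5e-05) say:
# under random draws one would expect to share 0.06 genes; sharing 3 is a
# ~47-fold excess, with probability 3.5e-05 of occurring by chance.

# A full MR run on a simulated dataset with true causal effect 0.5
cfg <- simulation_config(n_instruments = 12, theta = 0.5, seed = 101,
                         se_gamma = c(0.02, 0.05), se_Gamma = c(0.04, 0.09))
sim <- simulate_two_sample(cfg)
rep <- run_mr_report(sim$exposure, sim$outcome, n_boot = 1000, seed = 42)
rep$results
#> <mr_result_set: 10 instruments>
#>           method n_snps  beta     se       p
#>              IVW     10 0.483 0.0547 1.1e-18
#>  weighted-median     10 0.500 0.0707 1.5e-12
#>    weighted-mode     10 0.504 0.0973 2.2e-07
#>         MR-Egger     10 0.593 0.1810 1.1e-02
```

Two of the 12 simulated variants were palindromic and dropped by the
default harmonization policy, hence 10 instruments. All four estimators
recover the true effect 0.5 within their standard errors; the Egger
intercept (−0.040, p = 0.54) correctly finds no directional pleiotropy.
Converting a log-odds estimate to the odds-ratio scale:

```r
effect_transform(0.94, 0.13)[, c("odds_ratio", "ci_low", "ci_high")]
#> odds_ratio ci_low ci_high
#>       2.56   1.98    3.30
```

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`:

```sh
Rscript analysis/01_overlap_enrichment.R   # gene-list + locus-window enrichment
Rscript analysis/02_simulate_gwas.R        # four synthetic two-sample datasets
Rscript analysis/03_mr_pipeline.R          # full MR reports per dataset
Rscript analysis/04_method_properties.R    # estimator calibration summary
```

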