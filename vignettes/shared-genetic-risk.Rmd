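---
title: "Assessing shared causal genetic risk from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing shared causal genetic risk from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrshare)
```

Two clinically similar diseases can resemble each other for many reasons;
only some of them are causal. This package implements three complementary
ways of asking whether two phenotypes share *causal* genetic risk using
only published GWAS summary statistics and gene lists: over-representation
of shared predicted causal genes, over-representation of overlapping
genomic risk intervals, and two-sample Mendelian randomization (MR) in
both directions. This vignette describes the models, the tunable
parameters, the synthetic-data generator used for validation, and the
numerical and design choices a user should know about.

## Overlap enrichment

Both overlap analyses use the same statistic. With a background of $N$
elements of which $K$ belong to the subject set, and a query draw of $n$
elements showing $k$ in common, the null distribution of the overlap is
hypergeometric. We report the expected overlap $nK/N$, the fold
enrichment $k/(nK/N)$, and the inclusive upper tail
$P(X \ge k) = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
the standard over-representation convention. The tail is accumulated in
log space from `lchoose` terms, so values down to the double-precision
floor (~1e-300) are exact; the test suite checks every parameter
combination with $N \le 25$ against exact enumeration, and spot-checks
the log tail against the distribution's survival function.

For **gene lists**, symbols are upper-cased and de-duplicated before
intersection; the default background of 19,303 genes is the size of a
whole-proteome interaction network from which predicted causal gene lists
are typically drawn. The published table this analysis mirrors is
internally ambiguous about one row (the narrative reports an overlap of
19 against a 131-gene list, while the table's expected value implies a
127-gene list and its fold implies an overlap of 20). We deliberately
expose $k$, $n$, $K$, $N$ as explicit parameters and compute all
parameterizations side by side in `analysis/01_overlap_enrichment.R`
rather than asserting one reconciliation. Fold enrichment is reported at
full precision; display formatting (2 decimals for the expectation, 2
significant figures for $p$) is separate from computation. Note that the
exact tail for the monogenic row ($k=3$, $n=23$, $K=54$, $N=19303$) is
$3.52\times10^{-5}$; the external web calculator historically used for
such tables displays $3.6\times10^{-5}$, a one-unit-in-the-last-digit
difference we attribute to that tool's display, since exact enumeration,
the survival function, and the log-space sum agree here to 12 digits.

For **genomic intervals**, associated variants are merged into loci
transitively whenever adjacent same-chromosome variants lie within
250 kb of each other ("within" read as inclusive), each locus is
represented by the 500 kb half-open window centered on its lead variant
(smallest p-value; left edge clipped at zero), and $k$ counts query
windows intersecting at least one subject window — not intersecting
pairs, because the hypergeometric draw is over query loci. Two windows
overlap iff they share a chromosome and their centers differ by less than
the window size; abutting half-open windows do not overlap, which keeps
the count consistent with the background model of the genome divided
into disjoint 500 kb blocks, $\mathrm{round}(3{,}298{,}912{,}062 / 500{,}000) = 6598$
of them (halves rounded away from zero). Chromosome labels `chr1` and
`1` are treated as equal; no special handling is given to the MHC region.
Where a merged locus spans several variants, the window is centered on
its lead variant — the natural reading when lead-variant windows and
proximity-merged loci are combined in one pipeline.

## Two-sample Mendelian randomization

The estimand is $\beta_{XY}$, the causal effect of the exposure on the
outcome on the log-odds scale. For instrument $j$ with harmonized
exposure effect $\hat\gamma_j$ (se $\sigma_{\gamma j}$) and outcome
effect $\hat\Gamma_j$ (se $\sigma_{\Gamma j}$):

* **Wald ratio** $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with
  first-order delta standard error $\sigma_{\Gamma j}/|\hat\gamma_j|$
  (a second-order option adds
  $\hat\Gamma_j^2\sigma_{\gamma j}^2/\hat\gamma_j^4$).
* **IVW** is weighted least squares of $\hat\Gamma$ on $\hat\gamma$
  through the origin with weights $1/\sigma_{\Gamma j}^2$; algebraically
  the inverse-variance weighted mean of the Wald ratios. The default
  standard error is multiplicative random effects: the fixed-effect se
  $1/\sqrt{\sum w_j\hat\gamma_j^2}$ scaled by the residual standard
  deviation when that exceeds one (inflation only, never deflation).
  This default reflects that disease-pair analyses typically show real
  effect heterogeneity; a fixed-effect model is available by argument.
* **MR-Egger** adds an intercept to the same weighted regression after
  orienting every instrument to $\hat\gamma_j > 0$, because the Egger
  estimate is not invariant to allele-coding sign. The slope estimates
  $\beta_{XY}$ under the InSIDE assumption; the intercept estimates mean
  directional pleiotropy and is tested with a $t$ distribution on $n-2$
  degrees of freedom (small-$n$ robustness), as is the slope.
* **Weighted median**: ratios are ordered, weights (normalized inverse
  first-order ratio variances) accumulated, and the estimate interpolated
  at standardized cumulative position $1/2$ using
  $p_j = (S_j - w_j/2)/S_n$.
* **Weighted mode**: the argmax of a weighted Gaussian kernel density of
  the ratios with bandwidth
  $h = \phi \cdot 0.9\,\min(\mathrm{sd}_w, \mathrm{mad}_w/0.6745)\,n^{-1/5}$
  ($\phi = 1$ by default; larger values smooth more). If the weighted MAD
  degenerates to zero with distinct ratios, the sd term alone is used; if
  all ratios coincide, that common value is returned.

Median and mode standard errors come from a parametric bootstrap
(default 1000 replicates): $(\hat\gamma_j, \hat\Gamma_j)$ are resampled
from their normal sampling distributions and the point estimate
recomputed; the se is the standard deviation across replicates. All
stochastic operations take an explicit seed; unseeded calls draw one from
the session RNG and log it. Setting `n_boot = 0` skips the bootstrap when
only point estimates are needed.

**Heterogeneity** is Cochran's $Q = \sum w_j(\hat\Gamma_j - \mathrm{fit}_j)^2$
with $w_j = 1/\sigma_{\Gamma j}^2$, about the IVW fit ($n-1$ df) and the
Egger fit ($n-2$ df); on this scale it equals the ratio-scale $Q$ with
first-order ratio weights, and the Egger $Q$ can never exceed the IVW $Q$.
P-values are $\chi^2$ upper tails. The sensitivity suite provides
leave-one-out IVW (falling back to the Wald ratio when one instrument
remains), a single-variant table whose overall rows equal the IVW and
Egger fits exactly, and funnel ($\hat\beta_j$ vs $1/\mathrm{se}_j$) and
scatter tables with per-method fitted lines.

### Harmonization and clumping

Exposure and outcome records are joined on variant id (an optional strict
mode also requires agreeing coordinates). The exposure defines the
reference orientation: outcome rows with swapped alleles have their
effect negated and frequency reflected; rows matching only after strand
complementation are flagged and complemented (complementation alone never
changes sign); indels are matched exactly or exactly-swapped but never
complemented. Palindromic variants (A/T, C/G) cannot be oriented from
labels. Two policies are exposed, because published practice is genuinely
double-minded about them: `drop` (default — the conservative choice when
strand provenance is unknown) and `infer`, which keeps a palindrome only
when both effect-allele frequencies fall on the same side of the 0.3 MAF
cutoff after label alignment. Alignment never changes effect magnitudes
or standard errors, and harmonizing an already harmonized pair is the
identity — both properties are tested over randomized inputs.

Clumping is greedy: the smallest exposure p-value becomes an index (ties
broken by chromosome, position, id), all unclumped same-chromosome
variants within the window with $r^2$ at or above the threshold are
removed, and the process repeats. Defaults $r^2 = 0.001$ and a 10 Mb
window mirror common two-sample MR practice; the source of $r^2$ is a
user-supplied offline matrix or long table (computing LD from genotype
panels, and proxy-variant search, are out of scope). Pairs without LD
information are treated as unlinked with a warning. The retained set is
order-invariant and provably LD-pruned, both tested.

## The synthetic-data generator

`simulate_two_sample()` draws true exposure effects
$\gamma_j \sim N(0, \sigma_\gamma^2)$, observed effects with independent
noise in each of the two samples (the defining feature of two-sample MR),
and outcome effects $\Gamma_j = \theta\gamma_j + \mathrm{sign}(\gamma_j)\,\alpha_j + \lambda u_j$
where $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ on a configurable
fraction of instruments and $\lambda u_j$ is an optional confounded
component shared with the exposure effect (correlated pleiotropy).
Directional pleiotropy is expressed relative to the exposure-increasing
allele: with $\alpha$ attached to an arbitrary coding and mean-zero
$\gamma$, a nonzero $\mu_\alpha$ would be unidentifiable after the sign
reorientation Egger performs, so this convention is what makes "mean
pleiotropy" a meaningful target. `inside_corr` correlates $\alpha_j$ with
instrument strength $|\gamma_j|$ to violate InSIDE on demand. Instrument
selection at $p < 5\times10^{-8}$ is modelled by rejection sampling of
the observed exposure association, which induces realistic winner's
curse; `selection_threshold = 1` disables it. Effect-allele frequencies
are Uniform(0.05, 0.95), except palindromic variants, which sit near 0.5
(width configurable) to exercise the MAF rule; configured fractions of
non-palindromic outcome rows are emitted strand-complemented and/or
allele-swapped (palindromic rows are excluded from those sets so the
truth record stays unambiguous). The truth record retains every latent
quantity, sufficient to predict each stage's output without
re-simulation.

What the generator does *not* emulate: LD structure between instruments
(LD enters only through the user-supplied $r^2$ table), sample overlap
between the two GWAS, allele-frequency differences between ancestries,
and case-control ascertainment effects on the log-odds scale. Passing
calibration tests on these simulations therefore demonstrates the
estimators' statistical correctness under their stated assumptions, not
robustness to those real-data complications.

## Calibration scenarios and problem sizes

The validation suite runs, per scenario, 500 replicates in a
strong-instrument regime: $\sigma_\gamma = 0.25$,
$\sigma_{\gamma j} = 0.002$, $\sigma_{\Gamma j} = 0.05$, selection
disabled, and presentation features off (they are tested separately).
The tiny exposure-side error is deliberate: Egger regression assumes
exposure effects measured without error (the NOME condition), and a
mean-zero $\gamma$ distribution otherwise allows rare sign
misorientations near $\gamma = 0$ that would leak pleiotropy sign into
the intercept. Constant $\sigma_\Gamma$ makes the multiplicative
random-effects model exactly specified under additive balanced
pleiotropy, so IVW coverage has a clean nominal target. The scenarios:
coverage and type-I error at $J = 30$, $\theta \in \{0.5, 0\}$,
$\sigma_\alpha = 0.05$; Egger intercept recovery at $J = 50$,
$\mu_\alpha = 0.05$; weighted-median robustness at $J = 30$ with 40% of
instruments given strong directional pleiotropy ($\mu_\alpha = 0.4$).
The analysis drivers use 200-replicate versions of the same scenarios,
and the simulated study datasets mirror the instrument counts of the
four motivating analyses (12, 32, 4, 30).

## Numerical and design notes

* P-values are two-sided normal ($2\Phi(-|z|)$) everywhere except the
  Egger slope and intercept ($t_{n-2}$). Log p-values are carried
  alongside; anything below 1e-300 prints as `<1e-300`.
* Odds-ratio-scale inputs are converted by $\beta = \ln \mathrm{OR}$,
  $\mathrm{se} = (\ln \mathrm{CI_{hi}} - \ln \mathrm{CI_{lo}})/(2 \times 1.96)$;
  when only an OR and p-value are given, the documented fallback
  $\mathrm{se} = |\ln \mathrm{OR}|/|\Phi^{-1}(p/2)|$ is used (published
  sources rarely state how they recovered such se's; this is our choice).
* The strict beta/se-vs-p consistency check is off by default because
  published tables round; it can be enabled when ingesting machine
  precision data.
* Instruments with $\hat\gamma_j = 0$ are dropped from ratio-based
  methods with a diagnostic; degenerate instrument counts produce
  classed errors, and `mr_run_all()` converts them into explicit
  `not_run` rows rather than failing the whole suite.
* Ties in clumping and in lead-variant selection are broken
  deterministically (chromosome, position, id), making every pipeline
  output reproducible byte-for-byte given a seed.

## Limitations

The package ingests flat summary-statistic tables and gene lists only; it
does not query GWAS repositories, compute LD from reference panels,
search for proxy variants, or annotate loci to genes — those steps need
external databases and are upstream of this analysis. The interval
enrichment inherits the block-background approximation (windows may
straddle block boundaries); permutation-based interval enrichment is out
of scope. MR extensions that were not part of the motivating analysis
(MR-PRESSO, multivariable MR, Steiger filtering, contamination mixtures)
are deliberately absent.
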