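---
title: "Methods: signature construction, consensus aggregation and connectivity"
author: "sigconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature construction, consensus aggregation and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconn)
```

This vignette is the package's account of its statistical machinery: the
models and formulas, the assumptions behind them, the tunable parameters and
their defaults, the numerical conventions adopted where a formula is silent,
and what the synthetic-data generator does and does not emulate.

## The signature model

A perturbation signature over a gene space of size $N$ is the pair
$(\mathbf d, \mathbf p)$: per-gene log-scale differential expression
$d_i$ (a $\log_2$ ratio for expression contrasts, a z-score for
L1000-style consensus signatures — the metrics below only assume a
symmetric, log-like scale) and a two-sided p-value $p_i \in (0, 1]$. The
p-vector is optional; its absence restricts which connectivity metrics
apply. Gene identifiers are opaque strings, upper-cased on entry, and gene
spaces are matched by exact identifier intersection — the package bundles no
identifier mapping, and libraries are harmonized to the intersection so
correlation metrics never see missing values.

## Constructing signatures from two-group experiments

`create_signature()` contrasts a treatment group A against a baseline group
B of a log-scale expression matrix:

$$d_g = \bar x_{A,g} - \bar x_{B,g}, \qquad
s_g^2 = \frac{\sum_A (x - \bar x_A)^2 + \sum_B (x - \bar x_B)^2}{n_A + n_B - 2}.$$

Gene-wise variances are shrunk toward a common prior with the standard
empirical-Bayes scaled-inverse-$\chi^2$ moment-matching fit on log variances
(delegated to `limma::squeezeVar`, which is the canonical implementation of
that fit), giving posterior variances $\tilde s_g^2$ and prior degrees of
freedom $d_0$; the moderated statistic
$t_g = d_g / (\tilde s_g \sqrt{1/n_A + 1/n_B})$ is referred to a
t distribution with $d_0 + n_A + n_B - 2$ degrees of freedom. Setting
`prior_df = 0` disables shrinkage and reduces the test to the ordinary
pooled two-sample t-test (verified against `t.test` in the suite); the
default fit is cross-checked against the independent `limma::lmFit` +
`eBayes` route. Assumptions: approximately normal within-group values on the
log scale and exchangeable gene variances for the prior. Raw RNA-seq counts
violate the first and are out of scope — the loader warns when a matrix
looks like counts and suggests a `log2(CPM + 1)` transform. Confounders are
handled by *sample filtering only* (`filter_samples()`, recorded in the
dataset provenance); there is no covariate regression.

Genes with exactly zero pooled variance (possible in degenerate fixtures)
are excluded from the prior fit and assigned the prior variance.

## Replicate aggregation: MODZ, QC, and the weighted t-test

Level-4-style replicate z-score signatures $Z_{g,i}$, $i = 1,\dots,R$, are
collapsed by `modz()` into the consensus
$\mathrm{MODZ}_g = \sum_i w_i Z_{g,i}$ with correlation-based weights:

* $R \le 2$: equal weights (there is no basis for asymmetry);
* $R \ge 3$: the raw weight of replicate $i$ is the mean of its pairwise
  Spearman correlations (over all $N$ genes — no landmark subset is
  assumed) with the other replicates, **clipped below at 0.01, then
  normalized** to sum to one. The clip keeps an anti-correlated outlier
  replicate from receiving zero or negative weight while still discounting
  it by two orders of magnitude; the clip-then-normalize order is fixed,
  and the constant is isolated in `modz_weights()` for easy revision.

A pair involving a constant replicate column has no defined rank
correlation; it is set to 0 with a warning.

Reproducibility QC is `distil_cc_q75()`: the 75th percentile of the
$R(R-1)/2$ pairwise Spearman correlations, computed with type-7 linear
interpolation between order statistics (the most common quantile default; a
choice this package fixes explicitly because the defining formula does not).
A signature passes QC iff the statistic strictly exceeds 0.2, and the
`aggregate` command excludes failing groups from library builds unless
`--keep-failed-qc` is given.

Per-gene inference against zero reuses the MODZ weights: the weighted
variance

$$s_g^2 = \frac{\sum_i w_i (Z_{g,i} - \mathrm{MODZ}_g)^2}{1 - \sum_i w_i^2}$$

is unbiased under $\sum_i w_i = 1$, is shrunk with the same
empirical-Bayes fit as above, and the moderated
$t_g = \mathrm{MODZ}_g / \sqrt{\tilde s_g^2 \sum_i w_i^2}$ gets
$d_0 + (R - 1)$ degrees of freedom ($\operatorname{Var}(\mathrm{MODZ}_g) =
\sigma_g^2 \sum_i w_i^2$ for independent replicates). With a single
replicate no inference is attempted and the consensus carries no p-values.
Consensus gene signatures (`cgs_aggregate()`) treat member signatures'
$\mathbf d$ vectors as replicate columns and apply exactly this machinery,
tagging the result `signature_type = "CGS"`.

## Connectivity metrics

`connect_query()` scores a query against every library signature and
dispatches on the query type; p-values are Benjamini–Hochberg adjusted
across the queried library and results are sorted by p ascending with
$|$score$|$ descending, then signature id, as deterministic tie-breaks. The
default significance threshold in reporting is FDR 0.05.

**Extreme Pearson (library-member queries).** Signed significances
$s_i = \operatorname{sign}(d_i)\,(-\log_{10} p_i)$ concentrate each
signature's evidence; the extreme transform zeroes everything but the $k$
most positive and $k$ most negative entries ($k = 100$ by default, matching
the two ~100-gene tails conventionally used for ~1,000-gene L1000
signatures). The boundary inequalities are inclusive, so ties with the
$k$-th value survive and more than $2k$ nonzero entries are possible; when
$N < 2k$ every gene is already extreme and the vector passes through with a
warning. The score is the standard Pearson correlation of the two extreme
vectors over **all** intersected genes, zeros included — the literal reading
of the definition; `extreme_support = "union_nonzero"` offers the
alternative support restricted to genes extreme in at least one signature.
The p-value uses the correlation t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n$ the scored gene count; the test suite
measures its null calibration under the synthetic generator.

**Weighted correlation (uploaded full signatures).** The score is the
weighted Pearson correlation of the two $\mathbf d$ vectors with per-gene
weights $w_i = (-\log_{10} p^{q}_i)(-\log_{10} p^{\ell}_i)$ — the product
reading of the two significance terms; a query without p-values uses the
library term alone. Zero-weight genes drop out. For the p-value the
t-transform needs an effective sample size, and here a subtlety matters:
**the weights are functions of the very observations being correlated**
(p-values derive from the $d$'s), so Kish's classical
$n_{\mathrm{eff}} = (\sum w)^2 / \sum w^2$ — exact for weights carrying no
information about the data — understates the null variance of the weighted
correlation and yields anti-conservative p-values. The package therefore
defaults to the self-normalized effective sample size

$$n^{*}_{\mathrm{eff}} =
\frac{\left(\sum_i w_i \tilde x_i^2\right)\left(\sum_i w_i \tilde y_i^2\right)}
     {\sum_i (w_i \tilde x_i \tilde y_i)^2},$$

the sandwich-type estimate of the inverse null variance of $r_w$ built from
the weighted products themselves ($\tilde x, \tilde y$ centered at the
weighted means). It agrees with Kish's form asymptotically when the weights
are uninformative and stays calibrated when they are not; the acceptance
suite verifies the resulting null connection rate at the 5% level.
`effective_n = "kish"` restores the classical form for comparison. When the
effective sample size does not exceed 2 the p-value is reported as 1 with a
flag.

**Up/down correlation.** Up/down queries are encoded $+1$/$-1$ and
correlated with the library $\mathbf d$ over the matched genes. For a
binary regressor the correlation t-transform is *algebraically identical*
to the two-sided two-sample equal-variance t-test comparing $\mathbf d$
between up- and down-genes (point-biserial equivalence) — the package
computes the t-transform and the suite confirms agreement with the
textbook t-test beyond ten significant digits. If matching leaves fewer
than two genes or an empty side, the query degrades to the gene-list
metric with a warning.

**Random Set (gene lists).** With per-gene scores
$g_i = -\log_{10} p^{\ell}_i$, the mean over the $m$ matched query genes is
standardized by the exact moments of the mean of a uniformly random
size-$m$ set drawn without replacement:
$\mu$ the grand mean, $\sigma_m^2 = \frac{N-m}{N-1}\frac{\sigma^2}{m}$ with
$\sigma^2$ the population variance. The normal approximation to
$z = (\bar X - \mu)/\sigma_m$ is used throughout (standard Random Set
practice); exhaustive enumeration validates the moments exactly for small
universes in the tests. All scores equal means no enrichment is decidable:
$z = 0$, $p = 1$ by convention. Gene-list p-values are two-sided.

**Perturbagen connectivity.** The per-signature connectivity scores of the
whole queried library form the universe; each perturbagen's member set is
tested with the same Random Set statistic, by default on **absolute**
scores with an upper-tail p — "unusually connected" regardless of sign —
because a perturbagen whose signatures all strongly anti-correlate with the
query is as interesting for repurposing as one that correlates; `signed =
TRUE` ranks concordant connections instead. The perturbagen universe is the
whole queried library (not restricted to matching cell line or time);
restriction is available by filtering the library before querying.

## Numerical conventions

* p-values are clipped below at $10^{-300}$ before $-\log_{10}$, so signed
  significances stay finite in double precision; reported p-values are
  clamped into $(0, 1]$ (a perfect correlation reports $10^{-300}$, not 0).
* Correlation-undefined cases (zero variance on the scored support) abort
  pairwise calls with a diagnostic and flag rows in library scans.
* In a ranked result set, the smallest BH-adjusted value is never below the
  smallest p-value, and adjusted values are monotone along the ranking —
  both properties are asserted in the suite.
* Simulations draw all randomness inside `withr::with_seed`, so a fixed
  seed yields byte-identical outputs and caller RNG state is untouched.

## What the generator emulates — and what it does not

`simulate_diffexp()` draws gene baselines from $\mathcal N(8, 2^2)$
(typical log2 microarray intensities), adds i.i.d. $\mathcal N(0,
\sigma^2)$ noise with $\sigma = 1$ by default, and plants a fixed
log-fold-change on a random gene subset of group A. `simulate_replicates()`
models Level-4 replicates as a latent standard-normal consensus plus
i.i.d. replicate noise ($\sigma = 0.3$ by default — reproducible but not
perfect replicates, the regime MODZ weighting is designed for).
`simulate_library()` draws null signatures as independent standard-normal
z-score vectors with $p_i = 2\Phi(-|z_i|)$ (uniform under the null) and
plants correlated pairs and perturbagen groups as bivariate-normal effects
at a target correlation $\rho$; because p-values derive from the planted
z-scores, the plant is visible to *every* metric — signed-significance
tails, weighted correlation, and Random Set alike.

The generator deliberately omits real-data features: bead-level L1000
artifacts, dose–response and time-course structure, gene–gene correlation,
batch effects, and heavy-tailed outliers. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated model, not robustness to those phenomena; on real data the
weighted-correlation calibration, in particular, inherits whatever
dependence structure the genes carry.

Test and acceptance problem sizes — 978-gene signatures (the L1000
landmark count), libraries of a few hundred to a thousand signatures, and
tens to hundreds of seeded replications — were chosen as the smallest sizes
at which the planted effects and calibration bands are statistically
unambiguous.

## Known limitations

* No precomputation or caching layer: every query rescans the library
  (fine up to ~10⁴–10⁵ signatures; the production-scale all-vs-all use
  case needs infrastructure this package does not provide).
* No negative-binomial GLM path for RNA-seq counts; pre-transform to log
  scale.
* No identifier mapping, pathway databases, or external enrichment
  services; gene sets come from user GMT files.
* The Random Set normal approximation thins out for very small member sets
  ($m \lesssim 5$) in skewed score universes; exact enumeration is
  practical only for tiny universes.
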