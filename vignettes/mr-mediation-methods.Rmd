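---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Whether particular immune-cell phenotypes causally influence pancreatic
cancer risk — and whether plasma metabolites transmit part of that
influence — cannot be settled by observational association alone.
Mendelian randomization (MR) uses genetic variants as instrumental
variables: because alleles are assigned at meiosis, a SNP that robustly
raises an exposure provides a quasi-randomized contrast that is immune to
classical confounding and reverse causation, provided the instrument
assumptions hold (relevance; independence from confounders; effect on the
outcome only through the exposure). In the two-sample setting the
SNP–exposure and SNP–outcome associations come from different GWAS
cohorts, so only published summary statistics are needed.

`mrmediate` implements this workflow end to end: instrument selection,
allele harmonization, five summary-data estimators behind one fitting
function (`mr_fit()`), heterogeneity and pleiotropy diagnostics, a
bidirectional exposure-screening cascade, and two-step MR mediation with
the mediated-proportion decomposition. A summary-level simulator with
known causal truth (`simulate_triple()`) supports the calibration studies
reported by the test suite and the acceptance script.

## Instrument selection

For each exposure, candidate instruments are filtered in sequence
(`select_instruments()`):

1. **Significance**: exposure association p-value strictly below
   `p_exposure` (default 5e-8, the conventional genome-wide threshold).
2. **LD clumping** (`clump()`): greedy, PLINK-style — candidates are
   ordered by ascending p-value with ties broken lexicographically by SNP
   id (a total order, so the result is invariant to input row order); the
   best remaining SNP is kept and all others on the same chromosome within
   `clump_kb` (default 10,000 kb, closed interval) whose r² with it
   exceeds `clump_r2` (default 0.001) are removed. Missing r² entries are
   treated as 0. The greedy algorithm is the field convention; only the
   thresholds are usually reported, not the algorithm, so we state ours.
3. **Confounder exclusion** (`confounder_filter()`): SNPs associated at
   p < `confounder_p` (default 1e-5) with any trait on a configurable
   confounder list (defaults: BMI, smoking, drinking, diabetes,
   pancreatitis) in a local annotation table — a stand-in for an online
   phenome-scan query, which this package deliberately does not perform.
4. **Instrument strength** (`f_statistics()`): per-SNP
   F = (beta/se)², with the weak-instrument flag raised when the mean F
   falls below `f_min` = 10. The flag is attached rather than silently
   dropping data: whether a weak set invalidates the exposure or
   individual SNPs should be dropped is an analyst decision, so both the
   per-SNP F list and the mean are reported.

## Harmonization

`harmonize()` joins exposure and outcome tables on SNP id and aligns the
outcome to the exposure's effect allele, negating the outcome beta when
the allele pair is swapped. Palindromic SNPs (A/T, C/G) cannot be
strand-resolved from alleles alone, so the default policy drops them all —
the strictest reading of "eliminate palindromic SNPs". A
`drop_intermediate` mode (drop only when EAF is in [0.42, 0.58]) is
available for sensitivity runs and requires non-missing EAF; `keep` is
available for simulations known to be on one strand. Allele sets that
cannot be reconciled either way are dropped as incompatible. Every drop
is recorded with a reason so that retained + dropped always equals the id
intersection. Strand is assumed forward in both studies; no EAF
discordance check is applied (whether the original workflow used one is
not stated, so we do not guess — users with real data should check EAF
agreement separately).

## The five estimators

All operate on per-SNP Wald ratios $b_j = \hat\Gamma_j / \hat\gamma_j$
with first-order standard errors
$s_j = \mathrm{se}(\hat\Gamma_j)/|\hat\gamma_j|$ and weights
$w_j = s_j^{-2}$ (`wald_ratios()`); exposure-side uncertainty is ignored,
the standard NOME approximation, adequate for the strong instruments the
selection stage enforces.

* **IVW** (`mr_ivw()`): $\hat\beta = \sum w_j b_j / \sum w_j$ —
  equivalently weighted least squares of $\hat\Gamma$ on $\hat\gamma$
  through the origin with weights $\mathrm{se}(\hat\Gamma)^{-2}$. The
  default is a *multiplicative random-effects* model: the fixed-effect
  SE $(\sum w_j)^{-1/2}$ is inflated by $\max(1, \sqrt{Q/(J-1)})$, so
  heterogeneity can widen but never narrow the interval. A fixed-effect
  mode is available. The source workflow names IVW without stating its
  effects model; multiplicative random effects is common two-sample
  practice and is our default.
* **MR-Egger** (`mr_egger()`): weighted regression with an intercept,
  each SNP first oriented so $\hat\gamma_j \ge 0$. The slope estimates
  the causal effect under the InSIDE assumption; the intercept estimates
  average directional pleiotropy. SEs carry the overdispersion factor
  $\max(1, \sqrt{Q'/(J-2)})$; p-values use t with $J-2$ df.
* **Weighted median** (`mr_weighted_median()`): the 50% point of the
  inverse-variance-weighted empirical ratio distribution, by linear
  interpolation of standardized cumulative weights
  $s_k = (\sum_{i\le k} w_i - w_k/2)/\sum w$; consistent when valid
  instruments carry a majority of weight.
* **Weighted / simple mode** (`mr_mode()`): the argmax of a Gaussian
  kernel mixture over the ratios with bandwidth
  $h = \phi \cdot 0.9\,\min(\mathrm{sd}(b), \mathrm{IQR}(b)/1.349)\,
  J^{-1/5}$ (the Silverman rule scaled by the tuning parameter
  $\phi$, default 1), weights inverse-variance (weighted) or uniform
  (simple); consistent under plurality validity.

Median and mode SEs come from a parametric bootstrap — ratios resampled
as $b_j^* \sim N(b_j, s_j)$ with weights held fixed, 1000 draws by
default — seeded per method from one pipeline seed, so a fitted object is
bit-reproducible. p-values for IVW/median/modes use the normal reference;
95% CIs are $\hat\beta \pm 1.96\,\mathrm{se}$ throughout (the reporting
convention of the field; we use the literal 1.96). Estimates are reported
on both the log-odds and odds-ratio scales.

Methods whose minimum instrument count is unmet (3 for all but IVW, which
needs 1) are returned by `mr_fit()` as explicit not-computable entries
rather than errors, so screens over hundreds of exposures run unattended.

## Diagnostics

`mr_sensitivity()` reports Cochran's Q against the IVW estimate
($\mathrm{df}=J-1$), the Rücker-type Q′ from the Egger residuals
($\mathrm{df}=J-2$), the Egger intercept test (pleiotropy flagged at
p < 0.05), and a leave-one-out table in which each row is exactly the IVW
estimate on the corresponding $J-1$ subset, with summary flags for sign
changes and significance crossings. The IVW Q and the random-effects
inflation factor are mutually consistent by construction:
$Q = (J-1)\cdot\text{inflation}^2$ whenever inflation is active.

## The screening cascade

`screen_exposures()` applies, in order: IVW significance at `alpha`
(default 0.05, uncorrected — the screen is hypothesis-generating;
Bonferroni and FDR variants are provided and labelled as deviations);
exclusion when the Egger intercept p-value is below a separate
`pleiotropy_alpha` (default 0.05); direction consistency (all computable
methods' estimates strictly on one side of the null; an exact zero is
inconsistent; fewer than two computable methods is indeterminate and
passes with annotation); and reverse-MR exclusion. Reverse causation is
operationalized as a significant reverse-direction IVW (p < 0.05) with
instruments selected for the outcome trait under the same rules; when the
outcome has no selectable instruments — typical for a modestly powered
disease GWAS — the reverse test is reported not computable and the
exposure is retained. Keeping the stage-1 alpha separate from the
pleiotropy threshold makes retention monotone in alpha, which the test
suite asserts.

## Two-step mediation

With total effect $\beta_0$ (exposure→outcome), step-1 effect $\beta_1$
(exposure→mediator) and step-2 effect $\beta_2$ (mediator→outcome), all
IVW by default:

* mediated effect $\mathrm{ME} = \beta_1\beta_2$, with the
  product-of-coefficients (Sobel, no cross term) delta-method SE
  $\sqrt{\beta_1^2\mathrm{se}_2^2 + \beta_2^2\mathrm{se}_1^2}$ and CI
  $\mathrm{ME} \pm 1.96\,\mathrm{se}$;
* direct effect $\beta_3 = \beta_0 - \mathrm{ME}$ (exact identity,
  asserted to machine precision);
* mediated proportion $\mathrm{MP} = 100\,\mathrm{ME}/\beta_0$ percent,
  with CI obtained by dividing the ME CI endpoints by $\beta_0$ and
  reordering ascending. Uncertainty in $\beta_0$ is *not* propagated into
  the MP interval — this matches the arithmetic of published mediation
  tables, where the printed proportion bounds equal the printed effect
  bounds divided by the total effect. When $\beta_0 < 0$ the division
  flips the interval, hence the reordering; signs are reported exactly as
  computed, with no absolute-value convention.

One published row we bundle as a worked example
(`published_mediation_examples()`) is internally inconsistent under this
arithmetic: the cortisone row prints a mediated proportion of −26.6%
although its mediated effect (−0.0223) and total-effect OR (0.920, i.e. a
negative log-odds total effect) imply +26.7%, and its printed CI
"(138%, −84.8%)" is not an ordered interval. The package reports the
self-consistent value; that row is excluded from the consistency checks.

**Step-2 instrument exclusivity.** `two_step_effects()` by default
removes from the step-2 (mediator) instrument set any SNP that reaches
the exposure's significance threshold in the exposure GWAS. A mediator
instrument shared with the exposure violates step 2's exclusion
restriction — it reaches the outcome through the exposure's direct path
as well — and, uncorrected, pulls the step-2 IVW toward
$\beta_0/\beta_1$ instead of $\beta_2$. With the exclusion, step 2 rests
on mediator-specific variants only. This is configurable
(`exclude_exposure_snps = FALSE` restores the naive behaviour).

## The synthetic-GWAS generator

`simulate_triple()` generates the three summary-statistic tables directly
at the summary level: estimated betas are the true per-SNP effects plus
Gaussian noise whose SD equals the reported standard error
$1/\sqrt{2\,n\,\mathrm{maf}(1-\mathrm{maf})}$ (per-allele effects on a
standardized trait), so instrument strength is controlled through the
GWAS sample size. No individual-level genotypes are simulated — every
estimator here consumes only summary data, and the summary-level route is
orders of magnitude faster.

The causal graph: exposure instruments carry
$\gamma_j \sim N(0, \texttt{gamma\_scale}^2)$; a disjoint
`mediator_snp_frac` of the panel are mediator-specific instruments with
$\delta_j \sim N(0, \texttt{delta\_scale}^2)$ and zero exposure effect.
True effects are $\gamma_j$ on the exposure,
$\beta_1\gamma_j + \delta_j$ on the mediator, and
$\beta_{\mathrm{direct}}\gamma_j + \beta_2(\beta_1\gamma_j + \delta_j)
+ \alpha_j$ on the outcome, with
$\beta_{\mathrm{direct}} = \beta_0 - \beta_1\beta_2$ exactly. Without
mediator-specific variants the mediator would inherit *only*
exposure-driven genetics and no instrument set could identify $\beta_2$
— the step-2 ratio would converge to $\beta_0/\beta_1$ even with
infinite data — so their presence is what makes two-step mediation
well-posed in simulation, mirroring reality: metabolites have strong
trait-specific (often cis-enzyme) loci.

Direct (pleiotropic) effects $\alpha_j$ are none / balanced (mean-zero
normal) / directional (nonzero mean), applied on the
*exposure-increasing allele* orientation: that is the orientation in
which the Egger intercept measures average directional pleiotropy, so a
directional mean is detectable rather than cancelling across arbitrarily
coded alleles. Symmetric modes are unaffected by the orientation.

Defaults and why:

* `n_snps = 100`, `gamma_scale = 0.3` — of order the strong per-allele
  effects seen for the immune phenotypes that yield usable instruments;
  gives ~60–90 genome-wide-significant instruments at n = 1e5.
* `mediator_snp_frac = 0.3`, `delta_scale = 0.7` — metabolite-style
  architecture: fewer, larger trait-specific loci.
* `n_exposure = n_mediator = 1e5`, `n_outcome = 6000` — the outcome
  default is the *effective* sample size of a case-control GWAS with a
  few thousand cases (4/(1/cases + 1/controls)), the regime of a rare
  cancer. This matters qualitatively: at much larger outcome n the
  forward causal effect itself becomes genome-wide significant in the
  outcome GWAS, and a reverse-direction analysis would (correctly, but
  unhelpfully) re-detect the forward signal — as with real disease
  outcomes, reverse MR is only meaningful when the outcome's own
  instruments are not mere shadows of the exposure's.
* `maf_range = (0.05, 0.5)` — common variants, as instrument panels are
  in practice; `palindromic_frac = 0.1` so the harmonization drop policy
  is exercised by default, with palindromic SNPs given EAF near 0.5.
* LD blocks: same-block SNPs share `within_block_r2` and sit < 10,000 kb
  apart; blocks are 20,000 kb apart, so clumping with default settings
  keeps exactly one SNP per correlated block. `ld_matrix()` reproduces
  the layout deterministically.

What the generator does *not* emulate: realistic LD decay from a
reference panel (blocks are uniform), case-control liability-scale
subtleties (betas are treated as log-ORs directly), sample overlap
between cohorts, allele-frequency differences between studies, and
population stratification. Passing calibration on these synthetic
conditions therefore demonstrates the estimators and the pipeline logic,
not robustness to those real-data complications.

## Numerical choices

* Mode density: 512 grid points spanning [min(b) − 3h, max(b) + 3h]; the
  grid step is the resolution of the mode location (tests compare against
  a 1e5-point brute-force grid). All-equal ratios give h = 0 and the
  common value is returned directly.
* Clumping tie-break: p-value then SNP id, making output order-invariant.
* Zero exposure effects: dropped from ratio-based estimation with a
  warning; an all-zero set is an error.
* Bootstrap and simulation determinism: one seed per object; per-stage
  sub-seeds are derived arithmetically so adding a stage never perturbs
  another stage's stream. Identical config + seed gives byte-identical
  pipeline outputs.
* p-values from the simulator are floored at the smallest positive
  double to stay within (0, 1].

## Problem sizes in the checks

The calibration studies run by the acceptance script and the test suite
use: 1000 replicates (J = 50, n = 1e5) for Egger-intercept type-I error
and IVW coverage; 100 replicates at n = 1e5 per GWAS for
mediated-proportion recovery (truth −20%); 200 null replicates for the
stage-1 exclusion rate and 100 for reverse-MR power. These sizes put the
Monte-Carlo error comfortably inside the tolerance of each check while
keeping the whole run in tens of seconds.

## Limitations

Beyond the simulator's simplifications listed above: no MR-PRESSO or
other outlier-robust extensions, no multivariable MR (so mediation with
correlated or multiple simultaneous mediators is out of scope), no
Steiger directionality filtering, no proxy-SNP lookup or liftover, and
the confounder screen is only as good as the annotation table supplied
to it.
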