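---
title: "Two-sample Mendelian randomization for vitamin D and multiple sclerosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization for vitamin D and multiple sclerosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The model

Write $x$ for centered natural-log 25-hydroxyvitamin D (25OHD) and $y$
for the log-odds of multiple sclerosis (MS), linked by the structural
equation $y = \alpha x + \eta$, where the error $\eta$ is in general
correlated with $x$ through confounding. A SNP that perturbs $x$ but is
independent of $\eta$ identifies $\alpha$: with $\gamma_i$ the
per-allele effect of SNP $i$ on log 25OHD and $\beta_i$ (SE
$s(\beta_i)$) its per-allele log-odds of MS, the Wald ratio
$\alpha_i = \beta_i/\gamma_i$ estimates $\alpha$, with first-order
variance $v_i = (s(\beta_i)/\gamma_i)^2$. Instruments are pooled by
inverse-variance weighting ($w_i = 1/v_i$):
$$\hat\alpha = \frac{\sum w_i \alpha_i}{\sum w_i},\qquad
  s(\hat\alpha) = \Big(\sum w_i\Big)^{-1/2},$$
which coincides exactly with the zero-intercept weighted regression of
$\beta_i$ on $\gamma_i$ with weights $1/s(\beta_i)^2$ (the package
asserts this identity in its tests). Heterogeneity is measured by
Cochran's $Q = \sum w_i(\alpha_i - \hat\alpha)^2$ on $n-1$ df,
$I^2 = 100\max(0, (Q - \mathrm{df})/Q)$, and the DerSimonian–Laird
moment estimate $\tau^2 = \max(0, (Q-\mathrm{df})/C)$ with
$C = \sum w_i - \sum w_i^2/\sum w_i$; random-effects pooling reuses the
same equations with weights $1/(v_i + \tau^2)$, so it reduces exactly
to the fixed-effects fit when $\tau^2 = 0$.

The two-sample design estimates $\gamma_i$ in a population cohort with
measured 25OHD and $\beta_i$ in independent case-control consortia, so
no individual contributes to both sides.

## Conventions and tunable parameters

**Orientation.** All effects are expressed per copy of the
25OHD-*decreasing* allele, and the pooled estimand is the log-odds of
MS per unit *decrease* of log 25OHD. This keeps all four instrument
outcome effects positive and matches the clinical framing ("what does
genetically lower vitamin D do to risk"). `harmonize()` flips the signs
of $\gamma$ and $\beta$ in lockstep when a record arrives stated for
the increasing allele, and records the flip.

**Outcome standard errors.** Consortium results arrive as an odds
ratio with a 95% CI. The canonical derivation is CI-based,
$s(\beta) = (\ln \mathrm{hi} - \ln \mathrm{lo})/(2z)$ with
$z = \Phi^{-1}(0.975) = 1.959964$; a p-value-based derivation
($s(\beta) = |\beta|/\Phi^{-1}(1-p/2)$, computed with
`lower.tail = FALSE` to avoid cancellation at tiny $p$) is an explicit
opt-in (`se_method = "p"`). The two agree within about 12% on the
packaged table (the difference is printed-value rounding); the choice
matters in the third significant digit of $I^2$.

**The SD of log 25OHD ($\sigma$).** The per-SD odds ratio
$\exp(\hat\alpha\sigma)$ needs the population SD of log 25OHD, which
the source tables never state and are mutually inconsistent about: the
published per-SD odds ratios are jointly consistent with
$\sigma \approx 0.517$, while the published clinical-threshold
equivalences imply $\sigma = \ln(36.86/25) \approx 0.38829$. The
package therefore exposes $\sigma$ as configuration and ships both
calibrations — `sigma_logx = 0.51738` (calibrated once so the four-SNP
fixed-effects OR reproduces the published headline) for odds ratios,
and `sigma_thresh = 0.38829` for threshold equivalence
(`sd_equivalent_level(level, sigma)` returns
$\exp(\ln(\mathrm{level}) + \sigma)$) — rather than resolving the
conflict. The z-statistic, p-value, $Q$ and $I^2$ are invariant under
the choice; only the OR scale moves.

**Other defaults.** The Bonferroni screen uses a family-wise error
rate of 0.05 over the number of instruments (0.05/4 = 0.0125 here),
with a $\le$ comparison. Clinical thresholds default to 25, 50 and
75 nmol/l (deficiency / insufficiency / sufficiency). Proxy SNPs are
metadata only (`proxy_rsid`, `proxy_r2`): the packaged proxies are in
perfect LD ($r^2 = 1.0$) with their targets, so no LD adjustment is
performed.

## Numerical choices

The $I^2$ confidence interval is the test-based interval on
$\ln H$, $H = \sqrt{Q/\mathrm{df}}$, with
$se(\ln H) = (\ln Q - \ln \mathrm{df}) / (2(\sqrt{2Q} -
\sqrt{2\,\mathrm{df}-1}))$ for $Q > \mathrm{df}$ and the large-sample
fallback $\sqrt{\tfrac{1}{2(\mathrm{df}-1)}(1 -
\tfrac{1}{3(\mathrm{df}-1)^2})}$ otherwise, back-transformed through
$I^2 = 100(H^2-1)/H^2$ and truncated to $[0, 100)$. With exactly two
instruments the interval cannot be properly estimated; it is still
computed where the formulas apply and always flagged
(`ci_unstable = TRUE`), and the homogeneous two-instrument corner
($\mathrm{df} = 1$, $Q \le \mathrm{df}$), where no usable
$se(\ln H)$ exists, reports an `NA` upper bound rather than a made-up
number. $I^2$ and $\tau^2$ are truncated at zero; p-values are
two-sided normal tail probabilities with no small-p clamping.

Instrument-strength statistics follow the two-stage convention: log
25OHD is first residualized on sex, age, age², BMI and season by OLS,
then regressed on the allele score (or a single dosage), reporting
$F = t^2$ with $n-2$ denominator df. A one-stage alternative
(`score_strength_joint()`) fits the covariates and score jointly and
uses the covariate-adjusted df; the two differ slightly, and the
published strength statistics do not satisfy
$F = (n-2)r^2/(1-r^2)$ exactly, so both conventions are available.
The non-parametric trend across allele-count groups is Cuzick's
rank-based test with group scores equal to the counts and a
tie-corrected variance; with two groups it reduces to the normal
approximation of the Wilcoxon rank-sum test (asserted in tests). The
ancestry screen is the Cochran–Armitage trend test
(`stats::prop.trend.test`), with a 2×3 genotype chi-square as an
option. Pairwise LD is the squared sample correlation of dosages
(composite LD), invariant to allele relabeling $d \mapsto 2-d$.

## What the simulator emulates

`sim_params()` defines a generative model matched to the study
conditions: an exposure cohort of $n = 2{,}347$ with four biallelic
SNPs at the instrument frequencies and effects, and a case-control
outcome study sampled to 14,498 cases and 24,091 controls. Genotypes
are two independent allele draws (Hardy–Weinberg); the biomarker is
$$\log \mathrm{25OHD} = \mu + \textstyle\sum_j(-\gamma_j)(g_j - 2f_j)
  + \text{covariates} + \lambda_x U + \varepsilon,$$
with $U$ a latent standard-normal confounder, and the residual SD
solved so the marginal variance equals $\sigma^2$ *exactly* (the
covariate contribution uses closed-form/quadrature moments of the
configured distributions; an infeasible budget is an error that prints
the decomposition). Disease follows
$\mathrm{logit}\,P(y=1) = \kappa - \alpha_{\mathrm{true}} z_x +
\sum_j \delta_j g_j + \lambda_y U$ with $z_x$ the standardized
log-biomarker, so $\alpha_{\mathrm{true}}$ is directly the log-odds
per 1-SD decrease — the MR estimand. $\delta_j$ injects directional
pleiotropy; an optional second subpopulation with shifted allele
frequencies and baseline risk implements population stratification.

Default choices, made once: $\sigma = 0.38829$ and $\mu = \ln 60$;
covariate effects default to zero so $\sigma$ describes both the
marginal and the covariate-adjusted scale — the setting under which
the analytic per-SNP strength $n\,2f(1-f)\gamma^2/\sigma^2$ matches
the strengths the instruments are known to have (covariate
distributions — age, BMI, sex, season — are configurable and used by
the residualization tests); $\alpha_{\mathrm{true}} = 0.70$ per SD
(approximately the headline estimate, $\ln 2.02$);
$\kappa = \mathrm{logit}(0.35)$, a baseline chosen so outcome batches
of $1.25\,(n_{\mathrm{cases}}+n_{\mathrm{controls}})$ reach the
requested counts in one draw — sampling on the outcome changes only
the logistic intercept, not the slopes. In the pleiotropy test
scenario $\delta$ is placed on the *GC* analog, the locus whose
product (the vitamin D binding protein) is the analysis's named
candidate for an effect on MS independent of 25OHD. A master seed
spawns disjoint streams for the exposure and outcome cohorts, so the
two-sample separation holds by construction and identical
(parameters, seed) reproduce cohorts bitwise.

What the simulator does *not* emulate: LD structure and haplotypes
(instruments are drawn independently), assay measurement error as a
separate component (it is absorbed into $\varepsilon$), genome-scale
panels, age-of-onset, and the selection filters of real consortia.
Passing recovery tests therefore show the estimator stack is correct
under its own assumptions, not that those assumptions hold in any real
cohort.

## Test design and problem sizes

Deterministic checks recompute the published analysis from the
packaged instrument table (heterogeneity, sensitivity odds ratios,
threshold equivalences, the Bonferroni screen) and assert the
IVW/weighted-regression identity to $10^{-10}$ on 1,000 random
instrument sets. Stochastic checks state their replicate counts:
instrument-strength medians over 1,000 simulated cohorts at matched
$n$, frequencies, effects and $\sigma$; LD independence over 200
cohorts of $n = 10{,}000$; ancestry detectability over 500 stratified
cohorts; and 500 two-sample simulations at full study scale for each
of effect recovery, null calibration and leave-one-out pleiotropy
localisation. Type-I-error checks for the strength, trend and ancestry
tests use 5,000 null replicates each.

## Known limitations

* **Exposure-side uncertainty is ignored by design.** The Wald-ratio
  variance is the first-order formula $v_i = (s(\beta_i)/\gamma_i)^2$;
  the sampling error of $\gamma_i$ never enters the weights or the
  pooled SE (the exposure SE can be carried as metadata only). With
  instruments estimated in a cohort of 2,347 — per-SNP F statistics
  between about 3 and 20 — the neglected term
  $\alpha^2 s(\gamma_i)^2/\gamma_i^2$ is of the same order as $v_i$.
  Two consequences follow: fixed-effects confidence intervals are
  anti-conservative under the simulator's study-scale conditions (the
  recovery tests measure exactly how much), and noise in
  $\hat\gamma_i$ masquerades as between-instrument heterogeneity,
  inflating $Q$ and $I^2$ even when the per-SNP causal effects are
  identical.
* **Non-collapsibility.** Per-allele logistic odds ratios are
  attenuated relative to the conditional model that generates them, so
  simulated effect recovery is biased slightly toward the null; the
  recovery tolerance covers this.
* Only four fixed, pre-harmonized instruments are supported in the
  packaged analysis: there is no strand/palindrome resolution and no
  LD-proxy lookup against reference panels.
* Pleiotropy-robust estimators that postdate this design (MR-Egger,
  weighted median/mode, multivariable MR) are out of scope; the
  sensitivity instruments are named exclusions, pathway strata and
  leave-one-out.
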