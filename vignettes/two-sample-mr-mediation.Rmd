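---
title: "Two-sample MR with mediation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with mediation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Observational associations between a modifiable exposure (here, the running
example is relative carbohydrate intake, i.e. the share of energy from
carbohydrates) and a disease outcome (hypertension) are vulnerable to
confounding and reverse causation. Two-sample Mendelian randomization (MR)
instruments the exposure with genetic variants: because alleles are fixed at
conception and assigned quasi-randomly, a variant that robustly shifts the
exposure provides a randomized push whose downstream effect on the outcome
identifies a causal effect — provided the variant (1) is strongly associated
with the exposure, (2) is independent of confounders, and (3) affects the
outcome only through the exposure (exclusion restriction). `mrsuite`
implements the full analysis cycle on GWAS summary statistics: instrument
selection and allele harmonization, univariable and multivariable
estimation with a sensitivity suite, sensitivity-gated causal verdicts,
two-step MR mediation, and fixed-effect pooling across outcome cohorts.

## Estimators

For variant $j$, let $\hat\beta_{Xj}, \hat\sigma_{Xj}$ be its association
with the exposure and $\hat\beta_{Yj}, \hat\sigma_{Yj}$ with the outcome
(log odds for binary traits).

* **Wald ratio**: $\hat\beta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, SE by the
  first-order delta method $\hat\sigma_{Yj}/|\hat\beta_{Xj}|$; a
  second-order flag adds the exposure-side term
  $\hat\beta_{Yj}^2\hat\sigma_{Xj}^2/\hat\beta_{Xj}^4$. The delta
  approximation presumes a strong instrument; with $F \lesssim 10$ the
  ratio distribution is heavy-tailed and its moments are not usable.
* **IVW**: slope of the zero-intercept regression of $\hat\beta_Y$ on
  $\hat\beta_X$ with weights $1/\hat\sigma_Y^2$. The default
  random-effects variant inflates the SE multiplicatively by
  $\max(1, \sqrt{Q/(L-1)})$ — the standard overdispersion model; the named
  "random-effects IVW" in most software is this variant, and it is the
  package's main analysis.
* **MR-Egger**: the same regression with a free intercept after orienting
  all rows to non-negative exposure effects; the intercept estimates
  average directional pleiotropy and its test is the gate's pleiotropy
  criterion. Residual scale floored at 1 as for IVW.
* **Weighted median**: weight-interpolated 50th percentile of the Wald
  ratios (cumulative-weight midpoints), consistent when valid instruments
  hold half the weight; SE by seeded parametric bootstrap.
* **Weighted mode**: maximizer of a weighted normal-kernel density over
  the ratios; bandwidth is a modified Silverman rule
  $0.9\,\varphi\,\min(\mathrm{sd},\mathrm{mad})\,L^{-1/5}$ with
  $\varphi = 1$ by default, maximized on a 512-point grid over the ratio
  mean $\pm 3$ sd. Consistent when the largest cluster of instruments is
  valid.
* **MR-PRESSO**: leave-one-out residual sum of squares compared against a
  parametric simulation of the null (default 1000 draws); per-variant
  outlier tests Bonferroni-corrected at 0.05; outlier-corrected IVW and a
  distortion test (random same-size exclusions) follow when outliers are
  found.
* **MVMR**: MV-IVW is the zero-intercept weighted multiple regression of
  outcome on all exposure columns (direct effects conditional on
  co-exposures), SE inflation by $\max(1,\sqrt{Q/(L-K)})$; MVMR-Egger
  adds the oriented intercept; MVMR-median minimizes weighted absolute
  residuals; MVMR-Lasso gives every variant an L1-penalized intercept and
  drops those that absorb one.
* **Diagnostics**: per-variant $F = (\hat\beta_X/\hat\sigma_X)^2$ with the
  conventional mean-$F < 10$ weak-instrument flag; Cochran's $Q$ with
  $I^2 = \max(0,(Q-\mathrm{df})/Q)$; Steiger directionality comparing
  instrument $r^2$ in exposure versus outcome via Fisher-transformed
  correlations.

### Numerical choices

* MVMR-median is solved by cyclic coordinate descent in which each
  coordinate update is an exact weighted median, warm-started at the WLS
  solution. Exact coordinate updates never increase the weighted-L1
  objective, so the iteration is declared converged when either the
  iterates move less than 1e-8 or the objective stalls (ties between
  neighboring vertices); up to 1000 sweeps are allowed and exhausting them
  raises a classed convergence error carrying the last iterate. An
  IRLS/smoothed-LAD solver was rejected: its linear convergence near LAD
  vertices is too slow for bootstrap use.
* MVMR-Lasso tunes its penalty by a heterogeneity stopping rule:
  descending a 50-point log-spaced grid from the smallest all-zero
  penalty, the first (largest) value whose retained variants have
  $Q$ below the $\chi^2_{0.95}$ quantile wins. If no grid value
  qualifies, the most-penalized workable fit is returned with a warning;
  if the full set is already homogeneous the infinite-penalty limit
  (= MV-IVW) is returned.
* Conditional instrument strength is reported as
  $F_k = Q_k/(L-K+1)$, where $Q_k$ is the weighted RSS from regressing
  exposure $k$'s instrument effects on the co-exposures' effects. This
  convention makes two orthogonal strong exposures each report
  approximately their univariable mean $F$; the formula is recorded in
  the result so comparisons across software are explicit.
* Ties in instrument selection are broken lexicographically by variant ID,
  making greedy LD pruning independent of row order. Palindromic (A/T,
  C/G) variants default to being dropped; `infer_by_eaf` aligns them by
  which side of 0.5 their frequencies fall on and refuses frequencies
  inside 0.42–0.58 (a common community default), since strand cannot be
  resolved near 0.5.
* All p-values are two-sided normal except $Q$ (chi-square) and the
  MR-PRESSO tests (empirical, with the $+1$ correction so no simulated p
  is exactly zero).

## Two-step mediation

For a mediator $M$ on the path from exposure $X$ to outcome $Y$:
$\beta_1$ is the univariable IVW effect of $X$ on $M$; $\beta_2$ is $M$'s
coefficient in the MV-IVW of $(X, M)$ on $Y$ (the mediator's direct effect
holding the exposure fixed), estimated on the union of both traits'
instruments; the total effect is the univariable IVW of $X$ on $Y$. The
indirect effect is $\beta_1\beta_2$ and the mediation proportion is
$P = \beta_1\beta_2/\beta_{\mathrm{total}}$, with binary-outcome effects
entering on the log-odds scale.

A mediator is admissible only if (a) $X$ affects $M$, (b) reverse MR shows
no $M \to X$ effect, and (c) $M$ is associated with $Y$ in univariable MR.
When instrumenting the mediator, the exposure's own instruments are
excluded: a genuine $X \to M$ effect propagates the exposure's variants
into genome-wide significance in the mediator GWAS, and any that slip
through contaminate the reverse-MR screen with ratios of $1/\beta_{XM}$
(simulation shows the screen's null p-values become sharply non-uniform
without this exclusion). This mirrors standard bidirectional-MR practice.

Delta-method CIs for $P$ come in two variants. `delta_fixed_total`
(default) uses
$\mathrm{var}(P) = (\beta_2^2\sigma_1^2 + \beta_1^2\sigma_2^2)/\beta_{\mathrm{total}}^2$,
conditioning on the estimated total effect — this reproduces the CI style
of published mediation tables computed from reported estimates.
`delta_full` adds
$\beta_1^2\beta_2^2\sigma_{\mathrm{total}}^2/\beta_{\mathrm{total}}^4$,
treating the three estimates as independent (valid in a two-sample design
with non-overlapping cohorts). For comparing an estimated proportion
against a known truth the full variant is the calibrated one: ignoring
total-effect uncertainty is structurally anticonservative. Both are exact
delta approximations only when every component is precisely estimated;
with component z-ratios below about 10 the ratio distribution is visibly
skewed and the delta interval departs from the Monte-Carlo percentiles.
Proportions outside $[0,1]$ are reported unclamped with an
inconsistent-mediation flag.

## Causal gating and pooling

An IVW estimate is called causal only when it is significant at 0.05, at
least one sensitivity estimator (weighted median, weighted mode, MR-Egger,
MR-PRESSO) is significant with the same sign, and the Egger intercept
shows no pleiotropy (p > 0.05). Co-exposures enter the MVMR adjustment set
only if they carry their own forward causal call — the rule, not any
specific trait list, is implemented.

Estimates for the same pair from several outcome cohorts are pooled by
fixed-effect inverse-variance meta-analysis with $Q$/$I^2$ heterogeneity
assessment; under the `auto` rule a DerSimonian–Laird random-effects pool
replaces it when the heterogeneity test rejects, and the switch is logged.
In the mediation panel the outcome-facing pieces (total effect, $\beta_2$,
the mediator–outcome link) are pooled across cohorts before the proportion
is formed; $\beta_1$ and the reverse screen do not involve the outcome and
are cohort-invariant.

## The synthetic study generator

`simulate_two_sample()` draws individual-level data and then computes
summary statistics by per-variant regression, so SEs, F statistics and
Steiger $r^2$ are mutually consistent — a property direct summary-level
sampling does not give. Genotypes are binomial(2, maf) in linkage
equilibrium; the exposure is built from its instrument block plus noise;
the mediator from the exposure plus its own instrument block; the outcome
from the direct and mediated paths plus, for a configurable fraction of
invalid instruments, direct (pleiotropic) genotype effects, balanced or
directional. Each trait's statistics come from an independently drawn
cohort, honoring the two-sample no-overlap design. Binary outcomes use a
logistic link whose intercept is solved for the target prevalence by
bisection to 1e-6, and per-variant statistics use a one-step score
approximation to logistic regression (exact enough for GWAS-scale
per-allele effects, and vectorizable).

Defaults are the well-powered conditions of the motivating study design:
L = 50 instruments, cohorts of 20,000, mean instrument F targeted at 60
with per-variant strength drawn uniformly in 0.75–1.25 of target — so
every instrument sits clearly above the genome-wide threshold, matching a
study whose instruments all report $F \ge 50$ and keeping winner's-curse
bias minor. Allele labels are randomized over non-palindromic pairs and a
third of non-reference rows are reported on the swapped allele, so
harmonization is genuinely exercised in every simulated analysis.
Problem sizes used in the shipped checks: 300–500 replicates at the
default scale for size/coverage calibration, 200 for the pleiotropy
robustness comparison, 100 two-step runs for mediation recovery, and
tiny-scale fixtures (L = 10, n = 2,000) for pipeline behavior.

What the generator does **not** emulate: linkage disequilibrium between
instruments (LD fixtures for the pruning code are built separately from a
synthetic $r^2$ matrix), winner's curse from discovery/replication
asymmetry, sample overlap bias, population stratification, or
non-collapsibility subtleties of odds ratios beyond the logistic link
itself (the planted mediation chain uses a continuous outcome so the
product-of-coefficients identity is exact). Passing the shipped checks
therefore demonstrates internal statistical correctness under these
idealized conditions, not robustness to everything real GWAS data can do.

## Known limitations

* With instrument strength near the selection threshold, IVW-based
  estimates inherit the familiar few-percent regression-dilution and
  winner's-curse attenuation; at the default mean F = 60 this is ~2–3%
  of the effect and visibly shifts mediation-proportion point estimates
  (e.g. 0.39 recovered for a planted 0.40).
* The mediator screen tests marginal criteria at a fixed 0.05; it does
  not control the compound error of screening plus estimation.
* Nonlinear causal effects and exposure–mediator interactions are outside
  the two-step, two-sample design.
* Proportions from several mediators are reported individually; they are
  not an additive decomposition unless the mediators are independent.
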