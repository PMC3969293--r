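---
title: "Estimating the heritability of number sense: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the heritability of number sense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numbersense)
```

This vignette is the package's own account of the science it implements:
the psychophysical model behind the Weber fraction, the twin
variance-component machinery, the SNP-based (GREML) estimator, what the
synthetic-data generators do and do not emulate, and the numerical
choices that a maintainer would want written down.

## 1. The psychophysical model

The approximate number system is modelled the standard way: a set of $n$
items is represented as a Gaussian magnitude $N(n, (wn)^2)$, where $w$ is
the subject's Weber fraction. Comparing two sets of sizes $n_1$ and $n_2$
means comparing two correlated magnitudes, giving

$$P(\text{correct}) \;=\; \Phi\!\left(\frac{|n_1-n_2|}{w\sqrt{n_1^2+n_2^2}}\right)
 \;=\; 1-\tfrac12\,\mathrm{erfc}\!\left(\frac{|n_1-n_2|}{\sqrt2\,w\sqrt{n_1^2+n_2^2}}\right),$$

implemented in `predict_percent_correct()`. The curve is anchored at 0.5
for equal sets and approaches 1 as $w \to 0$. This linking function is
the module's central assumption: the task publications this package
mirrors cite it rather than print it, so it is stated here explicitly.

`estimate_weber()` fits $w$ by least squares on *binned* proportions
correct — trials are grouped by their (smaller, larger) count pair and
residuals are weighted by bin size — rather than on per-trial 0/1
residuals. The two objectives have the same optimum in expectation; the
binned form is numerically stabler. Equal-count (tie) trials carry no
information about $w$ and are excluded. The fit is constrained to
$w \in [0.01, 2]$; boundary solutions are flagged (`at_lower_bound`,
`at_upper_bound`, `below_chance`) rather than silently returned. The
optimiser is a coarse grid scan (step $10^{-3}$) followed by
golden-section refinement of the bracketing interval, which the test
suite holds to within grid resolution of an exhaustive grid search.

Reaction-time outliers are trimmed by the non-recursive moving-criterion
method: a trial is removed when its RT lies more than $k(n)$ sample SDs
from the session mean, where $k(n)$ is a published, sample-size-dependent
criterion (interpolated from a lookup table, rising from 1.46 at $n=4$
to an asymptote of 2.5 at $n \ge 100$). Small sessions thus use a
stricter criterion, avoiding the bias of a fixed cutoff. Sessions with
fewer than four trials or zero RT variance are left untrimmed (with a
warning in the former case).

## 2. Twin variance components

Phenotypes are prepared as in the standard behaviour-genetic workflow
(`prepare_phenotype()`): a normalising transform (accuracy is squared;
Weber fractions are square-rooted), z-standardisation, OLS
residualisation on age (linear) and sex (binary), and a single-pass
±3 SD screen. Order matters and is deliberate: the screen is applied
once, *after* standardisation and residualisation, and the retained
scores are not re-standardised — so the post-screen SD dips slightly
below 1. Twins share age exactly and often sex, so uncorrected age/sex
effects would masquerade as shared environment. The boundary value
±3.000 is kept (closed interval). Standardisation uses the full sample,
not zygosity subgroups.

`fit_twin_model()` maximises the full-information likelihood over
individuals: a complete pair contributes a bivariate normal with common
mean $\mu$ and covariance

$$\Sigma_{MZ} = \begin{pmatrix} V & a^2+c^2 \\ a^2+c^2 & V \end{pmatrix},
\qquad
\Sigma_{DZ} = \begin{pmatrix} V & \tfrac12 a^2+c^2 \\ \tfrac12 a^2+c^2 & V \end{pmatrix},$$

with $V = a^2+c^2+e^2$, and a singleton contributes $N(\mu, V)$. Path
coefficients are constrained non-negative and the reported components
are squared paths divided by $V$, so they sum to one exactly. The
saturated model estimates five moments per zygosity group (10
parameters); the E model fixes the mean at zero (it is meant for
residualised input) so its single parameter is the variance.

Numerical choices: multi-start bounded quasi-Newton (L-BFGS-B) on the
path scale with a *deterministic* jitter pattern for restarts — restarts
must not consume the caller's RNG stream, or seeded pipelines would lose
byte-reproducibility. Infeasible covariance structures return a large
finite penalty ($10^{10}$) because L-BFGS-B cannot digest `Inf`.
Convergence is to $10^{-8}$ on the objective; ties in model selection
break by BIC.

Fit statistics: `-2LL`; the classical `AIC = -2LL + 2p`; the legacy
structural-equation convention `AIC_mx = -2LL - 2(nobs - p)`, which is
the convention the motivating literature tabulates; and
`BIC = -2LL + p log(nobs)`. Published BIC magnitudes in this literature
are not reproducible from any single convention, so BIC is used for
relative ranking only.

Profile confidence intervals (`profile_ci()`) solve, on each side of the
estimate, for the component value at which the profiled `-2LL` rises by
the $\chi^2_1$ critical value (3.84 at 95%). Fixing a standardised
component at $t$ while keeping the simplex constraint exact uses a
spherical split of the remaining mass: the other two proportions are
$(1-t)\sin^2\phi$ and $(1-t)\cos^2\phi$ with $\phi$ free. Components at
a [0,1] boundary yield one-sided intervals, flagged.

Intraclass correlations are double-entry Pearson correlations (the
one-way random-effects ICC for interchangeable twins), with Fisher-z
intervals using the number of *pairs* as the effective sample size.

A caution the test suite encodes: when a true component sits on the
boundary (e.g. $c^2 = 0$), the likelihood-ratio statistic for dropping
it is a 50:50 mixture of a point mass at zero and $\chi^2_1$, so naive
p-values are conservative — about 75% of null p-values exceed 0.5, not
50%. Plain $\chi^2$ p-values are reported (as the literature does); the
mixture behaviour is asserted in the tests so it stays documented.

## 3. Sex-limitation models

Five groups (MZm, MZf, DZm, DZf, DZos; twin 1 is the male in DZos) share
one likelihood. Same-sex groups use that sex's paths; the opposite-sex
pair covariance is $r_g a_m a_f + c_m c_f$ with the shared-environment
correlation fixed at 1 ($r_g$ and $r_c$ are not jointly identified; the
genetic variant is implemented, matching the models the motivating
analyses report). The four models are Full ($r_g$ free; 8 parameters),
Common Effects ($r_g = 0.5$; 7), Scalar (female paths a single positive
multiple of male paths; 5) and Null (everything equated; 4).

A single grand mean is estimated in all four models. The alternative
(per-sex means except in the Null model) yields parameter counts
10/9/6/5 whose *differences* do not match the degrees-of-freedom pattern
the motivating tables print (Δdf = 1, 3, 4 from the full model); the
single-mean convention (8/7/5/4) does, and on residualised phenotypes
the distinction is immaterial in practice.

## 4. GREML

`compute_grm()` uses sample allele frequencies (the source analyses do
not state theirs), excludes monomorphic/constant markers, and by default
handles missing dosages by per-pair SNP intersection ($M_{jk}$), with a
mean-imputation compatibility mode. Two in-sample consequences the tests
pin down: the diagonal averages 1 under Hardy–Weinberg sampling, and
because frequencies are estimated from the same sample, row sums of the
GRM are shrunk towards zero, putting the off-diagonal *mean* near
$-1/(N-1)$ with SD $\approx 1/\sqrt{M}$.

`reml_h2()` fits $y = X\beta + g + \varepsilon$, $\mathrm{cov}(g) =
\sigma_g^2 A$, by restricted maximum likelihood: one EM step from equal
starting values, then average-information updates, convergence at
$10^{-8}$ on the restricted log-likelihood, components floored at
$10^{-6} V_p$ (constrained mode, the default) or free in unconstrained
mode. Standard errors come from the inverse AI matrix via the delta
method. An EM-only mode exists purely for cross-checking; the tests
verify both algorithms reach the same optimum, and that the AI estimate
matches a profiled-likelihood grid search over $h^2$.

**Relatedness pruning and desk scale.** The conventional threshold
removes one member of every pair with $|A_{jk}| > 0.025$
(`prune_related()`, a greedy cover: most-offending individual first,
ties by id order). That constant is calibrated to GRMs built from
millions of markers, where off-diagonal noise is $\sim 10^{-3}$ and the
threshold only catches genuine relatives. A desk-scale simulated panel
of $M \le 10^4$ independent SNPs has noise SD $1/\sqrt{M} \ge 0.01$:
the threshold then sits *inside* the sampling noise and would decimate a
panel of truly unrelated individuals. The pruning default therefore
stays 0.025 on the function and CLI (faithful to the method), but the
pipeline's desk-scale default config and the GREML null-calibration
experiment run REML without pruning — their panels are unrelated by
construction.

## 5. What the generators emulate — and what they do not

`simulate_twin_dataset()` draws phenotypes as $a A + c C + e E$ with
standard-normal latent factors: $A$ shared within MZ pairs, correlated
0.5 in same-sex DZ pairs and `rg_os` (default 0.5) in opposite-sex
pairs; $C$ shared; $E$ independent; ages uniform on 16.1–17.1 years
(identical within pair, mean 16.6); group sizes defaulting to 317 MZm,
519 MZf, 281 DZm, 452 DZf, 689 DZos pairs, mirroring a large adolescent
cohort; and 13% of pairs reduced to singletons completely at random,
mimicking observed completeness. Implied correlations are
$r_{MZ} = a^2+c^2$, $r_{DZ} = \tfrac12 a^2+c^2$.

`simulate_population_sessions()` draws per-subject Weber fractions from
a lognormal matched (after truncation) to mean 0.28, SD 0.13 on
[0.10, 0.99] — positivity and right skew motivate the shape; the window
is the observed range in 16-year-olds. Sessions have 150 trials;
correctness is Bernoulli with the analytic curve's probability; RTs are
lognormal (median 650 ms, sdlog 0.35 — plausible for a 400 ms exposure
task, not a published value) with 3% of trials inflated fourfold to
exercise the trimmer. Under these defaults the trimmer removes about
0–10 trials per session, matching the published removal range, and
accuracy correlates with the fitted $w$ at about $-0.93$ (Spearman
$-0.98$); the published Pearson value of .97 is attenuated here by the
curvature of the accuracy-to-$w$ mapping under a skewed acuity
distribution.

The default ratio schedule spans bins 1:3, 1:2, 2:3, …, 9:10 with dot
counts 5–21, uniform over schedule entries. The easy 1:3 anchor is a
deliberate design choice: without it the instrument stops discriminating
at the blunt end of the acuity range, a visible fraction of per-subject
fits clamp at the upper box bound (which the motivating task's observed
score range shows did not happen), and the accuracy–$w$ coupling drops
to ~0.88–0.90. The published task's exact schedule is not public; this
default is a stand-in, not a reconstruction, and is fully configurable.

`simulate_snp_panel()` draws independent binomial(2, p) dosages with
frequencies uniform on the MAF window, standard-normal effects at
`n_causal` markers acting on standardised dosages, the genetic value
rescaled so its sample variance is exactly `h2_snp`, and Gaussian noise
topping variance up to 1. **Not emulated:** linkage disequilibrium
(so GREML standard errors here do not match array-data SEs, which real
LD inflates), allele-frequency/effect-size coupling, genotyping error
and missingness patterns, population stratification. A green GREML test
therefore establishes the estimator's statistical behaviour on its own
assumptions — not robustness to real-array pathologies.

## 6. Degenerate inputs and tie-breaks

Constant phenotypes: residualisation and ICC raise errors; descriptive
reports flag the ANOVA as undefined. All-tie sessions make $w$
unidentifiable (error). Below-chance sessions clamp at the upper bound
with a flag. Zero-SD reaction times trim nothing. Pruning ties break by
id order; model-selection ties break by BIC. `compare_models()` flags a
nested model beating its parent (an optimiser-failure signal) instead of
reporting a negative test statistic.

## 7. Known limitations

* Likelihoods are Gaussian; heavy-tailed or skewed phenotypes are
  handled by transformation, not by robust likelihoods (ML is known to
  be tolerant here, but p-values near boundaries are approximate).
* Profile CIs assume a unimodal profile; at pathological flat
  likelihoods (tiny samples) the reported interval can span nearly the
  whole unit interval, which is the honest answer.
* The GREML implementation is single-component and univariate;
  covariates are supported but no LD-aware weighting.
* Absolute AIC/BIC magnitudes are convention-dependent; only
  differences within a run are meaningful.
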