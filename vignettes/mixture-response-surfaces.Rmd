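---
title: "Mixture response surfaces: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture response surfaces: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raytox)
```

This vignette is the package's account of the science it implements: the
dose–response and mixture models, the deviation family, how the joint fit and
model selection work, what the synthetic bioassay generator does and does not
emulate, and the numerical and design decisions that were genuinely open.

## Single-chemical model

A quantal endpoint (here: immobilization of *Daphnia magna* neonates after
48 h) is summarized per replicate well as percent mobile,
$100(1 - n_\mathrm{immobile}/n_\mathrm{exposed})$. Each chemical alone follows
a three-parameter log-logistic curve

$$y(c) = \frac{u_{max}}{1 + (c/EC_{50})^\beta},$$

with the lower asymptote fixed at zero: at a high enough dose every animal is
immobilized, which is biologically right for acute metal toxicity and matches
the three-row parameterization ($C_{max}$, $\beta$, $EC_{50}$) that mixture fit
summaries tabulate per model. $u_{max}$ (alias $C_{max}$) is a *fitted*
control response on the percent scale, not pinned to 100: wells lose an
occasional control animal, and forcing 100 would bias the slope.
`fit_single()` estimates the triple by least squares on replicate-level
percent-mobile values and brackets the $EC_{50}$ with a nonparametric
bootstrap that resamples wells within treatments (999 draws, percentile
interval). A bootstrap is used because it is distribution-free, honest about
the replicate structure, and directly testable; no claim is made that it
matches any particular parametric interval.

Parameters that matter:

* `beta` (dimensionless, default start 2): slope at the $EC_{50}$; bounded in
  $[0.05, 50]$ during optimization — outside that range a quantal assay with a
  handful of levels carries no information anyway.
* `ec50` (concentration, native unit): bounded within a factor 10 (single
  fits) / 50 (joint fits) of the observed concentration range.
* `u_max` (percent, in $(0, 100]$): starts at the control mean.

## Reference surfaces and the deviation family

Concentrations are potency-normalized to toxic units $TU_i = C_i/EC_{50,i}$;
a mixture's composition is $z_i = TU_i/\Sigma TU$ (along a "ray" design $z$ is
constant while $\Sigma TU$ is diluted). Two reference models describe a
non-interacting mixture:

* **Concentration addition** (Loewe): $\sum_i C_i / EC_{Y,i} = 1$, where
  $EC_{Y,i} = EC_{50,i}((1-Y)/Y)^{1/\beta_i}$ is the dose at which chemical
  $i$ alone leaves mobility fraction $Y$. Appropriate when components share a
  mode of action; its isoboles are straight.
* **Independent action** (Bliss): $y = u_{max}\prod_i q_i(C_i)$ with
  $q_i = 1/(1+(C_i/EC_{50,i})^{\beta_i})$ the non-response probability.

Both are extended with a deviation function $G$ that vanishes at the
reference:

* CA: $\sum_i C_i / EC_{Y,i} = e^{G}$, solved for $Y$;
* IA: $y = u_{max} (q_1 q_2)^{e^{-G}}$.

with

$$G_{S/A} = a\,z_1 z_2,\qquad
  G_{DR} = (a + b_{DR} z_{lead})\,z_1 z_2,\qquad
  G_{DL} = a\,(1 - b_{DL}\,s)\,z_1 z_2,$$

where $s = \Sigma TU$ for a CA base and $s = E_{ref} = 1 - q_1 q_2$ (the
reference effect fraction) for an IA base. Under both entries $G < 0$ lowers
the surface (synergism, more toxic than the reference) and $G > 0$ raises it
(antagonism). The reductions are exact: $a = 0$ recovers the reference and
$b_{DR} = 0$ or $b_{DL} = 0$ recovers S/A.

Sign-change loci follow in closed form (`switch_locus()`): DR switches at
$z_{lead}^* = -a/b_{DR}$ when $a$ and $b_{DR}$ have opposite signs; CA-DL at
$\Sigma TU = 1/b_{DL}$ (so $b_{DL} = 1$ puts the flip exactly at the mixture
EC50 level, $b_{DL} > 1$ below it, and $0 < b_{DL} < 1$ above it, with no
flip for $b_{DL} \le 0$); IA-DL at effect fraction $1/b_{DL}$ (flip at 50%
effect when $b_{DL} = 2$, none when $b_{DL} \le 1$). These thresholds are the
behavioural contract the algebra was reconstructed to satisfy.

**On the exact algebra.** The IA deviation entry
$y = u_{max}(q_1q_2)^{e^{-G}}$ and the two DL multipliers are this package's
own reconstruction: they are the simplest forms that (i) recover the
reference at $G=0$, (ii) keep $y \in (0, u_{max})$, and (iii) reproduce every
sign and switch-point statement above. Published variants of the MIXTOX
deviation family differ in algebraic detail; all tests in this package are
written against the sign/reduction/switch contract rather than one particular
algebraic form, so substituting another entry form that honours the same
contract would not invalidate them.

## Solving the CA surface

The CA left side is strictly increasing in $Y$ (each term is), so the
extended condition has a unique root in $(0,1)$, found by bisection on
$[10^{-12}, 1-10^{-12}]$ (cap 200 iterations; the interval shrinks below
$10^{-14}$ in ~47, and the residual is checked afterwards). Two choices keep
the solve robust:

* $G$ uses **EC50-based** toxic units, never effect-level ones, so it is a
  constant during the solve and the monotonicity argument survives;
* $G$ is clamped to $[-50, 50]$ so that $e^G$ cannot overflow under wild
  optimizer proposals; the clamp is far outside any scientifically meaningful
  deviation ($|a| \lesssim 5$).

Degenerate inputs are pinned before the solver runs: both concentrations zero
returns $u_{max}$ exactly (and $z$ is set to $(\tfrac12,\tfrac12)$ with
$G = 0$, since composition is undefined there), and a single-chemical pair
reduces analytically to the marginal curve because $z_1 z_2 = 0$.

## Joint fitting and model selection

All eight models — $\{$CA, IA$\} \times \{$reference, S/A, DR, DL$\}$ — are
fitted by minimizing the sum of squared residuals over **treatment means**
(replicates averaged; a `replicate`-level option exists in `run_config()`).
Each model re-estimates the full shared vector
$(u_{max}, \beta_1, \beta_2, EC_{50,1}, EC_{50,2})$ plus its deviation
parameters rather than freezing the marginals: the single-chemical data enter
the same SS, and letting the shared parameters move is what makes the nested
SS ordering $SS_{ref} \ge SS_{S/A} \ge SS_{DR/DL}$ exact rather than
approximate. Slopes and EC50s are optimized on the log scale; multi-start
initialization combines the two marginal fits (deviation parameters at 0 and
$\pm 1$) with Latin-hypercube perturbations up to the `multistart` budget
(default 16).

Minimizing Gaussian SS is maximum likelihood, so nested models are compared
with $\chi^2 = n \ln(SS_{reduced}/SS_{extended})$ on df = number of added
parameters, $n$ being the count of observation units (treatment means). Each
extension is tested **against its base reference** (df 1 for S/A, 2 for DR
and DL); the stepwise S/A→DR and S/A→DL comparisons are reported alongside.
With the default design below, $n = 35$; that convention — treatment means,
reference-based df — is the one under which the package's LRT reproduces the
published six-entry p-value row of the motivating study from its printed SS
values alone, which is what fixed it. Selection takes the significant
($p < \alpha$, default $\alpha = 0.05$) extension with the lowest SS, else
the better-fitting reference; ties between DR and DL go to the lower SS.

## The synthetic bioassay generator

Raw well-level immobilization data for the motivating study are not
published, so the generator stands in for them and every claim in this
package is tested against it. It reproduces the study's *design*:

* single-chemical series: 6 log-spaced AgNO₃ levels on 0.5–2.5 µg/L and 7
  log-spaced ZnO levels on 0.04–20 mg/L (the printed ranges; the level
  counts are not printed and were chosen so the full design has 35
  treatments, the $n$ that reproduces the published p-value row);
* three rays at TU ratios 5:5, 3:7, 7:3, each at seven $\Sigma TU$ levels
  spanning 0.0625–2.0. "Serial dilution" across seven levels cannot be a
  constant factor-2 series (that yields six), so the levels are log-spaced
  with ratio $2^{5/6}$ — a reconstruction, recorded as such;
* one shared control; 8 replicate wells × 5 animals per treatment;
* well-level noise: $n_\mathrm{immobile} \sim
  \mathrm{Binomial}(5,\, 1 - y_\mathrm{pred}/100)$, no overdispersion term
  (none is inferable from the published summaries).

What it does **not** emulate: nanoparticle dissolution kinetics, ion
adsorption, agglomeration, exposure-medium chemistry, or any time structure —
the generator draws from the *fitted response surface*, so passing tests
demonstrate statistical correctness of the estimators on data that follow
the model, not robustness to the physico-chemical complications of real
nanoparticle suspensions. One visible consequence: pure binomial 8×5 noise
gives treatment-mean SS around 2000 on the full design, several times the SS
scale of the study's real fits, so a single simulated assay frequently fails
to flag the DR deviation as significant even when it generated the data.
Parameter recovery is therefore assessed over repeated simulations — medians
over 200 seeded simulate–refit runs recover the generating deviation
parameters and EC50s to a few percent — rather than from single-assay
significance.

Determinism: every stochastic routine takes an explicit seed, derives
per-simulation substreams from it, and restores the caller's RNG state; the
multi-start Latin-hypercube draws inside the optimizers use a fixed local
substream, so a fit is a deterministic function of (data, configuration).

## Numerical choices and degenerate inputs

* Optimizer: `nlminb` with box constraints; SS tolerance $10^{-10}$.
* Non-identifiable single-chemical data (no response gradient) raise a typed
  error rather than returning a flat fit; a missing control warns and leaves
  $u_{max}$ unconstrained.
* A worse extended fit (possible only through optimizer slack) clamps the
  LRT statistic to 0, $p = 1$.
* Isoboles are extracted from a rectilinear surface grid by contour
  interpolation; effect levels not attained on the grid yield empty output
  with a warning.
* Problem sizes in the test suite: property loops use 10–25 random draws;
  recovery checks use 50–200 simulations at the 35-treatment design; the
  bisection solver is cross-checked against a $10^{-6}$-resolution grid
  search.

## Known limitations

* Strong *antagonistic* S/A deviations ($a \gtrsim 2$) make both extended
  surfaces locally non-monotone along axis-parallel transects — the deviation
  term grows from the axis inward faster than the reference falls. This is a
  property of the deviation family itself, not of the solver; monotonicity
  is guaranteed (and tested) for the reference surfaces and, for any S/A
  deviation, along fixed-ratio rays where $G$ is constant.
* Binary mixtures only; the deviation algebra is written for two components.
* Least squares on percent scale, not a binomial GLM: variance is treated as
  homoscedastic across treatments, which is the convention of the MIXTOX
  family this package follows, not an efficiency claim.
* Hormesis, time-to-event endpoints and nonzero lower asymptotes are out of
  scope.
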