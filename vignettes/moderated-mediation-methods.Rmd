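---
title: "Bayesian two-level latent moderated mediation: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian two-level latent moderated mediation: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bmlmm` fits a 1-1-1 latent mediation model — predictor X, mediator M,
outcome Y all measured at the individual level by continuous indicators —
for individuals nested in clusters, with an observed cluster-level moderator
acting on the two mediation paths. Every observed indicator is decomposed
into a between-cluster and a within-cluster component,

$$y_{kig} = \nu_k + \lambda^b_k\,\eta^b_{f(k),g} + \delta_{kg}
          + \lambda^w_k\,\eta^w_{f(k),ig} + \varepsilon_{kig},$$

so that each factor has a within score per row and a between score per
cluster, each with its own loadings and residual variances. The moderator
$Z$ is decomposed by latent centering: a sampled cluster-level component
$Z_{bg} \sim N(\mu_Z, \psi_{Zb})$ plus an individual deviation — not the
arithmetic cluster mean (an `update_z` control flag can freeze the
decomposition for comparisons).

The within-level structural model has cluster-specific a and b paths,

$$M^w_{ig} = s_{a,g} X^w_{ig} + \beta_{MZ_w} Z^w_{ig} + \zeta_{M,ig},
\qquad
Y^w_{ig} = s_{b,g} M^w_{ig} + c'_w X^w_{ig} + \beta_{YZ_w} Z^w_{ig}
  + \zeta_{Y,ig},$$

with
$s_{a,g} = \gamma_{a0} + \gamma_{aZ}\,(Z_{bg}-\mu_Z) + u_{a,g}$ and
likewise for $s_{b,g}$, where $(u_a, u_b) \sim N(0, T)$ with an
unstructured $2\times 2$ covariance $T$. The between-level structural
model repeats the paths on the between scores with the centered moderator
as covariate. Because the slopes vary and may covary, the expected
within-level indirect effect is $E(a_g b_g) = E(a)E(b) + \sigma_{ab}$ with
$\sigma_{ab}$ the off-diagonal of $T$; all effect functions
(`indirect_within()`, `conditional_indirect()`) include this term per draw.

### Two parameterizations, one posterior

The cross-level moderation can be written two ways. Random coefficient
prediction (RCP) regresses the random slopes on the moderator at level 2;
the latent-interaction form (often called LMS in the maximum-likelihood
literature) keeps the slopes intercept-only and adds the product terms
$X^w (Z_b - \mu_Z)$ and $M^w (Z_b - \mu_Z)$ with fixed coefficients to the
level-1 equations. Substituting the slope equation into the level-1 model
shows the two mixed forms are identical term by term, with the slope
regression weight of the one equal to the product-term coefficient of the
other — `mixed_form()` exhibits the common canonical form and
`conditional_mean()` evaluates each route numerically (they agree to
machine precision).

With matched priors the two parameterizations induce the *same joint
posterior*; what differs is the Gibbs blocking. `brcp_spec()` samples the
moderation weight in the cluster-level slope regression (J observations,
error covariance $T$); `bint_spec()` samples it in the row-level structural
regression through the product term (N observations). The canonical trace
labels `mod_a`/`mod_b` hold the weight either way, which is what makes
`compare_models()` a like-for-like comparison and is why the two fits are
expected to differ only by Monte Carlo error.

## The Gibbs sampler

All full conditionals are conjugate: multivariate normal for factor scores
(drawn jointly per row at the within level, per cluster at the between
level, from the precision assembled out of the measurement part and the
recursive structural part), normal for loadings, intercepts and structural
coefficients, bivariate normal for the random effects, inverse-gamma for
every residual variance, inverse-Wishart for $T$, and normal for the latent
moderator decomposition (which collects terms from the moderator's own
two-level model, the between regressions, and — because the slopes depend
on $Z_b$ — the within equations).

Identification follows the usual anchor convention: the first loading of
each factor is fixed to 1 at both levels, factor variances are free, latent
means are zero, and the between-level indicator intercepts $\nu_k$ are
free. The moderator enters every structural equation centered at its
estimated grand mean $\mu_Z$; this keeps the zero-latent-mean constraint
consistent without free structural intercepts (a free intercept would be
redundant with $\nu$ and the between scores and produces a likelihood-flat
ridge).

Two blocking refinements matter for mixing and are worth documenting:

* **Collapsed cluster-level draws.** The between residual $\delta_{kg}$ of
  each indicator is integrated out of the conditionals of $\nu_k$,
  $\lambda^b_k$ and the between factor scores (their likelihood then uses
  the cluster means with variance $\theta_b + \theta_w/n_g$), and
  $\delta_{kg}$ is redrawn from its full conditional immediately after each
  collapsed draw. Each such pair is a valid joint block update; without the
  collapse these parameters random-walk against $\delta$ and dominate the
  potential scale reduction.
* **Primitive random effects.** The state stores $u_g$ (slope residuals),
  not the effective slopes, so the latent-moderator update conditions on
  $u$ and recomputes $s_{a,g}, s_{b,g}$ afterwards; both parameterizations
  share all blocks except the two that carry the moderation weight.

Starting values are least-squares composites (block means split into
cluster means and deviations) with loadings 1, coefficients 0 and variances
1; chains after the first jitter their starting coefficients
($SD = 0.1$). Draws are stored without thinning.

### Priors

The prior families are the conjugate ones: normal for loadings, intercepts
and regression coefficients, inverse-gamma for residual variances,
inverse-Wishart for $T$. Hyperparameters default to diffuse choices —
$N(0, 10^6)$, $IG(0.001, 0.001)$, $IW(I_2, 3)$ — exposed through
`mlmm_priors()`. The $IW(I_2, 3)$ prior is the weakest proper choice for a
$2\times2$ covariance; at very small cluster counts it is mildly
informative about the slope variances, which is shared by any proper
inverse-Wishart default.

### Convergence and extension

`psr()` implements the classic (non-split) Gelman–Rubin potential scale
reduction per stored parameter, with the zero-variance convention that
identical constant chains give 1 (anchor loadings) and differing constants
give infinity. A fit is flagged non-converged when any parameter exceeds
1.1. `fit_until_converged()` doubles the retained length on failure —
continuing each chain from its final state and promoting the pre-extension
half to burn-in, the classic practice of discarding the early portion of a
run — until a per-chain iteration ceiling is reached (default 100,000;
desk-scale runs use much lower ceilings, see below).

## The data generator

`mlmm_design()`/`simulate_mlmm()` implement the generating model used
throughout the tests: six indicators per factor, reliability 0.60, latent
intraclass correlation 0.20, paths $a = 0.4$, $b = 0.5$, $c' = -0.2$ at
both levels (within indirect effect $0.4 \times 0.5 = 0.2$), moderator
effects $-0.1/0.1$ within and $-0.2/0.2$ between, moderator variance 0.5
per level (total 1), clusters of size 30, random-slope variance 0 or 0.5,
moderation 0 or 0.3. Choices the design description leaves open were fixed
once:

* **Variance split.** "Latent variance 1" and "ICC 0.20" are reconciled as
  total latent variance 1 split $\psi_b = 0.2$, $\psi_w = 0.8$, keeping the
  factors and the (total-variance-1) moderator on the same scale.
* **Residual derivation.** Structural residual variances are derived so the
  *baseline* model (zero slope variance, zero moderation) reproduces those
  factor variances exactly; with active moderation or slope variance the
  realized M and Y variances inflate slightly, as in any such design.
* **Reliability over levels.** All loadings are 1 and the total indicator
  error $(1-\rho)/\rho$ is split across levels in proportion to the level's
  factor variance, so total reliability is 0.60 without asserting a
  per-level reliability the design does not define.
* **Slope covariance.** The generating $\sigma_{ab}$ is 0 (slope variances
  only are specified); the fitted model still estimates a full $T$.
* **Moderator effects.** The within-level moderator effect on the outcome
  is $+0.10$ (its description is ambiguous between levels; the between
  effect is separately $+0.20$).

The generator stores its latent scores, cluster slopes and all generating
values alongside the data, which is what makes generator-side truths (for
conditional indirect effects at $\pm 1$ SD) and latent-score checks (ICC,
reliability) possible without refitting. What the generator does *not*
emulate: non-normal indicators, unbalanced clusters, missing data, latent
moderators. Passing tests therefore speak to the estimator under the
generating model, not to robustness against those departures.

## Effects and comparison metrics

Effect traces are computed draw by draw and summarized by the posterior
median and the 2.5th/97.5th percentile interval (linear interpolation
between order statistics — the interpolation rule matters at these
percentiles and is therefore fixed and documented); an effect is flagged
significant when the interval excludes zero. Conditional indirect effects
at $\pm 1$ SD of the moderator use, by default, the per-draw posterior SD
of the latent between component ($\sqrt{\psi_{Zb}}$); a raw moderator value
can be supplied instead.

Posterior agreement between the two parameterizations uses two metrics: the
overlap coefficient $\int \min(f_a, f_b)$, estimated from kernel density
estimates on a common 512-point grid with a shared bandwidth (a histogram
estimator was considered and rejected: its downward bias of order
$\sqrt{\text{bins}/n}$ masks genuinely identical posteriors at realistic
draw counts), and a probability-based effect size, the absolute difference
in posterior means over the pooled posterior SD. Differences are negligible
at effect size < 0.2 and overlap > 0.9; both estimators are deliberately
simple and replaceable.

## The Monte Carlo harness and desk-scale choices

`run_condition()` generates, fits until converged, and records the
moderation weights' medians and credible intervals and the conditional
indirect effects at $\pm 1$ SD. Detection (interval excludes zero) is
evaluated per moderation parameter and the headline rate averages the two;
replications still above the PSR threshold at the iteration ceiling are
counted into the non-convergence rate and replaced from a disjoint seed
stream (`base_seed + 100000 + k`), all seeds recorded. Relative bias,
`(mean estimate − truth)/truth`, is computed only against nonzero truths;
for moderated mediation the truths come from the generator.

The shipped test suite runs the study at reduced scale, a deliberate
choice of problem sizes: 50 replications per condition; chains of 1,200
iterations with 500 burn-in, extended up to ceilings of 19,200 (J = 100)
and 9,600 (J = 20); conditions (J = 100, $\tau^2 = 0.5$, $\gamma = 0.3$),
(J = 20, $\gamma = 0.3$) and (J = 20, $\gamma = 0$) under the BRCP
blocking, the posterior-equivalence check standing in for a duplicate run
under BINT. Rates at 50 replications carry binomial noise, so the bounds
are asserted with a two-standard-error Monte Carlo allowance. Two
quantities are reported but not asserted at J = 20: the relative bias of
the moderation weight (its per-replication dispersion at 20 clusters makes
a 50-replication mean an unreliable estimate of bias) and the
non-convergence rate (that bound is a property of the 100,000-iteration
ceiling, an order of magnitude beyond the desk-scale ceilings used here).

## Known limitations

* Only the 1-1-1 topology with one observed moderator acting on both
  random slopes is supported; 2-1-1/2-2-1 designs, latent moderators and
  categorical indicators are out of scope.
* Missing values are rejected rather than imputed.
* The between-level coefficients mix more slowly than within-level ones
  (their information comes from J clusters through noisy cluster scores);
  at J = 20 expect chain extensions.
* No thinning and full trace storage: long runs at the 100,000-iteration
  ceiling hold all draws in memory (~100 MB per chain at 127 parameters).
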