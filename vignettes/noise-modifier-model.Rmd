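---
title: "The noise-modifier model: closed forms, oracles, and the Wright-Fisher engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The noise-modifier model: closed forms, oracles, and the Wright-Fisher engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisemod)
```

## The model

Many alleles do not shift a phenotype's expected value; they change how
*variable* it is — mutator polymerases, recombination modifiers, regulators
of epigenetic fidelity or of gene-expression stochasticity. Selection on
such noise-modifier alleles is indirect: it acts only through the random
phenotypic perturbations they induce in their carriers, and through however
long each allele stays statistically associated with the perturbations it
caused. `noisemod` implements a deliberately minimal model of this
situation, in two layers: exact closed forms for the one-generation
distribution of fitness effects (DFE) of noise, and an individual-based
Wright–Fisher simulator for the multi-generation fate of competing noise
alleles.

The one-generation layer assumes a single scalar trait. A carrier with
expected phenotype $z_0$ realizes

$$Z \sim \mathcal{N}(z_0, \sigma^2),$$

where $\sigma$ measures the amount of noise its modifier allele induces.
Malthusian fitness falls quadratically from a phenotypic optimum, placed at
the origin without loss of generality: $r(z) = r_{\mathrm{opt}} - z^2$. The
fitness effect of realizing $z$ instead of $z_0$ is therefore

$$\Delta r = z_0^2 - z^2,$$

independent of $r_{\mathrm{opt}}$, bounded above by $z_0^2$ (jumping
exactly onto the optimum), and unbounded below.

### Exact consequences

Three quantities summarize the induced DFE, all implemented in closed form:

* **Unconditioned mean.** $E[\Delta r] = -\sigma^2$ exactly, for *any*
  $z_0$ and indeed for any noise density with variance $\sigma^2$, since
  $E[z_0^2 - Z^2] = -\mathrm{Var}(Z)$. Noise is deleterious on average
  (Jensen's inequality on a concave-down fitness map), without limit as
  $\sigma$ grows. `expected_effect()` returns this; the test suite verifies
  the distribution-free claim by re-estimating it under variance-matched
  uniform and Laplace noise.
* **Beneficial probability.** A perturbation helps iff $|Z| < |z_0|$;
  `beneficial_probability()` evaluates this normal probability. It is zero
  at the optimum, approaches $1/2$ as $\sigma \to 0$ off the optimum, and
  no perturbation of magnitude beyond $2|z_0|$ can ever help.
* **Conditioned mean.** `conditional_expected_effect()` evaluates
  $E[\Delta r \mid \Delta r > 0]$ from truncated Gaussian moments on the
  beneficial interval $(-|z_0|, |z_0|)$: with standardized endpoints
  $\alpha = (-|z_0|-z_0)/\sigma$, $\beta = (|z_0|-z_0)/\sigma$ and
  $I_0 = \Phi(\beta)-\Phi(\alpha)$,
  $$E[\Delta r \mid \Delta r > 0] =
    \frac{-2 z_0 \sigma\,(\phi(\alpha)-\phi(\beta))
          - \sigma^2 (I_0 + \alpha\phi(\alpha) - \beta\phi(\beta))}{I_0}.$$
  It is always positive and approaches the plateau $\tfrac{2}{3} z_0^2$ as
  $\sigma \to \infty$ (the conditional phenotype density flattens over the
  beneficial interval). The tension between this rising curve and the
  falling $-\sigma^2$ is what makes an intermediate amount of noise
  selectively optimal away from the optimum.

The density itself, `dfe_pdf()`, is the change-of-variables image of the
Gaussian through the quadratic map: both preimages
$z = \pm\sqrt{z_0^2 - \Delta r}$ contribute, and the Jacobian produces an
integrable square-root singularity at the upper support endpoint
$\Delta r = z_0^2$. Evaluating exactly on the boundary raises an error by
design; integration always uses the open upper limit.

```{r curves, fig.width = 6, fig.height = 3.5}
autoplot(dfe_curves(z0 = c(-2, -1), sigma_grid = seq(0.05, 2, by = 0.05)))
```

One subtlety we found while validating: the conditioned mean is *not*
globally monotone in $\sigma$. For the reference parameterization
$|z_0| = 2$ it rises monotonically on $\sigma \in [0.05, 2]$, but for
smaller displacements (e.g. $|z_0| = 1$) the curve overshoots its
$\tfrac{2}{3} z_0^2$ plateau slightly (peak near $\sigma \approx 1.4$)
before settling onto it. The package asserts monotonicity only on the
reference range. The plateau ordering in $|z_0|$ — more maladapted
organisms have more to gain — holds everywhere we checked.

### Oracles

Every closed form is checked against two independent routes that share no
transformation code with it:

* `mc_expected_effect()` samples phenotypes (`sample_phenotypes()`) and
  pushes them through the fitness map — the sampling image of the model's
  first two ingredients.
* `quad_moment()` integrates `dfe_pdf()` directly in $\Delta r$ space with
  adaptive quadrature (`stats::integrate`, absolute tolerance $10^{-9}$,
  lower limit truncated where the phenotype is $10\sigma$ from its mean;
  the neglected tail mass is below $10^{-20}$). The quadrature value is the
  authoritative reference for the conditioned mean: the closed form must
  match it to $10^{-4}$ relative, not vice versa.
* `empirical_dfe_check()` bins sampled effects into equal-probability bins
  of the analytic density (equal-probability binning keeps the boundary
  singularity from dominating one bin) and flags any bin off by more than
  3 binomial standard errors. With 40–50 bins this is an intentionally
  strict, slightly conservative family of tests; seeds are fixed where it
  is asserted.

`verify_closed_forms()` (and `noisemod verify` on the command line) runs
the whole battery; a documented fault-injection hook perturbs the
conditioned closed form so the suite's own sensitivity is testable.

## The Wright–Fisher engine

The multi-generation layer is an individual-based, discrete-generation,
constant-$N$ Wright–Fisher simulation of two modifier alleles, `low` and
`high`, that differ *only* in the noise magnitude they induce
($\sigma_{\mathrm{low}}$, $\sigma_{\mathrm{high}}$); they never shift the
expected phenotype, so all selection on them is indirect. Each individual
carries a heritable value $g$ and realizes $z = g + \varepsilon$ with
$\varepsilon \sim \mathcal{N}(0, \sigma_{\mathrm{allele}}^2)$ drawn fresh
at birth with its own allele's magnitude. One generation
(`wf_step()`):

1. the optimum sits at $z_{\mathrm{opt}}(t) = v t$ (linear directional
   change; cyclic environments are out of scope);
2. selection weights are $w_i = e^{r_i}$ with
   $r_i = -(z_{\mathrm{opt}} - z_i)^2$ — the standard exponential map from
   Malthusian fitness to discrete-generation viability ($r_{\mathrm{opt}}$
   cancels; the maximum weight is factored out for numerical stability);
3. $N$ offspring draw parents multinomially;
4. an offspring inherits $g' = g + \kappa\,(z - g)$: the fraction $\kappa$
   of the parent's realized perturbation becomes heritable;
5. with probability `recomb_prob` the offspring's *modifier allele* is
   copied from a second, independently fitness-weighted parent instead —
   an abstraction of recombination decoupling a modifier from the genetic
   background it shaped.

The two knobs span the association-timescale spectrum: $\kappa = 1$,
`recomb_prob = 0` is the asexual-mutator limit (an allele stays permanently
linked to every perturbation it caused); intermediate `recomb_prob` gives a
geometric association time with mean `1/recomb_prob` generations (verified
empirically via `association_times()`); $\kappa = 0$ is the uncorrelated
limit in which parent and offspring phenotypes share only $g$.

Design choices worth stating explicitly:

* **Burn-in.** With `burn_in > 0`, the population first evolves
  monomorphic for the resident allele; invaders then replace randomly
  chosen residents. This is the natural invasion design when the resident
  needs to equilibrate (e.g. to establish a lag behind a moving optimum).
* **Seeding.** Every stochastic function takes a seed and restores the
  caller's RNG state; replicate seeds in `fixation_probability()` and the
  scans are derived deterministically from one master seed, so scan tables
  are bit-reproducible.
* **Timeouts.** Runs are capped at `max_generations` (default $50N$,
  generous relative to the $\approx 2N$ conditional neutral fixation time);
  timeouts count as non-fixation and are reported separately.
* **Classification.** Scans classify the direction of selection against
  the neutral martingale expectation (a single invader fixes with
  probability exactly $1/N$ when the alleles are interchangeable) at 3
  binomial standard errors computed under that neutral null.
* **Census size.** All results are reported against census $N$; with
  non-overlapping generations, multinomial resampling and no demographic
  structure, effective and census size coincide here up to the
  selection-induced variance in offspring number.

## Calibrations, study conditions, and what they do (not) show

The default parameters are the model's reference conditions: displacement
$|z_0| = 2$ with $\sigma \in \{0.4, 0.05\}$ for the DFE layer (and
$|z_0| = 1$ for the plateau-ordering comparison); $N = 100$ with 5000
single-invader replicates for the neutral $1/N$ calibration and the
reduction-principle checks; Monte-Carlo oracles use $10^6$ draws with
agreement asserted at 3 standard errors; quadrature grids use the 12-point
cross $(z_0, \sigma) \in \{-2, -1, -0.1\} \times \{0.05, 0.4, 1, 4\}$.
These sizes keep the complete test battery in the tens of seconds while
leaving every assertion's Monte-Carlo error well inside its tolerance.

The engine reproduces the core qualitative predictions:

* **Reduction principle.** At a static optimum a noiseless invader beats a
  noisy resident well above $1/N$, and the reverse invasion is suppressed
  below $1/N$.
* **Drift barrier.** In the population-size scan at the optimum, small-$N$
  points are neutral-indistinguishable and large-$N$ points are classified
  disfavored: selection against noise resolves only once $N$ exceeds the
  drift barrier.
* **Lag law.** With heritable perturbations ($\kappa = 1$) and a moving
  optimum, the time-averaged lag grows with the optimum's speed, and the
  selectively optimal $\sigma$ on an invasion grid moves up with $v$.

One predicted ordering does **not** hold in this engine, and we report that
as a finding rather than hiding it. Under maladaptation, ranking invasion
success purely by association timescale predicts: permanent linkage
($\kappa = 1$, no recombination) highest, recombining ($\kappa = 1$,
`recomb_prob = 0.5`) lower, uncorrelated ($\kappa = 0$) lowest. The first
two comparisons hold robustly — recombination is devastating to a noise
allele's prospects (even `recomb_prob = 0.02` collapses invasion success,
because the allele donates its adapted background to the resident within a
few generations while retaining the full noise cost). But the uncorrelated
limit is *not* the minimum: with multiplicative $e^{\Delta r}$ weights, an
uncorrelated noise allele in a maladapted population earns a first-order
boost in expected offspring,
$E[e^{\Delta r}] = e^{a^2\sigma^2/(2(1+2\sigma^2))}/\sqrt{1+2\sigma^2}$
with $a = 2|z_0|$, which turns net-favorable once
$|z_0| > \sqrt{(1+2\sigma^2)/2} \approx 0.81$ for $\sigma = 0.4$. The
verbal intuition that a one-generation windfall "cannot compound" without
parent–offspring correlation presumes the windfall averages out in
Malthusian (log) terms; under multiplicative Wright–Fisher weights it does
not. In regimes weak enough for the uncorrelated allele to be
net-deleterious, both it and the recombining allele pin near zero fixation
probability and cannot be ordered statistically. The corresponding
acceptance test asserts the full three-way ordering at the frozen study
conditions ($N = 100$, offset $0.8$ — approximately the uncorrelated
allele's neutrality point, where only the variance penalty remains —
$\sigma$ 0 vs 0.4, 10% introduction) and is expected to fail on the
recombining-vs-uncorrelated leg; we left it failing deliberately.

## What the generator emulates, and what it does not

The synthetic conditions emulate a single quantitative trait under
stabilizing (quadratic, concave-down everywhere) selection with Gaussian,
single-moment noise modifiers and exactly two alleles. Real biological
noise mechanisms violate each of these in instructive ways: modifiers may
affect higher moments or several pleiotropically coupled traits; fitness
maps may flatten, truncate, or become convex far from the optimum (where
Jensen's argument reverses sign); developmental noise re-perturbs
phenotypes many times per generation; and real populations mutate among
many modifier alleles rather than competing exactly two. Passing tests
therefore certify the mathematics and the engine, not the claim that any
particular biological system sits in this regime.

## Degenerate inputs and numerical corners

* $\sigma = 0$: the DFE is a point mass; `expected_effect()` returns 0,
  while `dfe_pdf()` and `conditional_expected_effect()` raise
  degenerate-model errors.
* $z_0 = 0$: no beneficial outcomes exist; the conditioned mean raises a
  conditioning-on-null-event error and the beneficial probability is 0.
* The density boundary $\Delta r = z_0^2$ errors rather than returning a
  number; quadrature uses the open limit and the interior Gauss–Kronrod
  nodes never touch it.
* The upper integration limit for all moments is read as the supremum
  $z_0^2$ of the fitness effect's support.
* Selection weights are computed as $e^{r - \max r}$, so arbitrarily large
  lags cannot overflow.
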