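---
title: "Methods: Bayesian phylogenetic regression of tumour prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian phylogenetic regression of tumour prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloprev)
```

## The problem

Comparative oncology asks whether species-level life-history traits — above
all body mass and maximum longevity — predict tumour prevalence across
vertebrates (Peto's paradox: a naive multistage-carcinogenesis argument
predicts more cancer in bigger, longer-lived animals, which is largely not
observed). The available data are zoo necropsy registries: for species $i$,
$k_i$ tumour cases (neoplasia, malignancy, or lethal cancer) out of $n_i$
necropsies, with $n_i$ small (floor of 20, median around 40) and prevalence
low (mostly below 0.2). Two statistical facts dominate: binomial uncertainty
at these sample sizes is large (a true prevalence of 0.1 is hard to
distinguish from 0 below $n \approx 25$), and species are not independent —
related species resemble each other.

## The model

phyloprev fits the binomial phylogenetic regression

$$k_i \sim \mathrm{Binomial}(n_i,\ p_i), \qquad
\mathrm{logit}(p_i) = \beta_0 + \sum_m \beta_m x_{mi} + u_i,$$

with $x_m$ the log10 body mass (kg) and/or log10 maximum longevity (months),
optionally their product, and $\mathbf{u} \sim \mathcal N(0,
\sigma^2_{\mathrm{phylo}} R(\theta))$ a species random effect correlated
along the phylogeny. Two correlation families are supported, both built from
the shared-path-time matrix $t_{ij}$ (root-to-MRCA time) of an ultrametric
tree of depth $T$:

* **Ornstein–Uhlenbeck** (root-anchored, unit diffusion):
  $V_{ij} = \frac{1}{2\alpha} e^{-2\alpha(T - t_{ij})}
  (1 - e^{-2\alpha t_{ij}})$, normalized by its constant diagonal to a
  correlation matrix. As $\alpha \to 0$ this is exactly the Brownian
  correlation $t_{ij}/T$; large $\alpha$ erases phylogenetic correlation.
  The OU covariance is never written out in the source analyses; this
  root-anchored non-stationary form is the standard comparative-methods
  `vcv` and was chosen because its closed-form limits make it testable.
* **Pagel's λ**: $R_{ij} = \lambda\, t_{ij}/T$ off-diagonal, unit diagonal,
  $\lambda \in [0,1]$.

Trees are depth-normalized to 1 by default before fitting so that $\alpha$
(units 1/time) is comparable across datasets. Ultrametricity is validated
within a relative tip-depth spread of `1e-3` and never silently repaired.
The structure parameter is **estimated jointly** with the other parameters
by default (`structure_mode = "estimate"`); a `fixed` mode exists because
brms-style workflows supply a pre-transformed covariance matrix. We default
to joint estimation since fixing the parameter understates posterior
uncertainty, and nothing in the source workflow requires a fixed value.

## Priors

The source analyses used unstated sampler-default priors. The documented
stand-ins here are proper and weakly informative: $\beta_m \sim
\mathcal N(0, 10)$; $\sigma_{\mathrm{phylo}} \sim$ half-Student-t(3, 0, 2.5)
(the common default scale for random-effect SDs); $\alpha \sim$
half-$\mathcal N(0, 5)$ on a depth-1 tree; $\lambda \sim U(0,1)$. All are
adjustable through `prior_config()` for prior-sensitivity checks.

## Sampler and its numerical choices

Sampling uses adaptive random-walk Metropolis-within-Gibbs (compiled core)
over $(\beta, \log\sigma, \theta, \mathbf z)$ with the **non-centred**
parameterization $\mathbf u = \sigma L(\theta)\mathbf z$, $L$ the Cholesky
factor of $R(\theta)$ — this keeps the chain well-behaved when $\sigma$ is
small and makes the $\lambda = 0$ / $\sigma = 0$ reductions exact. Proposal
scales adapt during burn-in only (Robbins–Monro on the log scale toward 0.44
acceptance) so the retained chain is a valid Markov chain. The structure
parameter moves on a transformed scale ($\log \alpha$, logit $\lambda$) with
Jacobians; each accepted move recomputes the Cholesky factor, with a
diagonal jitter ladder ($10^{-10} \dots 10^{-6}$) guarding semi-definite
matrices. Draws are retained at burn_in + thin, burn_in + 2·thin, …
(`(iterations - burn_in) %/% thin` per chain); identical seeds give bitwise
identical draws.

A consequence worth stating plainly: the default run length (5000
iterations, burn-in 2000, thin 5, 4 chains — the settings of the original
workflow) yields ~2400 retained draws whose bulk/tail ESS under this
random-walk sampler is typically 100–300, so the strict convergence gate
(ESS > 1000, |R-hat − 1| ≤ 0.01, |lag-1 autocorrelation| < 0.1) often fails
even when point estimates and intervals are accurate. The original used
Hamiltonian Monte Carlo, which mixes far better per draw. The gates are
reported faithfully and are configurable; the pipeline retries a failing fit
once at 4× iterations. Parameter-recovery tests (bias, coverage) rather than
raw ESS establish estimation quality at desk scale.

## Model evaluation

* **Split R-hat** (each chain halved) with the constant-chain convention
  R-hat = 1 + warning.
* **ESS**: rank-normalized bulk ESS and 5%/95% indicator tail ESS, Geyer
  initial-monotone-sequence truncation, capped at 1.5× the draw count.
* **WAIC** from the pointwise log-likelihood matrix (log-sum-exp stabilized),
  and **PSIS-LOO** with a Zhang–Stephens (2009) empirical-Bayes generalized
  Pareto fit to the top 20% of importance weights, expected-order-statistic
  smoothing capped at the raw maximum, and the Pareto-$k > 0.7$ count
  reported. A species whose pointwise log-likelihood is constant across
  draws is flagged with $k = -\infty$ (degenerate weights). No regularizing
  prior is added to the Pareto shape, keeping the estimator an exact
  transcription of the published algorithm.
* **OU vs λ comparison**: lower WAIC wins; |ΔWAIC| < 2 is flagged
  indistinguishable but still resolved, and deltas are reported signed
  (λ − OU).
* **Posterior predictive checks** use randomized-quantile (PIT) residuals —
  the correct residual object for discrete data — with a Kolmogorov–Smirnov
  uniformity test and observed-vs-replicated zero-count and max-prevalence
  summaries.

## Effect reporting

Slopes are reported as odds ratios: quantiles are computed on the logit
scale and exponentiated (exp is monotone, so this is exact). "Significant"
everywhere means the central 95% credible interval of the slope excludes 0.
Marginal-effect curves hold the other covariates **at their in-sample
means** and the species effect at 0; the original description ("holding all
parameters constant") does not say at which values, and in-sample means are
the standard population-level choice and reproduce the published curve
shapes. Raw per-species prevalences get Jeffreys intervals
(Beta(k+½, n−k+½) quantiles with the k = 0 / k = n boundary rules). The
source text recommends Jeffreys for n ≤ 40; we apply it uniformly for
consistency across a dataset, noting that above n ≈ 40 all standard
intervals agree closely anyway. `ci_width_curve()` computes the expected
interval width by exact summation over $k \sim \mathrm{Binomial}(n, p)$ —
deterministic, hence testable — and reproduces the qualitative picture that
motivates the whole enterprise: widths shrink in $n$, peak at $p = 0.5$, and
are very wide below $n = 25$.

## Resampling sensitivity study

`shuffle_necropsies()` permutes the multiset $\{n_i\}$ across species and
sets $k_i' = \mathrm{round}(\hat p_i n_i')$ (half away from zero, clamped),
holding each species' observed prevalence fixed up to rounding — the
minimal-noise reading of "adjusting counts to preserve the prevalence
ratios"; a `redraw = "binomial"` variant adds resampling noise for
sensitivity. `resampling_study()` refits 50 shuffled replicates (the stated
design) with shorter chains by default (2000 iterations, burn-in 1000) to
keep 50 refits desk-feasible, re-estimating the structure parameter per
replicate by default (`fix_structure = TRUE` reuses the base-fit posterior
median instead — the source is silent on which was done). Per-replicate
convergence uses the conventional relaxed R-hat ≤ 1.1 bound; failures are
counted, reported, and excluded from denominators only in `strict` mode,
and a report with > 20% failures is marked unreliable.

## The synthetic-data generator

`simulate_dataset()` states the world the tests assume: a Yule tree
(depth 1), log10 body mass spanning roughly −2 to 3 (the observed range is
0.00035–4800 kg), log10 longevity (months) correlated with mass at ρ ≈ 0.5,
both optionally Brownian on the tree so covariates carry phylogenetic
signal; necropsy counts $n_i = 20 + \mathrm{NegBin}(\text{mean } 25,
\text{dispersion } 1.2)$, giving the observed floor of 20, median ≈ 38 and a
long right tail; and a baseline prevalence of
$\mathrm{logit}^{-1}(-3) \approx 0.047$ with $\sigma_{\mathrm{phylo}} = 0.5$
(OU $\alpha = 2$), so most simulated prevalences sit below 0.2 as in the
real registries. It does **not** emulate: cause-of-death censoring
(Kaplan–Meier-based incidence), cross-registry heterogeneity, diagnostic
effort differences, domestication effects, or taxonomic subgroup structure.
A green recovery test therefore establishes that the estimator works when
its assumptions hold — not that any particular biological conclusion from
the real registries is robust to those unmodelled features.

## Known limitations

* Random-walk MCMC needs long runs to pass the strict ESS gate (above).
* OU-vs-λ discrimination is weak at a few dozen species with low counts;
  the package reports WAIC deltas honestly rather than forcing a winner.
* Consensus-tree construction, covariate curation, and the earlier two-step
  zero-inflated modelling tradition are out of scope; a single ultrametric
  Newick tree and a count CSV are the interface.
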