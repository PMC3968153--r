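---
title: "Variance-component likelihood-ratio tests for rare-variant sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component likelihood-ratio tests for rare-variant sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rvlrt` tests whether a pre-specified set of rare variants (a gene, a
regulatory region) is collectively associated with a continuous
phenotype. For sample $i$ with phenotype $y_i$, covariates $x_i$ and
minor-allele dosages $G_i = (g_{i1}, \dots, g_{im})$, the weighted
mixed-effects model is

$$ y_i = \beta_0 + x_i^\top \beta + G_i^\top \gamma + \varepsilon_i,
   \qquad \gamma_j \sim N(0, \tau w_j^2), \qquad
   \varepsilon_i \sim N(0, \sigma^2), $$

where $w_j$ is a per-variant weight. The set-level null hypothesis is
$H_0: \tau = 0$, equivalently $\lambda = \tau/\sigma^2 = 0$. Unlike the
score-based SKAT family, the likelihood-ratio approach also *estimates*
$\lambda$, and $\hat\lambda/(1+\hat\lambda) = \hat\tau/(\hat\tau +
\hat\sigma^2)$ is a set-level heritability: a comparable effect-size
measure across genes, which a p-value alone cannot provide.

The same model has a kernel-machine reading: with
$K = G\,\mathrm{diag}(w_j^2)\,G^\top$ the weighted linear kernel, the
genetic term is a random effect $h \sim N(0, \tau K)$ on the samples.
The two formulations share every nonzero eigenvalue of their covariance
factors and are exactly equivalent for this kernel; `rvlrt` implements
both (`LRT.M`/`ReLRT.M` via the $m \times m$ route, `LRT.K`/`ReLRT.K`
via the $n \times n$ kernel route) and its test suite asserts their
agreement to $10^{-6}$. Other kernels (IBS, Gaussian, polynomial) are
available behind the same interface but are flagged experimental: only
the weighted linear kernel participates in the validated equivalences.

## Weights

Weights follow the Beta(1, 25) density at the variant's MAF,
$w_j \propto (1-\text{MAF}_j)^{24}$, so rarer variants are up-weighted.
Raw Beta weights can be numerically awkward in variance-component
software, so they are rescaled by their maximum, per tested set, after
the rare filter (`max(scaled) = 1`). Per-set scaling changes the scale
on which $\lambda$ lives, so $\hat\lambda$ values are comparable across
sets only under the same scaling convention; the output records the
convention for this reason.

## The boundary problem and the exact simulated null

Under $H_0$, $\lambda = 0$ lies on the boundary of $[0, \infty)$, so
the LRT statistic $\mathrm{LRT}_n = 2[\sup_{\lambda \ge 0}
\ell(\lambda) - \ell(0)]$ is *not* asymptotically $\chi^2_1$. The
classical repair—a 50:50 mixture of a point mass at zero and
$\chi^2_1$—is known to be conservative in finite samples: the exact
null places substantially more than half its mass at zero (about 0.7
for a single variant) and has lighter tails than $\chi^2_1$. `rvlrt`
therefore simulates the exact finite-sample null from the spectral
representation: with $\xi_j$ the eigenvalues of
$W^{1/2}G^\top G W^{1/2}$ (resp. $K$), $\mu_j$ the eigenvalues of
$W^{1/2}G^\top P_0 G W^{1/2}$ (resp. $K^{1/2}P_0K^{1/2}$), $P_0$ the
residual projector off the fixed-effects design, and $u_j$ iid standard
normals,

$$ N(\lambda) = \sum_j \frac{\lambda\mu_j}{1+\lambda\mu_j}u_j^2,\quad
   D(\lambda) = \sum_j \frac{u_j^2}{1+\lambda\mu_j}
              + \sum_{j > K}u_j^2, $$

$$ \mathrm{LRT}(\lambda) = n\log\!\Big(1+\frac{N}{D}\Big)
   - \sum_j \log(1+\lambda\xi_j), \qquad
   \mathrm{ReLRT}(\lambda) = (n-p)\log\!\Big(1+\frac{N}{D}\Big)
   - \sum_j \log(1+\lambda\mu_j), $$

and each simulated replicate is $\max(0, \sup_\lambda \cdot)$. The
p-value is the add-one tail proportion of the observed statistic in the
simulated sample. The suite cross-checks the simulated null against a
brute-force null (repeatedly generating null data and maximising the
profile likelihood): the two agree in distribution, including the point
mass at zero.

The REML variant (ReLRT) profiles the restricted likelihood built from
error contrasts; it removes the downward bias of the ML residual
variance and is the variant with slightly higher power in practice.

## Numerical choices

* **Search grid.** $\sup_\lambda$ is taken over $\{0\} \cup$ an
  81-point logarithmic grid on $[10^{-4}, 10^4]$, followed by
  golden-section refinement (tolerance $10^{-4}$ on $\log\lambda$).
  The *same* grid and refinement are used for the observed statistic
  and for every simulated null replicate, so both share whatever
  residual maximisation bias remains and the simulated null is exact
  for the statistic as implemented. If the grid maximum sits at the
  upper boundary a warning is raised.
* **Observed statistic.** Computed from the data-dependent profile
  likelihood (through a one-off eigenfactorisation of the genetic
  covariance, $O(n(p{+}1))$ per candidate $\lambda$), not by plugging
  data into the spectral form, which is a distributional identity only.
  The test suite checks the observed statistics against a dense-matrix
  generic-optimiser ML/REML oracle to $10^{-5}$.
* **Eigenvalue truncation.** Eigenvalues below
  $10^{-10}\max(\xi)$ are dropped; rank deficiency (collinear variants,
  $m > n$) otherwise injects $\log(1+\lambda\epsilon)$ noise into the
  null. The tail sum $\sum_{j>K}u_j^2$ is drawn as a single
  $\chi^2_{n-p-K}$ deviate, which is distributionally identical to
  summing individual normals.
* **Degenerate inputs.** A zero kernel or an empty rare set raises a
  typed "not testable" condition which the set-level pipeline converts
  into an `NA` row rather than an error. $\hat\lambda = 0$ and
  statistic $= 0$ are linked by construction, and the p-value floor is
  $1/(n_\text{sims}+1)$.
* **Score-test p-values.** Burden/SKAT p-values invert the
  characteristic function of the fitted $\sum_j c_j \chi^2_1$ mixture
  (Imhof's integral, tolerance ladder $10^{-10} \to 10^{-6}$), with
  exact chi-square tails for degenerate (single or equal weight)
  mixtures and a four-moment (Liu) fallback if the oscillatory
  quadrature fails; the fallback is logged. SKAT-O minimises the
  fixed-$\rho$ p-value over the squared-decile grid
  $\{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ and calibrates the
  minimum by Monte Carlo under the fitted null, using Liu p-values on
  both sides of the comparison so it is like-with-like. The analytic
  one-dimensional-integration p-value of Lee et al. is deliberately not
  implemented: SKAT-O is a comparator here, and the Monte-Carlo route
  is exact in the limit and oracle-checkable.

## The synthetic-data generator

The generator emulates the study design the tests were validated under,
without wrapping a coalescent simulator:

* site MAFs from a truncated power-law spectrum (density
  $\propto \text{maf}^{-\alpha}$ on $[5\times10^{-4}, 0.01]$;
  $\alpha = 1$, the neutral $1/x$ spectrum, by default);
* a pool of 1000 haplotypes carrying independent sites at those
  frequencies; individuals are random haplotype pairs, so carriers
  share haplotypes but sites are uncorrelated in expectation;
* covariates $x_1 \sim N(0,1)$ and $x_2 \sim \mathrm{Bernoulli}(0.5)$,
  entering the phenotype with coefficients $(0.5, 0.5)$ and unit
  Gaussian noise (type-I error is invariant to these since all tests
  adjust for the covariates; the values are fixed once in the config);
* under the alternative, 30% of rare variants are causal with
  $|\gamma_j| = 0.3\,|\log_{10}\text{MAF}_j|$ (1.2 at MAF $10^{-4}$,
  0.6 at MAF $10^{-2}$), and 0/30/50% of the causal effects are
  negated;
* for variance-ratio recovery checks, an alternative regime draws
  $\gamma_j \sim N(0, \lambda_\text{true}\sigma^2 w_j^2)$, the model's
  own generative law.

Sample sizes 300/400/500 carry 41/47/51 rare variants respectively,
matching the reference study's realised counts; variants that come out
monomorphic in the sampled cohort (or reach the MAF ceiling) are
redrawn, which means the smallest usable cohort at the default ceiling
is $n = 100$ (below that no polymorphic site can have realised MAF
below 0.01).

**What the surrogate does and does not show.** Because sites are
independent, there is no linkage disequilibrium. Type-I error is
insensitive to LD, so the calibration results transfer to real data.
Power comparisons are qualitative: the burden test's collapse under
sign-mixed effects (it loses most power, with SKAT-O next) reproduces
well, but the moderate power losses that sign-*invariant* tests (SKAT,
LRT, ReLRT) show on coalescent genotypes are an LD effect and are close
to zero under the surrogate — without cross-variant correlation, sign
flips leave their noncentrality essentially unchanged. The harness
documentation and acceptance checks state this explicitly rather than
tuning the generator toward numbers it cannot honestly produce.

## Study harness

`run_type1_study()` / `run_power_study()` reproduce the reference study
layout: per cell, fresh genotypes each replicate (a config flag allows
a fixed panel instead — the reference design is ambiguous on this),
null or alternative phenotypes, and empirical rejection rates with
binomial intervals. Defaults are 2000 null replicates, 1000 power
replicates, and 2000 null simulations per (Re)LRT p-value (p-value
floor $5\times10^{-4}$, adequate for $\alpha \ge 0.01$; per-set
analyses default to 10000). One root seed drives everything through a
documented counter scheme (`child_seed()`), so serial and parallel runs
produce identical tables. The acceptance checks in the test suite run
the type-I cells at full scale (2000 replicates) and the power cells at
300 replicates per cell; those sizes keep the whole suite's Monte-Carlo
error well inside the asserted bands.

## Known limitations

* Continuous phenotypes only; no binary traits, no kinship/relatedness.
* One variance component; no multiple-region joint models.
* Non-linear kernels are plumbed but not validated against the
  mixed-model route (no such equivalence exists off the linear kernel).
* The conservative 50:50 mixture p-value is available only as the
  cross-check utility `chibarsq_pvalue()`, never as a default.
* Per-set max-scaling of weights means $\hat\lambda$ comparisons
  across sets assume the same scaling convention.
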