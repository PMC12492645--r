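---
title: "Genome-level gene-environment interaction from summary statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-level gene-environment interaction from summary statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-variant interaction scans (GWIS) are underpowered because each
SNP-by-environment effect is tiny. `gxeldr` instead targets two
*genome-level* quantities from summary statistics alone:

* the **G×E interaction proportion** $h_I^2$ — the share of phenotypic
  variance explained by SNP-by-environment interaction effects, and
* the **G×E genetic covariance** $\rho_{IG}$ — the covariance between
  per-SNP additive effects and per-SNP interaction effects, with the
  corresponding correlation $r_{IG} = \rho_{IG} / \sqrt{h_g^2 h_I^2}$.

Because additive signal ($h_g^2$) is usually much stronger than
interaction signal, $\rho_{IG}$ can carry more detectable evidence of
interaction than $h_I^2$ itself whenever $r_{IG} \neq 0$. The package
therefore estimates both and combines them in a joint test.

## Model

For standardized phenotype $Y$, standardized environment $E$ and
standardized genotypes $G_{ji}$ ($j = 1, \dots, M$ variants):

$$Y_i = \sum_j G_{ji} \beta_j + \sum_j G_{ji} E_i \gamma_j
        + \epsilon_{1i} E_i + \epsilon_{0i},$$

with polygenic random effects

$$\begin{pmatrix}\beta_j\\ \gamma_j\end{pmatrix} \sim N\!\left(0,\;
\frac{1}{M}\begin{pmatrix} h_g^2 & \rho_{IG}\\ \rho_{IG} & h_I^2
\end{pmatrix}\right),$$

and a bivariate residual $(\epsilon_0, \epsilon_1)$ with variances
$(\sigma_0^2, \sigma_1^2)$ and covariance $\rho_{01}$; $\epsilon_1 E$ is
a non-genetic residual interaction.

## Moment conditions on whitened Z-scores

Let $R$ be the LD (correlation) matrix of a genomic block, with
eigen-decomposition $R = U D U^{\mathsf T}$. GWAS and GWIS Z-score
vectors are whitened per block,
$\tilde{Z} = D^{-1/2} U^{\mathsf T} Z$, which decorrelates the summary
statistics and preserves *all* of the block's LD information — not just
the diagonal of $R^2$ that LD-score-based methods use. Per retained
eigencomponent $j$ with eigenvalue $D_{jj}$:

$$
\begin{aligned}
E[\tilde{Z}_{G,j}^2] &= \tfrac{N_G h_g^2}{M} D_{jj} + 1,\\
E[\tilde{Z}_{I,j}^2] &= \tfrac{N_I h_I^2}{M} D_{jj} + 1 +
  2(h_I^2 + \sigma_1^2),\\
E[\tilde{Z}_{G,j}\tilde{Z}_{I,j}] &=
  \tfrac{\sqrt{N_G N_I}\,\rho_{IG}}{M} D_{jj} +
  \tfrac{2 N_S(\rho_{IG} + \rho_{01})}{\sqrt{N_G N_I}}.
\end{aligned}
$$

Each parameter is the slope of a weighted regression of a per-component
product on the eigenvalue. The intercepts are always fitted freely: the
cross-product intercept absorbs the sample overlap $N_S$ and residual
covariance, so GWAS and GWIS cohorts may be identical, disjoint, or
anything in between without biasing $\rho_{IG}$; $\sigma_1^2$ is
identified from the GWIS chi-square intercept given $h_I^2$ (both slope
and intercept contain $h_I^2$, which is why the package solves for
$\sigma_1^2$ explicitly after the slope fit).

**Weights.** The optimal weight for the cross regression is
$w_j = \min(D_{jj}, 1) / T_{jj}$, where $T_{jj}$ is the product of the
two marginal variance factors plus the squared fitted mean — the
variance of a product of correlated Gaussians. The $\min(D_{jj},1)$
shrink tempers high-eigenvalue components, which carry large signal but
also large noise. Because $T_{jj}$ depends on $\rho_{IG}$ and the
intercept, the fit is iteratively reweighted (IRLS), initialized at
zero, with $h_g^2$, $h_I^2$ and $\sigma_1^2$ held fixed at their
pre-estimated values (they enter only through weights, where plug-in
error is second-order; variance plug-ins are clipped at zero *inside
the weights only* — reported estimates are never truncated, since
truncation would bias the jackknife downstream). The chi-square
regressions for $h_g^2$ and $h_I^2$ use the analogous
$\min(D,1)/f^2$ weights with their own marginal factors, refreshed over
`n_iter = 3` passes. IRLS defaults: `max_iter = 10`, `rtol = 1e-6`;
convergence is typically reached in 3–5 iterations because the weights
depend on $\rho_{IG}$ only weakly.

**Diagonal baseline.** For efficiency comparisons the package ships the
LD-score-style comparator: per-variant products $Z_G Z_I$ regressed on
LD scores $\ell_j = (R^{\mathsf T} R)_{jj}$ with the conventional
$1/\max(\ell_j, 1)$ shrink times the same inverse-variance factor, and
the same IRLS scheme. Under identity LD both estimators face literally
the same (degenerate) regression problem; with real LD the whitened
regression uses strictly more information.

## Inference

**Delete-block jackknife.** Blocks are assigned, in genome order, to
`min(200, number of blocks)` contiguous groups; the *entire* estimation
chain is re-run with each group deleted, giving the covariance
$\hat\Sigma$ of $(\hat h_I^2, \hat\rho_{IG})$ and SEs for all
parameters. Contiguity preserves any residual adjacency structure.

**Tests.** The univariate tests are two-sided Wald tests (moment
estimates of variance components can legitimately be negative, so
two-sided is the honest default; one-sided alternatives are exposed by
flag). The joint test is the squared Mahalanobis distance
$\hat d^2 = \hat V^{\mathsf T} \hat\Sigma^{-1} \hat V$ of
$\hat V = (\hat h_I^2, \hat\rho_{IG})$ from the origin.

With many blocks the natural references are the normal and
$\chi^2_2$ distributions. With few jackknife groups $G$ those are
anticonservative, so the default `"finite"` method uses $t_{G-1}$ for
the Wald tests and the Hotelling-type
$\hat d^2 (G-2) / (2(G-1)) \sim F(2, G-2)$ for the joint test; both
converge to the asymptotic references as $G$ grows.

Even those references are imperfect at very small $G$: the $h_I^2$
slope is a linear contrast of chi-square-distributed products, so its
t-statistic is left-skewed, and first-order skewness corrections are
inaccurate in the tails. The package therefore provides
`null_calibration()`: under the global null the whitened GWIS
components are i.i.d. Gaussian with a variance that cancels from every
test statistic, so the *exact* finite-sample null distribution of all
three statistics depends only on the eigenvalue design, the block
structure and the (insensitive) GWAS nuisance profile, and can be
simulated once per LD design. P-values read off this reference are
exact up to Monte-Carlo error. Recommendation: use the calibrated
reference below a few dozen blocks; at biobank-scale block counts
(hundreds of blocks) all three references agree and the asymptotic one
is cheapest.

## Heritable-environment confounding

If $E$ is itself heritable, $E_i = \sum_j G_{ji}\alpha_j + \epsilon_2$,
with $\rho_{GE} = M\,\mathrm{cov}(\beta_j, \alpha_j)$ and
$\rho_{IE} = M\,\mathrm{cov}(\gamma_j, \alpha_j)$, the GWIS statistics
absorb part of $E$'s genetic signal and the plain estimates are biased.
With an additional GWAS of $E$ (sample size $N_E$), the whitened-product
slopes become

$$
\begin{aligned}
E[\tilde{Z}_{E,j}^2] &= \tfrac{N_E h_E^2}{M} D_{jj} + 1,\\
E[\tilde{Z}_{E,j}\tilde{Z}_{I,j}] &=
  \tfrac{\sqrt{N_E N_I}\,\rho_{IE}(1 + h_E^2)}{M} D_{jj} + c_1,\\
E[\tilde{Z}_{I,j}^2] &= \tfrac{N_I (h_I^2 + 2\rho_{IE}^2)}{M} D_{jj} + c_2,\\
E[\tilde{Z}_{G,j}\tilde{Z}_{E,j}] &=
  \tfrac{\sqrt{N_G N_E}\,\rho_{GE}}{M} D_{jj} + c_{ge},\\
E[\tilde{Z}_{G,j}\tilde{Z}_{I,j}] &=
  \tfrac{\sqrt{N_G N_I}\,(\rho_{IG} + \rho_{GE}\rho_{IE})}{M} D_{jj} + c_3,
\end{aligned}
$$

inverted in the order $h_E^2 \to \rho_{IE} \to h_I^2 \to \rho_{GE}
\to \rho_{IG}$, with the weight plug-ins refreshed over `passes = 3`
passes of the whole chain (the estimates themselves stabilize after the
first pass; the passes only sharpen weights). Before freezing these
slope factors we verified each of them against direct simulation from
the generative model — whitened-product slope averages over replicated
studies match $\rho_{IE}(1+h_E^2)$, $h_I^2 + 2\rho_{IE}^2$ and
$\rho_{IG} + \rho_{GE}\rho_{IE}$ within Monte-Carlo error, and the
noise-free inversion identity is covered by the unit tests. The
cross-trait $\rho_{GE}$ condition takes the standard genetic-covariance
form; its intercepts, like $c_1$–$c_3$, are fitted freely because total
sample overlap is the common case.

Two structural consequences are worth noting. The corrected
$h_I^2$ subtracts $2\hat\rho_{IE}^2 \ge 0$, so it can never exceed the
uncorrected value. And under the global null of no interaction,
$\rho_{IE} = 0$ by construction, so the correction cannot inflate the
type-I error of any of the tests. The confounding test itself is the
two-sided Wald test of $\rho_{IE}$.

The jackknife for corrected quantities deletes each group once and
re-runs the entire correction chain per deletion, so the reported
covariance reflects every estimation stage.

## The simulation engine

The generator emulates the data-generating process end to end:
block-diagonal LD genotypes, correlated effect sizes on a sparse causal
subset, phenotype and environment construction, and in-process per-SNP
least-squares scans (vectorized closed forms, verified against `lm()`
in the tests; the GWIS regression is `y ~ g + e + g:e` with the
interaction t-statistic taken as the Z-score).

Reference desk-scale design, used by the test suite and the acceptance
script: $n = 2{,}000$ subjects, $M = 1{,}000$ variants in 10 LD blocks
of 100, 5% causal variants, 500 replications for test-size experiments
and 200 paired replications per cell for efficiency experiments. These
sizes keep a full study (simulate, scan, whiten, estimate, jackknife)
around 50–100 ms so that replicated grids are cheap, while leaving
enough signal per scan that the estimators operate away from degenerate
regimes.

Design choices and what they emulate:

* **LD profile.** Within each block the adjacent-variant correlation
  follows a non-stationary AR(1) ramp from 0.2 up to 0.9 and back
  (`ld_decay = c(0.2, 0.9)`), emulating the genome's alternation of
  weak- and strong-LD regions. This gives every block the same mixed
  eigenvalue spectrum and substantial variant-to-variant LD-score
  variation. Two degenerate alternatives were rejected deliberately: a
  homogeneous AR(1) profile makes within-block LD scores nearly
  constant, which collapses the diagonal-LD baseline toward its
  degenerate identity-LD case and makes any efficiency comparison
  meaningless; concentrating all strong LD in a few blocks puts most of
  the regression information into one or two jackknife groups, which no
  genome-wide analysis with ~1,000 blocks would exhibit.
* **Genotypes** are correlated Gaussians standardized per column (all
  estimators operate on standardized-genotype moments); a
  binomial-dosage mode (latent-Gaussian thresholding, MAF uniform on
  0.05–0.5) exists for realism checks.
* **Causal scaling.** Causal effects get variance $h^2/M_0$ on the
  $M_0$ causal variants so realized variance matches the nominal
  target; marginally each variant still has variance $h^2/M$, which is
  what the estimators assume. The alternative `scale_by = "all"`
  (variance $h^2/M$ on causal variants only, realized $h^2 M_0/M$) is a
  config switch.
* **Panel reuse.** Within a replicated scenario the genotype panel (and
  hence the in-sample LD reference) is drawn once and reused; effects,
  environment and noise are redrawn per replication. This mirrors an
  association study with a fixed panel and makes replications cheap.
  Estimates are conditionally unbiased given a panel up to small
  panel-specific wobble that averages out over panels.
* **Confounded scenarios** fix $h_g^2 = h_E^2 = 0.3$, $r_{GE} = 0.5$,
  vary $h_I^2 \in \{0.03, 0.05\}$ and $r_{IE} \in \{0.3, 0.5\}$, and
  set $r_{IG} = 0.3$ (a mid-grid value; the implied 3×3 effect
  correlation matrix must be positive semi-definite, which
  `sim_config()` checks).
* **Determinism.** One master seed; scenario and replication child
  seeds are derived deterministically, so any single replication can be
  reproduced in isolation.

What the generator does **not** emulate: real LD panels and their MAF
spectrum, covariate adjustment (age, sex, principal components), binary
phenotypes, rare variants, or reference/target ancestry mismatch.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions and the claimed efficiency ordering under
block LD — not robustness to the full messiness of biobank data.

A scale caveat for efficiency numbers: at the desk-scale design the
per-variant signal $N h^2 / M$ is roughly 40 times larger than in a
biobank-scale analysis, which pushes the product regressions into a
signal-dominated regime where whitening helps more. The SD reduction of
the eigen estimator over the diagonal baseline measured at desk scale
(high 30s of percent on the default grid) is therefore expected to
overstate the reduction a full-scale analysis would see.

## Numerical choices and degenerate inputs

* Eigenvalue truncation: components with $D_{jj} \le 10^{-6} \max(D)$
  are dropped — $D^{-1/2}$ explodes on near-null components. With
  `tol = 0` the reconstruction $U D U^{\mathsf T} = R$ is exact to
  1e-8.
* Eigenvector signs are fixed (largest-magnitude element positive) so
  output is reproducible across linear-algebra backends.
* A regression with a constant regressor (identity LD, or all
  eigenvalues equal) raises a degenerate-design error rather than
  returning an arbitrary slope.
* Strand-ambiguous variants (A/T, C/G) are removed during
  harmonization: allele frequencies are not guaranteed in the schema,
  so frequency-based resolution is not attempted. Per-variant sample
  sizes are summarized to a scan-wide scalar by the median, since the
  moment conditions use scalar sample sizes.
* Positions are 1-based throughout; variants match by ID plus allele
  pair, with position carried as metadata.
* The joint test refuses a (near-)singular $\hat\Sigma$
  (`rcond < 1e-12`) and suggests more jackknife groups.

## Known limitations

Annotation-stratified (partitioned) analyses, multi-environment joint
fits, binary phenotypes and rare variants are out of scope. The joint
test reports only a p-value — when it is significant, the univariate
estimates give the interpretable magnitudes. Departures from Gaussian
effect sizes (strong sparsity) reduce efficiency and can bias
magnitude estimates, though null calibration is unaffected because all
interaction terms vanish under the null.
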