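---
title: "Separation-robust GEE: penalized and augmented estimation for clustered binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separation-robust GEE: penalized and augmented estimation for clustered binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firthgee)
```

## The problem

Marginal logistic regression on clustered binary data — patients contributing
several observations, study centres enrolling several patients — is usually
fitted by generalized estimating equations (GEE). When the data are
*separable* (some linear combination of covariates perfectly discriminates
events from non-events, typically because of a rare binary covariate, a low
event rate or a small sample), the maximum-likelihood logistic score has no
finite root, and GEE solvers inherit the pathology: coefficients drift off to
infinity, or the working-correlation estimate leaves its admissible range.
Separation is sufficient but not necessary for GEE non-convergence, so any
remedy can reduce, not abolish, the problem.

For independent data the established remedy is Firth's logistic regression
(FL): penalizing the likelihood by the Jeffreys prior $|I(\beta)|^{1/2}$
yields finite, bias-reduced estimates and is invariant under invertible
linear reparameterization. This package transfers FL to GEE in the three
ways studied in the recent methodological literature, plus ordinary GEE as
the baseline:

* **`fit_gee()`** — ordinary GEE, Fisher scoring alternated with a moment
  update of the correlation parameter $\alpha$;
* **`fit_pengee()`** — *penalized GEE*: the estimating function
  $U(\beta,\alpha)$ is modified in the manner of Firth,
  $U^*(\beta,\alpha) = U + \tfrac12\,\mathrm{trace}\!\big(I^{-1}\,
  \partial I/\partial\beta_m\big)$, one trace term per coefficient, with
  $I(\beta,\alpha)=\sum_i X_i'\Omega_i X_i$ and
  $\Omega_i = W_i^{1/2}R_i(\alpha)^{-1}W_i^{1/2}$;
* **`fit_auggee()`** — *iterated augmented GEE*: the FL equivalence with an
  augmented weighted dataset is generalized to clusters. At the current
  $(\beta,\alpha)$ the leverage blocks
  $H_i=\Omega_i^{1/2}X_i\big(\sum_j X_j'\Omega_j X_j\big)^{-1}X_i'\Omega_i^{1/2}$
  give per-observation weights $h_{ij}$; two pseudo clusters per original
  cluster carry the covariates with weights $h/2$, once with the observed and
  once with the flipped outcome, and weighted GEE is re-solved on the
  $3N$-cluster pseudo-data until the outer iteration stabilizes;
* **`fit_auggee1()`** — *single-step augmented GEE*: one FL fit, one
  augmentation with the ordinary FL hat diagonals, one weighted GEE solve
  warm-started at the FL estimate. With an independent working structure it
  *is* FL, so it always returns finite estimates and serves as the fallback
  estimator in the simulation harness.

All four reduce to (penalized) logistic regression under the independent
working structure; the three modified estimators coincide with FL there,
which the test suite verifies on randomized fixtures.

## Model and estimating equations

With clusters $i=1,\dots,N$ of sizes $n_i$, outcomes
$y_{ij}\in\{0,1\}$ and covariate rows $x_{ij}$ (leading 1 for the
intercept), the marginal model is
$P(Y_{ij}=1\mid x_{ij}) = \pi_{ij} = \operatorname{expit}(x_{ij}\beta)$, and
$\beta$ solves
$$\sum_{i=1}^N X_i' W_i \big(W_i^{1/2}R_i(\alpha)W_i^{1/2}\big)^{-1}(y_i-\pi_i) = 0,$$
with $W_i=\operatorname{diag}(\pi_{ij}(1-\pi_{ij}))$ and working correlation
$R_i(\alpha)$ (independent, exchangeable, AR(1) or unstructured). The scale
parameter is fixed at 1. $\alpha$ is estimated by the moment formula: for the
exchangeable structure, the mean over clusters (with $n_i\ge2$) of
$\frac{1}{n_i(n_i-1)}\sum_{j\ne k}\hat e_{ij}\hat e_{ik}$, with Pearson
residuals $\hat e_{ij}=(y_{ij}-\hat\pi_{ij})/\sqrt{\hat\pi_{ij}(1-\hat\pi_{ij})}$.
AR(1) uses lag-one products and the unstructured form per-pair means over the
clusters providing that pair.

### Scale weights

Per-observation weights are *scale factors* (the PROC GEE / geem2 dialect):
with $Q_i=\operatorname{diag}(w_{ij})$ the working covariance is
$V_i=\Delta_i^{1/2}Q_i^{-1/2}R_iQ_i^{-1/2}\Delta_i^{1/2}$, algebraically the
same as folding the weights into $W_i$ and rescaling the residual, so the
independent-structure score is the *weighted* logistic score. In the
$\alpha$ estimator the residuals carry $\sqrt{w_{ij}}$ while the pair-count
denominator stays unweighted; at unit weights this is exactly the printed
formula, and on augmented data it damps the pseudo observations by their
$h/2$ weights. (A fully weight-normalized denominator is *not* used: flipped
pseudo observations have Pearson residuals of order $1/\sqrt{\pi}$, and
normalizing by their own small weights lets single pseudo clusters produce
correlation estimates far outside $(-1,1)$.) This damping is a dialect
choice: it attenuates the augmented-data $\alpha$ estimate relative to the
original-data one, which costs the augmented estimators a little efficiency
when the true correlation is strong but keeps their convergence behaviour
stable.

### Solver organization and convergence rules

One Newton step per outer iteration, alternating with the $\alpha$ update.
`fit_gee()` uses the freshly updated $\alpha$ in each step and starts from
the (possibly unconverged) ML logistic fit; `fit_pengee()` follows the
published 4-step algorithm literally, which evaluates the step at the
*previous* iteration's $\alpha$, and starts from FL with an identity working
correlation. Both declare convergence when $\max_m|\hat\beta^{k+1}_m -
\hat\beta^k_m| < 10^{-3}$, within 30 (ordinary; the iteration cap for
stand-alone GEE is not pinned down by the reference algorithms, and 30 is
used everywhere for comparability) or 20 (penalized) iterations. The
augmented algorithms cap inner weighted-GEE solves at 30 iterations and the
outer loop at 20, warm-starting each inner solve at the previous estimate;
the iterated algorithm is declared non-convergent if *any* inner solve
fails its criterion — its first inner solve is identical to the single-step
fit (the generalized hat at $\alpha=0$ is the ordinary hat), which is what
makes single-step non-convergence provably no higher than iterated.
A fit is also flagged non-convergent when $\hat\alpha$ leaves $(-1,1)$
(never silently clipped) or on any numerical failure; fitting functions
return a flagged object rather than throwing.

Firth's logistic regression itself uses Newton–Raphson on the modified score
with step-halving (up to 5 halvings when the penalized log-likelihood would
decrease), tolerance $10^{-6}$ on the maximal coefficient change, 50
iterations.

### Numerical choices

* Linear predictors are clamped at $|\eta|\le30$ so fitted probabilities stay
  strictly inside $(0,1)$; beyond that the working variance underflows.
* The exchangeable $R^{-1}$ uses its closed form
  $\frac{1}{1-\alpha}\big(I-\frac{\alpha}{1+(n-1)\alpha}J\big)$, and the
  whole estimating-function assembly is vectorized over clusters via grouped
  sums; AR(1)/unstructured go through per-cluster factorization.
* $\Omega_i^{1/2}$ in the generalized hat is the symmetric PSD square root
  (eigendecomposition). Any root reproduces the trace; the symmetric one
  keeps the diagonals in $[0,1]$ and reduces exactly to the ordinary
  weighted-logistic leverages under independence.
* The inner inverse of the hat blocks uses the whole-data information
  $\sum_j X_j'\Omega_j X_j$: this is the only reading of the block formula
  under which $\mathrm{trace}(H)=p+1$ holds, which the augmentation needs
  (total pseudo weight $p+1$).
* $\partial I/\partial\beta_m$ is analytic: only $W_i$ depends on $\beta$
  ($R_i$ held fixed during the $\beta$-step), giving
  $\partial\Omega_i/\partial\beta_m = \tfrac12(C_m\Omega_i+\Omega_iC_m)$ with
  $C_m=\operatorname{diag}((1-2\pi_{ij})x_{ijm})$; a finite-difference oracle
  backs this in the tests.
* An exchangeable $\hat\alpha\le -1/(n_{\max}-1)$ makes $R$ singular even
  inside $(-1,1)$; this raises the singular-correlation failure path and the
  fit is flagged, mirroring the correlation-approaching-singularity failure
  mode of GEE.

## Variance estimation

Reported covariances are the sandwich
$S=I_0^{-1}I_1I_0^{-1}$ ($I_0$ the model-based information, $I_1=\sum d_id_i'$
from the per-cluster scores) and the Morel small-sample correction
$$S^* = I_0^{-1}I_1^*I_0^{-1} + \delta\,\phi\, I_0^{-1},\qquad
I_1^* = \tfrac{N^*-1}{N^*-p-1}\,\tfrac{N}{N-1}\sum_i (d_i-\bar d)(d_i-\bar d)',$$
$\delta=\min\!\big(0.5,\tfrac{p+1}{N-p-1}\big)$,
$\phi=\max\!\big(1,\mathrm{trace}(\alpha\,I_0^{-1}I_1^*)/(p+1)\big)$.
For the unstructured working correlation the scalar $\alpha$ in $\phi$ is
replaced by the mean off-diagonal estimate (the printed formula presumes a
scalar; this substitution is the package's documented reading). Confidence
intervals are $\hat\beta_m \pm t_{N,\,0.975}\,\widehat{\mathrm{se}}_m$ with
exactly $N$ (not $N-p$) degrees of freedom. For the augmented estimators the
covariance is evaluated on the **original** data at the final
$(\hat\beta,\hat\alpha)$ — deliberately different from the sandwich of the
last augmented-data fit, and asserted so in the tests.

## Separation detection

`detect_separation()` decides separability exactly: data are
(quasi-)separable iff some nonzero $\gamma$ satisfies
$z_i x_i'\gamma\ge0$ for all $i$ (with $z_i=2y_i-1$), strictly somewhere.
By Stiemke's duality this holds iff
$\{\sum_i\lambda_i z_i x_i=0,\ \lambda\ge1\}$ is infeasible, which a compact
phase-1 simplex with Bland's anti-cycling rule settles in a few dozen
pivots on $(p+1)$ constraint rows; the phase-1 multipliers at a positive
optimum are returned as the separating direction. The simplex is implemented
in the package because the available general LP routines mishandle the fully
degenerate zero right-hand side this problem produces.

## The synthetic-data generator

`scenario_config()` / `generate_dataset()` emulate a factorial simulation
design for clustered binary data:

| parameter | values | meaning |
|---|---|---|
| `N` | 20 / 50 / 100 | clusters per dataset |
| `cluster_size` | small / moderate / large | truncated Poisson, mean 5/10/20 (untruncated parameter), range 1–10 / 1–20 / 1–40, by rejection |
| `latent_corr` | 0.7 / 0.9 | exchangeable correlation of the latent Gaussians |
| `event_rate` | 0.1 / 0.3 | marginal $P(Y=1)$, met by calibrating $\beta_0$ |
| `beta1` | 0.69 | slope of the main binary between-cluster covariate |

Covariates arise by transforming correlated standard normals
$Z_1,\dots,Z_5$ (common latent correlation 0.2): binaries of prevalence
0.5 / 0.3 / 0.2 (the first two cluster-constant, drawn at cluster level with
$Z_3..Z_5$ from their conditional distribution so the joint latent
correlation is exact), a quartile-binned 4-level ordinal coded 0–3, and
$X_5=\exp(Z_5/2)$ winsorized at $Q_1-3\,\mathrm{IQR}$ and
$Q_3+3\,\mathrm{IQR}$ with quartiles taken as transforms of the
standard-normal quartiles. The latent correlation, prevalences, and the
non-focal slopes $(-0.5, 0.5, 0.25, 0.25)$ are *reconstructions* of a
design whose exact covariate tables are not available to the package; they
were fixed once as realistic epidemiological defaults and are configurable.

Outcomes come from a latent-threshold (Gaussian copula) model:
$g_{ij}=\sqrt{\rho}\,b_i+\sqrt{1-\rho}\,\varepsilon_{ij}$ and
$Y_{ij}=\mathbf 1\{\Phi(g_{ij})<\operatorname{expit}(x_{ij}\beta)\}$, so the
marginal logit model holds *exactly* while $\rho$ controls the
within-cluster dependence. The achieved correlation of the *binary*
outcomes is smaller than $\rho$ and increases with the event rate;
`achieved_correlation()` measures it by the exchangeable moment estimator at
the true probabilities. The intercept is calibrated by root-finding on a
fixed Monte-Carlo covariate sample of $2\times10^5$ draws.

What the generator does **not** emulate: covariate measurement error,
informative cluster sizes, non-exchangeable dependence, or the particular
covariate distributions of any real study. Tests that pass on these
simulations demonstrate the estimators' behaviour under a correctly
specified marginal model with exchangeable latent dependence — not
robustness beyond it.

`make_dental_fixture()` provides a deterministic, fully synthetic stand-in
for a multi-implant dentistry study: 134 clusters, 533 observations, event
rate ≈ 0.05, and a rare cluster-constant binary covariate (24 observations)
whose carriers have no events, which makes the data quasi-completely
separable; ordinary GEE fails on it while the penalized and augmented fits
return finite coefficients.

## The evaluation harness

`run_scenario()` reproduces the study-style performance loop: generate,
check separation, fit, classify convergence, replace, accumulate. A fit
counts as non-convergent if the procedure itself failed, $\hat\alpha$ left
$(-1,1)$, or any *slope* lies more than 10 reference standard errors from
its true value — the reference scale being the sandwich at the true
coefficients and the true (achieved binary-scale) correlation, averaged over
the scenario's datasets. Non-convergent fits are replaced by single-step
augmented GEE with independent working structure for the accuracy measures.
Prediction RMSE averages per-dataset mean squared errors across datasets
*before* the square root. Datasets whose design is degenerate (e.g. a
between-cluster binary that never occurs in 20 clusters) are inestimable by
every method; they count toward convergence and separation proportions and
are dropped from accuracy measures.

Per-dataset seeds are drawn once from the scenario master seed, so results
are reproducible and independent of evaluation order.

## Problem sizes used by the shipped checks

The packaged test-suite runs the hardest scenario (20 clusters, small
sizes, latent correlation 0.9, event rate 0.1) at 500 datasets, the
achieved-correlation checks at $2\times10^4$ clusters, and the full
36-scenario factorial at 200 datasets per cell; `scripts/acceptance.R` uses
1000 datasets for the hardest scenario and $10^5$ clusters for the
correlation summaries. These sizes were chosen so the whole suite runs on a
single CPU in minutes while keeping binomial Monte-Carlo error near or
below one percentage point on the reported proportions.

## Known limitations

* Only the logit link and binary outcomes; no GEE2, no scale-parameter
  estimation.
* The moment estimator dialect on weighted (augmented) data is one of
  several defensible choices; alternatives shift the augmented estimators'
  correlation estimates and hence their non-convergence rates. Our inner
  solver converges noticeably more often than the reference pipeline the
  design emulates, so non-convergence proportions for the augmented methods
  land below published values, while the orderings between methods are
  preserved.
* The reconstructed covariate defaults shift separation-frequency summaries
  by a few percentage points relative to the published design.
* Formula interfaces, interactions and automatic contrasts are out of
  scope: covariates enter as pre-expanded numeric columns.
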