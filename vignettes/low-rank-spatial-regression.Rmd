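---
title: "Scalable Bayesian image-on-scalar regression: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalable Bayesian image-on-scalar regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsir)
```

## The model

Group-level neuroimaging analyses regress an image-valued response on
participant-level scalars.  For participant $i = 1, \dots, N$ and location
$s_v$, $v = 1, \dots, V$ (voxels of a masked volume or vertices of a
cortical surface, represented by their geometric coordinates), `bsir` fits

$$
y_i(s_v) \;=\; \sum_{j=0}^{J} x_{ij}\,\alpha_j
  \;+\; \sum_{j=0}^{J} x_{ij}\,\beta_j(s_v)
  \;+\; \eta_i(s_v) \;+\; \epsilon_i(s_v),
\qquad \epsilon_i \sim \mathrm{GP}(0, \sigma_\epsilon^2 K),
$$

with $x_{i0} \equiv 1$.  Each covariate contributes a global effect
$\alpha_j$ and a spatially varying effect $\beta_j(\cdot)$; $\eta_i(\cdot)$
is a participant-specific deviation field.  All three spatial components
share one Matérn correlation kernel $K$ with their own variances:
$\beta_j \sim \mathrm{GP}(0, \sigma_\beta^2 K)$,
$\eta_i \sim \mathrm{GP}(0, \sigma_\eta^2 K)$.  The standard deviations
$\sigma_\alpha, \sigma_\beta, \sigma_\eta, \sigma_\epsilon$ carry
half-Cauchy priors with scale $A = 100$, written as the usual
inverse-gamma mixture
($\sigma^2 \mid a \sim \mathrm{IG}(\tfrac12, 1/a)$,
$a \sim \mathrm{IG}(\tfrac12, 1/A^2)$) so every block stays conjugate.
The decomposition into global plus spatial parts is identified by
$\sum_i \eta_i(s_v) = 0$ and $\sum_v \beta_j(s_v) = 0$.

The quantity of scientific interest is the voxel-level effect
$\alpha_j + \beta_j(s_v)$, summarized by its posterior mean, credible
interval, the posterior probability of a positive effect $P_+$, and the
evidence measure $E_s = 2(P_+ - \tfrac12) \in [-1, 1]$.  Frequentist
baselines are mapped onto the same scale via $E_s = \pm(1 - p)$ with
BH-adjusted $p$-values, and a location is declared active when
$|E_s| > 0.95$ (a positive-only rule is also available).

## Low-rank kernel machinery

Dense GP inference costs $O(V^3)$ and is hopeless at $V \sim 10^4$–$10^5$.
`bsir` uses the Nyström method: $L \ll V$ inducing locations (k-means
centroids snapped to the mask by default — space-filling sets approximate
the kernel much better than uniform draws) give
$K_V \approx K_{V,L} K_L^{-1} K_{V,L}^\top$.  A Cholesky factor
$K_L = R R^\top$ and an SVD of $K_{V,L} R^{-\top}$ yield the spectral form
$K_V \approx \Psi \Lambda \Psi^\top$ with orthonormal $\Psi$.  Spatial
fields are then expanded in Karhunen–Loève form,
$\beta_j = \Psi \Lambda^{1/2} \theta_{\beta j}$ with iid normal
coefficients, and similarly $\eta_i = \tilde\Psi \tilde\Lambda^{1/2}
\theta_{\eta i}$ from a separate rank-$L_\eta$ decomposition (default
$L_\eta = \lceil 0.1 L \rceil$, a fraction that captures individual
variation without overfitting).

Projecting the images with $\Phi = \Psi \Lambda^{-1/2}$ whitens the GP
noise: with $\tilde y_i = y_i^\top \Phi$ the model becomes an
$L$-dimensional multivariate regression

$$
\tilde y_i = (x_i^\top \alpha)\, 1_V^\top \Phi + x_i^\top \theta_\beta
  + \theta_{\eta i}^\top \Phi_\eta + \tilde\epsilon_i,
\qquad \tilde\epsilon_i \sim N(0, \sigma_\epsilon^2 I_L),
$$

with $\Phi_\eta = \tilde\Lambda^{1/2} \tilde\Psi^\top \Psi \Lambda^{-1/2}$.
Everything downstream touches only $L$- and $L_\eta$-sized objects
($O(N L L_\eta + L_\eta^3)$ per sampler iteration).

Numerical choices: coordinates are affinely mapped into $[0,1]^d$ by the
largest axis extent (aspect preserved), making the length scale
unit-free; the inducing Gram matrix gets jitter $10^{-8}$, escalated
tenfold up to $10^{-4}$ before failing; eigenvalues below
$10^{-10}\lambda_1$ are trimmed; the Matérn smoothness defaults to
$\nu = 3/2$ (once-differentiable fields, closed form) and is
configurable.

## Inference engines

**Gibbs.**  Every block has a closed-form full conditional by conjugacy:
multivariate normal for $\alpha$, for each basis column of $\theta_\beta$
(one shared $(J{+}1)\times(J{+}1)$ precision — diagonal in the
intercept-only case), and for each $\theta_{\eta i}$ ($L_\eta \times
L_\eta$ precision shared across participants); inverse-gamma for the four
variances and auxiliaries.  The update cycle is $\alpha \to \theta_\beta
\to \theta_\eta \to$ variances $\to$ auxiliaries $\to$ recentering; the
order is a fixed convention.  Defaults are three chains overdispersed by
factors $\{0.5, 1, 2\}$ on the initial variances, 4000 burn-in and 1000
kept draws, convergence monitored by the Gelman–Rubin factor on the
conditional log-likelihood with the common 1.1 threshold.  Variances are
floored at $10^{-12}$.

The identifiability constraints are enforced by *exactly*
likelihood-invariant recentering after each iteration: participant means
of $\theta_\eta$ move into the intercept row of $\theta_\beta$ (through
$\Phi_\eta$), and $\delta_j = g^\top\theta_{\beta j} / g^\top h$ (with
$g = 1_V^\top \Psi \Lambda^{1/2}$, $h = 1_V^\top \Phi$) moves the voxel
mean of each reconstructed $\beta_j$ into $\alpha_j$.  Both shifts cancel
exactly in the projected mean, so the sampler's stationary law is
untouched; the constraints hold to machine precision on every kept draw.

**Variational inference.**  The mean-field family mirrors the Gibbs
blocks: Gaussian factors for $\alpha$, for each $\theta_\beta$ column
(shared covariance), and for each $\theta_{\eta i}$; inverse-gamma factors
for variances and auxiliaries, with $E[1/\sigma^2] = \text{shape}/\text{rate}$
closing the half-Cauchy hierarchy in closed form.  Coordinate ascent
sweeps the same order as the sampler and monitors the evidence lower
bound, which is computed in closed form and must not decrease; sweeps stop
when the relative ELBO change is below $10^{-8}$ (default, max 500
sweeps).  Two deliberate deviations from textbook behavior: variance-factor
rates are floored (at shape $\times 10^{-10}$) because degenerate inputs —
duplicated participants, for instance — otherwise drive the residual
variance factor to a fixed point at infinity where floating-point
cancellation breaks monotonicity; and recentering is applied *once at
convergence* rather than per sweep, because the recentering shift, while
likelihood-invariant, perturbs the prior terms of the objective and would
break the monotone-ELBO guarantee that the implementation asserts as a
hard invariant.  The combined effect $\alpha_j + \beta_j(s_v)$ is
essentially unaffected by where the recentering happens.

Mean-field factors underestimate posterior variances when blocks are
correlated (verified against dense two-block oracles in the test suite);
in practice the voxel-effect posterior means correlate $> 0.99$ with the
Gibbs means on simulated data, and coverage of the credible intervals is
conservative rather than anticonservative at the study's noise levels.

## Choosing the number of basis functions

$L$ trades smoothing bias against variance and computation.  Likelihoods
under different $L$ live on different projected spaces and are not
comparable, so information criteria are deliberately not offered.
Instead: an $L_{\max}$-point decomposition (default
$\min(V, 2000)$, set by available computation) gives an eigenvalue
spectrum; candidates are restricted to the window where cumulative
variance reaches 80–98% of that spectrum's total; within the window a
small grid (default 5 candidates) is scored by leave-one-participant-out
predictive mean squared error, fitting on $N-1$ participants (VI engine by
default) and predicting the held-out image from fixed effects alone.
Ties go to the smaller $L$.  The basis depends only on coordinates, so it
is built once per candidate and reused across folds.

## The synthetic-data generator

The generator reproduces the statistical structure of a slice-level
group study: a connected brain-slice-like 2-D mask of ~5000 voxels
(ellipse with sinusoidal boundary perturbation); sparse true effect maps
for intercept and one covariate, each two compact regions (a disk and a
rounded rectangle, one positive and one negative so maps are approximately
centered) with squared-cosine profiles decaying smoothly to *exactly* zero
at the region boundary and ~14.5% of voxels active per map; participant
deviations $\eta_i(s_v)$ iid standard normal; and GP noise drawn through a
rank-500 kernel representation (a dense-Cholesky option exists for small
domains and is used as the oracle in tests).  The signal is calibrated so
that $\mathrm{Var}_{i,v}(\beta_0(s_v) + x_i \beta_1(s_v)) / \sigma_\epsilon^2$
hits the target SNR; this definition makes the study's two noise levels
($\sigma_\epsilon = 2$ at SNR 0.3, $\sigma_\epsilon = 5$ at SNR 0.05)
consistent with a single fixed pair of truth maps, which is how the
scenarios are constructed.

Two generator choices deserve explanation.

*Length scale.*  Published simulation designs of this kind quote kernel
length scales in their own coordinate units.  In normalized $[0,1]^d$
coordinates — the convention used throughout this package — a Matérn(3/2)
scale of 0.3 on a ~5000-voxel slice concentrates 98% of the kernel
variance in ~26 eigenfunctions, far too few to represent localized
activation regions; basis-size selection then caps $L$ at a level where
estimates bleed far outside the true regions.  The generator therefore
defaults to $\rho = 0.1$ in normalized units, the scale at which the
80–98% window spans roughly 30–190 basis functions — the regime this
design is known to operate in, and the same normalized-units scale that
empirical pairwise-correlation estimation yields on dense volumetric
data.  `estimate_length_scale()` recovers the generating scale from
simulated data, closing the loop.

*Region profiles.*  The squared-cosine taper is $C^1$ at the region
boundary, and the exact zeros outside the regions are a hard feature: the
truth is deliberately *not* representable in any finite basis.  The
residual projection ripple this creates is visible in the evidence maps
(see Limitations).

What the generator does not emulate: hemodynamic response structure,
multi-site or scanner batch effects, realistic anatomy of activation
shapes, and spatially *smooth* participant deviations — $\eta$ is iid
across voxels by design even though the fitted model represents it in a
smooth low-rank basis.  This mismatch is intentional (it mirrors the
study design being emulated) and is why posterior predictive envelopes are
checked on well-specified data in the tests: under the mismatch the
replicate densities are visibly narrower than the observed ones.
Accordingly, passing tests demonstrate correct algorithms and calibrated
behavior *under this generator*, not validity for any particular real
dataset.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on ~300–600-voxel masks with $N \le 50$ and
$L \approx 40$–60, sizes at which dense oracles (full Gram eigendecompositions,
brute-force conjugate algebra, dense GP sampling) are exact and fast.  The
study-level script uses the full ~5000-voxel mask with 100 replicates for
the GLM-calibration quantities and 20 replicates for the spatial-model
quantities, with $L$ selected once by the window + LOOCV procedure
($L_{\max} = 1000$, five candidates) on an $N = 200$ dataset and reused
across replicates.  These sizes are the package's own reproducibility
choices.

## Known limitations

* **Evidence-threshold selection inflates FDR under unrepresentable
  truths.**  With $N = 200$ and truth maps that are exactly zero outside
  compact regions, the low-rank posterior concentrates on the *projected*
  truth, whose ripple outside the regions is small but nonzero; $|E_s| >
  0.95$ then flags a ring of near-boundary voxels, and the empirical FDR
  against the exact-zero set settles around 0.1–0.2 at the
  window-selected $L$ (it falls to ~0 when $L$ is pushed well past the
  98% window, where the ripple drops below the posterior noise floor).
  This is a structural property of evidence thresholding combined with
  basis truncation, not a sampler or CAVI defect; the test suite records
  it as a failing bound rather than masking it.
* Mean-field VI underestimates joint-posterior variances; interval
  conservatism at the study conditions comes from prior smoothing, not
  from calibrated uncertainty.
* The kernel (family, scale, smoothness) is fixed before fitting; no
  hyperparameter inference, geodesic surface distances, or nonstationary
  kernels.
* Covariates with missing values, and images with missing voxels, are
  rejected rather than imputed.
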