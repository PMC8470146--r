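---
title: "Generative modelling of the ipsilateral motor BOLD response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative modelling of the ipsilateral motor BOLD response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bolddcm)
```

## The scientific problem

Unilateral hand movements activate contralateral motor cortex, but they
also perturb the ipsilateral hemisphere. In young adults the ipsilateral
primary motor cortex (rM1, for a right-hand task) typically shows a
*negative* BOLD response that becomes progressively more positive with
age. Distinguishing whether that shift is neural (changed
inter-hemispheric effective connectivity) or vascular (changed
neurovascular coupling or venous haemodynamics) requires a generative
model that contains both ingredients and can be inverted from data.

`bolddcm` implements that analysis end to end for a six-region motor
network -- bilateral M1, dorsal premotor cortex (PMd) and SMA -- driven by
a cued audio/visual button-press task, together with a synthetic-cohort
generator so the entire pipeline is testable without access-restricted
data.

## The generative model

**Neural layer.** Activity $z \in \mathbb{R}^6$ follows linear dynamics
$\dot z = A^\top z + C u(t)$, where $A_{ij}$ (Hz) is the influence of
region $i$ on region $j$ (sources in rows -- the opposite of a common
convention, chosen because it reads naturally as "row source excites
column target"; all internal code follows it consistently) and $C$ routes
the three task conditions (audio+visual, audio-only, visual-only) into
regions. Self-connections must be inhibitory for stability and are
parameterised as $A_{jj} = -0.5\,\mathrm{Hz} \cdot e^{\lambda^A_j}$, so
any finite log-scaler yields a negative rate and $\lambda^A_j = 0$ gives
the default $-0.5$ Hz.

**Haemodynamic layer.** Each region runs a vasoactive-signal/balloon
cascade: $\dot s = z - \kappa s - \gamma (f - 1)$, $\dot f = s$,
$\tau_j \dot v = f - v^{1/\alpha}$ and
$\tau_j \dot q = f \, \frac{1-(1-E_0)^{1/f}}{E_0} - v^{1/\alpha} q / v$,
with $\kappa = 0.64\,\mathrm{Hz}\cdot e^{\lambda^\kappa}$ (one pooled
decay log-scaler) and $\tau_j = 2\,\mathrm{s}\cdot e^{\lambda^\tau_j}$
(per-region transit). The fixed balloon constants are $E_0 = 0.4$,
$\gamma = 0.32$ Hz and $\alpha = 0.32$; all are configurable in
`bold_constants()`.

**Observation.** The fractional BOLD change is
$y = V_0 (k_1 (1-q) + k_2(1-q/v) + k_3(1-v))$ with
$k_1 = 4.3\,\nu_0 E_0 \mathrm{TE}$, $k_2 = \epsilon r_0 E_0 \mathrm{TE}$,
$k_3 = 1-\epsilon$. The constants are set for 3 T: $\mathrm{TE}=30$ ms,
$V_0 = 4\%$, $r_0 = 110$ Hz, $\nu_0 = 28.265 \cdot B_0 \approx 84.8$ Hz,
and $\epsilon = 0.46$ fixed (not estimated) for stability.
`epsilon_prior_fit()` reproduces the derivation of that value by
evaluating $\epsilon = e^{-\mathrm{TE}/T_{2,i}^*} / e^{-\mathrm{TE}/T_{2,e}^*}$
over literature ranges of the relaxation times and fitting a lognormal;
the exact fitted location depends on the fitting criterion and grid
inclusivity, which the function exposes as options rather than
hard-coding the published rounding.

## Numerical choices

The coupled system is integrated at the microtime resolution of the
input indicator matrix (16 bins per TR by default; binary entries, one
bin per event). Haemodynamic states are propagated in log space so $f$,
$v$, $q$ remain positive by construction. The integrator is fixed-step
classical Runge-Kutta (RK4) at the bin width, with forward Euler
available for cross-checks; RK4 was made the default because the
step-halving reproducibility we require of the forward model (relative
change $< 10^{-4}$ when the step is halved) is met comfortably by RK4 at
0.125--0.25 s steps but not by Euler, whose first-order error at those
steps is of order $10^{-2}$. Predictions are sampled mid-scan
(configurable), and the state norm is monitored so that diverging
parameterisations raise an instability error naming the most extreme
parameters instead of returning garbage.

## Subject-level inversion

`dcm_fit()` is variational Laplace: a Gaussian posterior over the free
parameters is optimised by Gauss-Newton ascent on the free energy
$F = \langle \ln p(y \mid \theta) \rangle_q - \mathrm{KL}(q \Vert p)$,
with Levenberg-Marquardt damping; proposals that do not increase $F$ are
rejected and the damping raised, so the free-energy trace over accepted
iterations is non-decreasing by construction. Observation noise is
independent Gaussian per region with a log-precision hyperparameter
each, optimised by Newton steps within each iteration under a
$\mathcal{N}(h_0, 1)$ hyperprior centred on half the data variance. (An
early version used a nearly flat hyperprior of variance 16; with
noise-free data this lets the log-precision inflate indefinitely and
destabilises model comparison, so the tighter default was adopted.)
Priors follow the shrinkage convention of this model family: off-diagonal
$A \sim \mathcal{N}(0, 1/16)$, driving inputs $\mathcal{N}(0, 1)$,
self-connection log-scalers $\mathcal{N}(0, 1/16)$, haemodynamic
log-scalers $\mathcal{N}(0, 1/256)$, plus a per-region constant offset
$\mathcal{N}(0, 1/16)$ absorbing residual means. Parameters with exactly
zero prior variance are fixed: the two hypotheses about which hemisphere
drives the network (`m1`: lSMA+lPMd, `m2`: rSMA+rPMd) differ only in
which rows of $C$ are switched on.

Gradients of the forward model are finite differences (central, step
$10^{-4}$, the default chosen for robustness; a forward-difference mode
at half the cost is available and is used in the package's larger
simulation studies after checking it reproduces the same recovery
behaviour). Convergence is declared after four consecutive accepted
iterations changing $F$ by less than 0.01, capped at 128 iterations.
`dcm_reestimate()` re-runs the optimisation from an alternative start
(typically the group mean) and keeps whichever fit has the higher free
energy -- the spec's acceptance rule for re-estimation is not published,
so the max-$F$ rule is adopted as the natural Bayesian choice.

## Group level

`peb_fit()` implements parametric empirical Bayes: each subject's
posterior is converted to a Gaussian likelihood kernel (posterior
precision minus prior precision, clamped to positive semi-definite), and
the second level models the stacked parameters as
$\theta = (X_B \otimes I_M)\beta + \epsilon_2$ with the four-column
design (constant; group, coded 1 for negative responders before
centring; age residualised on group; rM1 amplitude residualised on group
and age) built by recursive Gram-Schmidt orthogonalisation with
mean-centring. Between-subject covariance has one component per
parameter field ($A$ -- including self-connections -- $C$, decay,
transit), parameterised as field log-precisions $\gamma$ with
$\mathcal{N}(0, 1)$ priors and a baseline of $1/16$ of the first-level
prior variance; $\gamma$ is optimised numerically (Nelder-Mead), all
other quantities are closed-form. Priors on $\beta$ replicate the
first-level prior variances over covariates. These second-level priors
are documented defaults -- the source analysis defers them to its
software implementation.

Bayesian model reduction re-scores reduced priors analytically;
`compare_model_space()` crosses the eight field subsets (all; A,C; A,
transit+decay; C, transit+decay; A; C; transit+decay; none) for the
group-average and group-difference coefficient blocks, giving the
64-model grid. `peb_search()` prunes coefficients greedily --
re-evaluating all single removals after each accepted one, ties broken
towards the first index, using the rank-one form of the reduction
identity so each candidate costs $O(1)$ -- and averages the terminal
model with its single-off neighbours, weighted by evidence. Since the
"rM1 amplitude" covariate of the original voxelwise analysis is out of
scope, `response_amplitude()` substitutes the fitted peak amplitude of
the rM1 timeseries regressed on a canonical impulse-response regressor;
this is a documented departure.

## The synthetic cohort

`sample_cohort()` draws subjects around two template parameterisations
(`negative_responder_model()`, `positive_responder_model()`) that share
a left-driven hierarchy (inputs to lSMA and lPMd, SMA over PMd over M1,
homotopic SMA-SMA and PMd-PMd coupling) and differ in the three
inter-hemispheric connections onto rM1 -- net inhibitory for negative
responders, net excitatory for positive responders -- plus slightly
longer right-hemisphere transit times and slower vasoactive decay in the
negative group. Template magnitudes (drives around 0.1--0.25 Hz,
connections 0.1--0.4 Hz) were chosen once so that neural excursions stay
within the balloon model's physiological regime (sustained activity
below the flow-feedback rate $\gamma$) and so that the left premotor
regions have distinguishable response waveforms (different input
strengths and an lSMA to lPMd edge); perfectly collinear source regions
would make the inter-hemispheric weights unidentifiable in principle,
which is a property of the experiment, not of the estimator. Group
assignment follows the 0.46/0.54 split of the cohort's printed
age-amplitude mixture, ages are drawn from the matching component, and
between-subject variation is independent Gaussian per parameter (SD 0.08
for neural, 0.05 for haemodynamic log-scalers). Two safeguards keep
every sampled subject physically valid: draws are rejected unless the
neural matrix is strictly dissipative (largest real eigenvalue below
$-0.01$), and unless a deliberately dense, 1.25x-amplified screening
event train integrates without leaving the positive-flow regime.
Observation noise is AR(1) with coefficient 0.2 at SNR 1 by default
(fMRI noise is autocorrelated; the upstream analysis pre-whitens, so
white noise is also supported), scaled per region to the region's
signal SD.

What the generator does *not* emulate: voxel-level structure, motion and
physiological artefacts, non-linear neural saturation, behavioural
variability. Passing tests therefore demonstrate internal consistency
of the estimator chain on data generated by the model family itself --
they do not validate the biophysical model against real fMRI.

## Virtual experiments

`sign_flip_set()` operationalises "the sign of the rM1 response" as the
sign of the extremum (largest absolute value, ties to earlier time) of
the first-order Volterra kernel to the audio+visual condition over a
32 s window; kernels below $10^{-6}$ fractional signal are treated as
indeterminate. Sweeps cover $\pm 1$ around the base value -- Hz for
connectivity and driving inputs, log units for the haemodynamic and
self-connection scalers, since a Hz offset has no meaning for a
log-scaler -- on a 21-point grid by default, with bisection to 0.01 for
the flip offset. Failed (unstable) offsets are recorded per offset, not
fatal.

## Problem sizes used by the test-suite experiments

The packaged simulation studies run at desk scale, chosen as the
smallest sizes at which the estimator chain is exercised meaningfully:
two-region toys for exact oracles; cohorts of 20 subjects with ~46-trial
designs (SOAs uniform on 2--14 s, TR 2 s, 8 microtime bins per scan,
around 200 scans) for parameter-recovery and hierarchical-inference
properties; and 20 replicates of the full 635-subject mixture simulation
for the clustering results, which match the published component means
and assignment proportions closely. The paper-scale quantities that
depend on the restricted cohort data (a log Bayes factor of order
$10^4$, exact explained-variance percentages) are not reproducible at
these sizes and are asserted only as properties (sign, ordering,
calibration) rather than values.

## Known limitations

* The neural model is one-state and linear: no excitatory/inhibitory
  separation, no modulatory (bilinear) effects, no stochastic dynamics.
* The free-energy landscape of a 6-region model is multi-modal; single
  subjects can converge to local optima, which is why group-average
  re-estimation exists and why individual-subject estimates at SNR 1
  carry substantial posterior uncertainty.
* The second-level component model estimates one variance per field;
  region-specific between-subject variances are not modelled.
* Exact numerical agreement with other implementations of this model
  family is not expected: integrator, hyperpriors and step rules differ
  in documented ways.
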