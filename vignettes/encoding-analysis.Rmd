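---
title: "Measuring sensory encoding from orientation estimation behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sensory encoding from orientation estimation behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orienc)
```

## The problem

In an orientation-estimation task an observer reproduces the orientation
$\theta \in [0^\circ, 180^\circ)$ of a briefly shown grating. Responses carry
two signatures of the underlying sensory code: a systematic bias
$b(\theta) = E[\hat\theta] - \theta$ (humans push estimates away from the
cardinal orientations, the "oblique effect") and an orientation-dependent
dispersion $\sigma^2(\theta)$ (precision is best at 0° and 90°). Both are
shaped jointly by the *encoding* of the stimulus in noisy neural activity and
by the *decoding* of that activity into a report. `orienc` implements an
analysis that separates the two: the Cramér–Rao bound links bias, variance,
and the Fisher information (FI) of the encoding, irrespective of the decoder,

$$\sqrt{I_F(\theta)} \;=\; \frac{1 + b'(\theta)}{\sigma(\theta)},$$

where equality holds for the wide class of decoders that attain the bound
(maximum-likelihood, Bayesian posterior estimates, and any smooth remapping of
them). Measuring $b$ and $\sigma$ therefore measures the encoding itself.
Under efficient coding, $\sqrt{I_F}$ is proportional to the prior density of
orientations the observer's visual system is adapted to, so the normalized
profile $\sqrt{I_F(\theta)} \big/ \int_0^\pi \sqrt{I_F}\,d\theta$ estimates
that prior, and the denominator is the total encoding resource.

The pipeline has four stages, each a module of the package:

1. **Circular psychometrics** (`sliding_profile()`, `rmse_profile()`): a
   sliding window moves over the orientation grid; within each window a von
   Mises distribution fitted to the (doubled-angle) responses yields the local
   mean and concentration, hence $b(\theta)$ and $\sigma^2(\theta) = 1/\kappa$.
2. **Fisher extraction** (`extract_sqrt_fi()`, `normalize_prior()`,
   `total_resource()`): the tight bound converts the profiles into
   $\sqrt{I_F(\theta)}$, its normalization, and the total resource.
3. **Parametric model** (`parametric_sqrt_fi()`, `predict_bias()`,
   `fit_fi_params()`): the shape of $\sqrt{I_F}$ is summarized by two
   parameters,
   $$\sqrt{I_F(\theta;\lambda,\omega)} = \lambda\left(\omega\,
   \frac{1 - |\sin 2\theta|}{\pi - 2} + (1-\omega)\frac1\pi\right),$$
   a mixture of a cardinal-peaked density and the uniform density. $\lambda$
   is the total resource (the mixture integrates to 1), $\omega$ the share
   allocated to the cardinals. Rather than fitting the noisy derivative
   $b'$, the model is fitted by integrating the bound —
   $\hat b(\theta) = \int_0^\theta (\sqrt{I_F(t;\lambda,\omega)}\,
   \sigma(t) - 1)\,dt$ with the *measured* $\sigma$ — and least-squares
   matching $\hat b$ to the observed bias.
4. **Group inference** (`combined_participant()`, `bootstrap_statistic()`,
   `group_contrast()`, `flexibility_regression()`): pooled
   "combined-participant" statistics, trial-resampling bootstrap tests, and
   the across-participant regression of post-feedback allocation on baseline
   capacity.

## Conventions that matter

**Orientation is axial.** All circular estimation doubles the angle
($2\theta$, period 360°) and maps back; this is the standard treatment for
axial data and is centralized in `fit_von_mises_orientation()`.

**One variance convention, used everywhere.** The reported variance is the
reciprocal concentration $1/\kappa$ of the doubled-angle von Mises fit
(dimensionless; values like 0.18 for a capable observer). When this enters
Fisher-information arithmetic, which lives on the orientation scale in
radians, the standard deviation is $\sigma(\theta) = \sqrt{1/\kappa}/2$ — the
factor 2 converting from the doubled-angle to the orientation scale. With
this convention the three headline quantities are mutually consistent: a
homogeneous observer with $1/\kappa = 0.18$ has total resource
$\int\sqrt{I_F}\,d\theta = 2\pi\sqrt{\kappa} \approx 14.8$ and an RMSE near
13–15°, the magnitudes reported for neurotypical adults.

**Windows.** 18° for a single participant's 200-trial block, 4° for the
combined participant (thousands of trials); half-open
$[c - w/2,\, c + w/2)$, wrapping across 0°/180°. Within a window the fit is
applied to each trial's deviation from the window centre (target offset
reduced modulo the working period plus the response error), which keeps
trials on either side of a fold boundary coherent.

**90° periodicity.** The oblique-effect bias repeats every 90°. With
`enforce_period_90` (the default) orientations are folded modulo 90° before
windowing — doubling the trials per window — and the profile is tiled back
onto $[0°, 180°)$. The parametric prediction is correspondingly computed on
the folded domain, mean-centred per cycle, and tiled.

**Cardinal normalizer.** The mixture's cardinal component uses the analytic
normalizer $1/(\pi - 2) \approx 0.8760$, which makes the mixture integrate
to exactly 1; the rounded constant 0.877 seen in some published material is
available through `analysis_config(cardinal_norm = "printed")` (the mixture
is then renormalized, so fits differ negligibly, well under 0.5% in
$\lambda$).

**Optimization.** `fit_fi_params()` runs bounded L-BFGS-B from a
deterministic 3×3 start grid ($\lambda_0 \in \{0.5, 1, 2\}\times$ the
nonparametric total, $\omega_0 \in \{0.1, 0.5, 0.9\}$) with a tight
objective tolerance; on bias generated from the model itself it recovers the
parameters to $10^{-3}$ and $R^2 = 1$. Missing grid points are circularly
interpolated and flagged; negative raw bound values (possible in noisy
windows) are floored at zero and counted; degenerate windows clamp
$\kappa$ at `kappa_cap` with a flag.

## The synthetic observer and cohort

Because the study's raw data are external, the package ships a generative
observer that makes every stage testable. The encoder follows the standard
efficient-coding construction: the stimulus is passed through the cumulative
of the prior onto a uniform internal space (the unit circle, scaled to
$2\pi$), where homogeneous von Mises noise of concentration $\kappa$ is
added. Any of three bound-attaining decoders maps the measurement back: the
inverse of the encoding map (MLE-like), the circular posterior mean
(720-point quadrature, tabulated over a fine measurement grid), or a
smoothly remapped estimate $g(\hat\theta) = \hat\theta + a\sin(4\hat\theta)/4$,
$|a| < 1$, which preserves the 90° period and trades bias against variance
while leaving the bound tight to first order. The encoder's analytic profile
is $\sqrt{I_F(\theta)} = 2\pi\sqrt{\kappa}\,p(\theta)$ on the same
concentration-based precision convention the analysis uses, so a cohort
simulated at capacity $\lambda$ uses $\kappa = (\lambda/2\pi)^2$ and feeds
$\lambda$ back through the pipeline.

`study_cohort_spec()` encodes the study conditions: 25 NT and 17 ASD
observers, three 200-trial blocks with uniform targets, per-block
$(\lambda, \omega)$ schedules following the published group trajectories
(NT 14.7→16.8 with $\omega$ 0.50→0.31; ASD ≈11.3 throughout with $\omega$
0.50→0.41). Quantities the group statistics do not pin down were calibrated
once against the published per-participant scatter and then frozen:
lognormal capacity heterogeneity (sdlog 0.20), a capacity–learning coupling
(0.033) that makes higher-capacity observers flatten their allocation more
(reproducing the strength of the capacity–flexibility correlation,
$R^2 \approx 0.4$), lognormal response times whose medians fall by ~0.6 s
(NT) and ~0.75 s (ASD) across blocks, and a remapped decoder whose
amplitude anneals with feedback (NT 0.65→0.30, ASD 0.70→0.42). The remap
deserves a note: a pure inverse-map observer at realistic noise produces
only a ~1.6° mean bias, far below the ~5.6–6.0° that humans show, because
its bias is a second-order effect of the encoding nonlinearity. Real
observers carry an additional systematic repulsive distortion; the remap
models it with the classic $\sin 4\theta$ shape, and — by the
decoder-invariance property — it changes the measured bias/variance
trade-off without changing the extracted FI. Feedback annealing of its
amplitude reproduces the observed bias reduction with learning.

What the generator does *not* emulate: sequential effects and response
autocorrelation, lapses and gross confusions beyond circular wrapping,
asymmetries between 0° and 90°, RT–accuracy coupling, and any neural-level
mechanism. Passing tests therefore validate the estimation machinery and
its self-consistency, not those aspects of real data.

## Numerical behavior and known limitations

Two systematic effects of the measurement pipeline are worth knowing.

*Window-spread inflation.* The von Mises fit inside a window of width $w$
sees the target offsets as extra dispersion ($\approx w^2/12$), so extracted
$\sqrt{I_F}$ carries a small multiplicative deficit where the response
dispersion is comparable to the window. At the study's noise levels and 4°
window this is below 1%; in the low-noise decoder-invariance demonstration
it reaches a few percent and is shared by all decoders, which is why that
check compares normalized profiles against the analytic pattern.

*Shape attenuation at bound-level noise.* When internal noise is large
(capacities $\lambda \lesssim 15$, i.e. $\kappa \lesssim 6$ on the internal
circle), the response distribution of a bound-attaining observer deviates
from the local-Gaussian regime: tails stretch at the precise orientations
and compress at the imprecise ones, flattening the measured
$\sigma(\theta)$ profile relative to the linearized one. The fitted
$\omega$ is consequently biased low — by roughly 0.06 at
$(\lambda, \omega) = (15, 0.5)$ and up to ~0.14 at $(10, 0.5)$, while
$\lambda$ itself stays within a few percent. This attenuation is intrinsic
to the moment-based pipeline at these capacities (it affects all three
decoder families) and applies equally to real data: fitted $\omega$ values
should be read as a lower bound on the sharpness of the underlying
allocation. Group *contrasts* of $\omega$ remain meaningful because the
attenuation is shared.

Problem sizes used in the shipped checks: the decoder-invariance
demonstration uses a smooth anisotropic encoder at $\kappa = 36$ with
$10^5$ trials per decoder and a 6° window; parameter-recovery runs pool 25
observers × 200 trials over 20 seeds per condition; bootstrap calibration
uses 500 replications of two 200-trial groups at 500 resamples. The
internal noise level of every simulated encoder is reported in its spec
(`encoder$kappa`).

## A worked run

```{r example, eval = FALSE}
cohort <- simulate_cohort(study_cohort_spec(seed = 1))
nt <- combined_participant(cohort, "NT", "woFB")
prof <- sliding_profile(nt, window_deg = 4, fold_90 = TRUE)
fisher <- extract_sqrt_fi(prof)
total_resource(fisher)          # ~14.5
fit_fi_params(prof)[c("lam", "omega", "r2")]   # ~14.5, ~0.50, ~0.98
```

The numbered scripts under `analysis/` run the same stages over the full
cohort and write tidy tables under `results/`; `scripts/acceptance.R`
recomputes the headline quantities end-to-end from a fresh cohort.
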