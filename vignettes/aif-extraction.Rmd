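---
title: "Impulse-response AIF extraction: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impulse-response AIF extraction: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifx)
```

## The measurement model

A blood-pool ROI in a dynamic PET study measures, at the mid-times $t_i$
of its acquisition frames, a mixture of the arterial signal and two
contaminants. `aifx` models the decay-corrected frame activities as

$$z_i = (1-\pi)\,C_p(t_i-\Delta) + \pi\,(E_\phi * C_p)(t_i-\Delta)
      + \alpha_3 S_{t_i} + \epsilon_i,$$

where $C_p = \mathcal R * C_I$ is the arterial input function written as
the convolution of the whole-body impulse response $\mathcal R$ with the
known injection wave-form $C_I$; $E_\phi(u) = e^{-u/\phi}/\phi$ is the
Kety–Schmidt mono-exponential dispersion kernel; $S_t$ is a background
spillover pattern; and the errors have variance inversely proportional to
known frame weights $w_i \propto \Delta_i e^{-\tau t_i}$ (frame duration
times decay-correction factor; $\tau$ is the isotope decay constant).
Writing the weights this way follows from the usual PET variance model
$\mathrm{Var}(z_i) \propto e^{+\tau t_i}/\Delta_i$; setting $\tau = 0$
disables the decay factor.

The impulse response is expanded as
$\mathcal R(t\mid\theta) = \sum_{k=1}^K \theta_k B_k(t)$ over
piecewise-linear elements: $B_k$ is 1 on $[0, t_{k-1})$, declines linearly
to 0 across $[t_{k-1}, t_k)$, and vanishes beyond. Non-negative $\theta$
therefore guarantees a non-negative, non-increasing response — the physical
shape constraints — and keeps every convolution with a square-wave
injection available in closed form (piecewise quadratic). The direct-signal
coefficient is fixed at 1, so $\theta$ is unnormalised (it carries the
activity scale of the data) and $\pi$ is the dispersed fraction.

For fixed $(\pi, \phi, \Delta)$ the weighted least-squares problem in
$\theta$ (plus the spillover coefficient $\alpha_3$) subject to
$\theta \ge 0$ and linear equality constraints is a quadratic program,
solved by the dual (Goldfarb–Idnani) method. The reduced objective is then
minimised over $(\pi, \phi, \Delta)$ by a coarse multi-start grid followed
by bounded quasi-Newton refinement, because the reduced surface can be
multimodal in $\Delta$.

## Identifiability and the two constraints

With dispersion or spillover present, even noise-free continuously sampled
ROI data cannot determine the normalised impulse response. Two functionals
restore identifiability when fixed to known values:

* the **mean residence time** $\mu_1 = \int t\mathcal R \,/ \int \mathcal R$,
  which separates the direct and dispersed components, and
* a **contrast ratio** $\mu_2 = \mathcal R(T_b)/\mathcal R(T_a)$ between a
  late and an early time, which separates the blood signal from the
  spillover ramp.

Both become linear equality constraints on $\theta$ and are calibrated
from a population of directly sampled arterial curves for the tracer.

**Choice of $(T_a, T_b)$.** The contrast times default to the knots at the
25% and 75% positions of the knot vector. An earlier design placed $T_b$
at $0.75\,t_K$; with geometrically spaced knots that point lies where a
fast tracer's response has decayed to roughly $10^{-3}$ of its early value,
so the ratio constraint pinned an essentially-zero quantity and left the
mid-tail — exactly where single-sample scaling operates — unconstrained.
Placing both contrast times inside the response's informative range makes
the constraint do its intended work.

## Population prior and regularisation

Arterial curves are fitted in *arterial mode*: dispersion and spillover are
fixed at zero, only the time shift is optimised, and no identifiability
constraints are imposed (these fits are what calibrates them). Sample
weights default to inverse activity, floored at 1% of the peak: counting
noise in blood samples scales with activity, and uniform weights were
observed to discard the late tail entirely, since the tail sits two orders
of magnitude below the peak and contributes negligible absolute residual.

The fitted coefficient vectors give the prior mean $\mu_\theta$ and
covariance $\Sigma_\theta$, used in the penalised criterion

$$\ell_\lambda = \mathrm{WRSS} + \lambda\,
 (\theta-\mu_\theta)'\Sigma_\theta^{-1}(\theta-\mu_\theta).$$

Two deliberate choices here:

* **The prior lives on the activity scale.** Because the ROI fit fixes the
  direct coefficient at 1, its $\theta$ is in the data's activity units. A
  unit-integral-normalised prior mean would be off in amplitude by an
  order of magnitude, and the shrinkage path toward it passes through
  badly distorted shapes; the prior therefore keeps the arterial fits'
  scale, and priors should be built from curves in the same units as the
  data they will regularise. Normalisation is still applied wherever it is
  the right thing: percentile summaries, and the scale-free $\mu_1, \mu_2$.
* **$\Sigma_\theta$ is ridged** by $10^{-6}\cdot\overline{\mathrm{diag}}$
  before inversion, since $K$ may exceed the number of arterial curves.
  The spillover coefficient is never penalised — the population carries no
  information about an ROI's spillover.

$\lambda$ is chosen by generalised cross-validation,
$\mathrm{GCV}(\lambda) = (\mathrm{WRSS}/n)\,/\,(1-\mathrm{tr}(H_\lambda)/n)^2$,
with the hat matrix of the equality-constrained penalised smoother
restricted to the converged active set. The nuisance parameters are
re-optimised at each $\lambda$ (warm-started from the previous value);
consequently the WRSS and penalty paths are monotone only up to small
optimiser wiggle — the exact monotonicity holds for the fixed-nuisance
smoother family, and the tests assert it there. The default grid is 25
log-spaced points spanning $10^{-4}$ to $10^{4}$ times
$n/\mathrm{tr}(\Sigma_\theta^{-1})$; on the study conditions examined this
scale sits in the middle of the effective-degrees-of-freedom transition.
Ties are broken toward the larger (smoother) $\lambda$.

## Pooling and scaling

When several candidate ROIs are available, each fit's
$\hat\sigma^2$ — the fraction of spillover-corrected variance left
unexplained — defines inverse-variance pooling weights, and the pooled
coefficients are the weighted average. The full covariance-weighted
combination is intentionally not implemented; the proportional-covariance
simplification is, and pooling operates on $\theta$ under common knots.
The nuisance parameters $(\pi, \phi, \Delta)$ are ROI-specific and never
pooled.

The extracted AIF's scale is arbitrary whenever contamination is present.
Three scalings are provided: passing through a single blood sample
(exact); matching the unit integrated residue expected of a pure vascular
ROI (the residue is deconvolved by the same basis-QP machinery; factors
outside $[0.2, 1.2]$ are flagged, since end-of-study retention or partial
volume both bias this rule); and targeting a late activity predicted from
injected dose per Nadler blood volume, with the proportionality
coefficient estimated from historical records by no-intercept weighted
least squares.

## The synthetic study conditions

The simulation module defines two archetypes spanning the extremes of
circulation behaviour: water-like (5 s injection, 41 frames over 7.25 min,
circulation half-life ≈ 9.5 s past a 5 s reference) and FDG-like (60 s
infusion, 30 frames over 89 min, half-life ≈ 75 s). The ground-truth
impulse response is a three-term decaying-exponential mixture —
deliberately outside the span of the piecewise-linear fitting basis, so
the experiment tests approximation, not self-fulfilment. Mixture
parameters were set once to reproduce the target circulation percentiles;
a decaying-exponential mixture cannot reproduce a near-plateau survival
with a sharp drop, so for the FDG-like archetype the 50% and 95%
percentiles are matched and the 25% one is knowingly fast. Subjects vary
by independent log-normal jitter (CV 20%) of the mixture parameters.

Contamination follows
$C_T = (1-p_d)C_p + p_d E_{\phi_d}*C_p + p_b\bar S$, with $\bar S$ the
cumulative integral of the AIF normalised to 1 at the study end and
$\phi_d$ set so the dispersion kernel's half-life matches the archetype's
circulation half-life. Because $\bar S$ is unit-normalised, the absolute
scale of $C_p$ determines what $p_b$ means: the generator therefore
produces curves in realistic decay-corrected activity units (peaks of a
few tens of kBq/ml), so that the lightest level $(0.1, 0.125)$ perturbs
the late blood signal only mildly — data "substantially free of
contamination" — while the heaviest $(0.6, 2.0)$ overwhelms it. With a
unit-normalised AIF instead, even the lightest spillover would dominate
the late tail ten-fold and every level would destroy the direct method
equally, erasing the contamination gradient the study is about.

Frame noise is Gaussian with variance
$\propto C_T(t_i)e^{\tau t_i}/\Delta_i$; the proportionality constant
defaults to a 2% coefficient of variation at the peak frame
(deliberately low noise; configurable via `cv_peak`). Negative simulated
activities are kept — the weights, not truncation, handle low-count
frames.

The experiment driver builds one prior per archetype from 20 simulated
arterial-mode fits, then for each contamination level and replicate
extracts the AIF (a) directly from the interpolated ROI curve and (b) by
the constrained, GCV-penalised method with the prior-mean spillover
pattern, scales both through a single simulated true-AIF sample (2 min for
the water-like, 10 min for the FDG-like archetype), and scores both by
RMISE over the study. Default problem sizes — 50 replicates per archetype
and level, 7-point $\lambda$ grid, $3\times3\times4$ multi-start — keep a
full run in the ten-minute range on one core.

What passing these simulations does *not* show about real data: the
generator has no metabolites, no recirculation structure beyond the slow
mixture component, no frame-to-frame correlated reconstruction noise, and
subject variation is a parametric jitter rather than real physiological
diversity. The single-sample scaling rule is exact here because the
"blood sample" is read off the true curve; with real venous samples its
error adds directly to the extraction error.

## Numerical choices and degenerate inputs

* Internal curves live on a uniform grid whose step adapts to the study
  duration (0.05–1 s, about 6000 points); dispersion uses the exact
  exponential-kernel recursion on that grid (compiled), which is causal
  and stable for any $\phi > 0$, rather than FFT convolution.
* Time shifts interpolate linearly; frames are half-open intervals; all
  times are seconds internally, with CSV inputs declaring `s` or `min`.
* The QP's quadratic form is rescaled to unit diagonal mean before
  solving; rank deficiency or conditioning failures retry with an
  escalating ridge (minimum-norm convention, warned).
* $\theta = 0$ is always feasible, so "infeasible" reports from the dual
  solver are treated as conditioning failures, not modelling errors.
* All-zero ROI data return a zero fit with a warning rather than an error.
* Equality constraints are enforced by the QP to solver precision
  (~$10^{-8}$ relative); there is no soft-penalty fallback.
* Optimiser bounds default to $\pi \in [0,1]$, $\phi \in [0.5, 120]$ s,
  $\Delta \in [-30, 120]$ s.

## Known limitations

* Under heavy contamination the data carry almost no information about the
  response's late tail (it is collinear with the spillover column), so
  tail recovery rests on the prior and the ratio constraint. When a
  subject's true mean residence time differs substantially from the
  population $\mu_1$, the equality constraint resolves the conflict by
  cutting late coefficients, and single-sample scaling at a deep-tail
  time point then amplifies the error. The water-like archetype shows
  occasional large negative percent improvements for exactly this reason;
  they are a property of the estimator as specified, reported as-is.
* GCV targets prediction error, not AIF shape error; under near-noise-free
  data it prefers light penalties, leaving weakly determined directions
  under-shrunk.
* The physiologic scaling rule ignores recovery-coefficient (partial
  volume) corrections.
* Knot placement (geometric, $K = 12$, first knot 3–5 s) is an engineering
  default; sparse late knots limit tail resolution for slow tracers.
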