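# aifx

Arterial input function (AIF) extraction from dynamic PET blood-pool data
that may be contaminated by dispersion and background spillover.

## The problem

Kinetic analysis of dynamic PET needs the tracer concentration in arterial
blood over time, C<sub>p</sub>(t). When direct arterial sampling is
impractical, C<sub>p</sub> must be recovered from the time–activity curve
(TAC) of an image-derived blood-pool region of interest (ROI). Such ROI
signals are rarely pure blood: they are smeared by dispersion in the
vascular network and inflated by spillover from surrounding tissue. Naively
reading the ROI curve as the AIF then misestimates both its shape and its
scale.

`aifx` represents the AIF through the whole-body impulse response R to the
injection: C<sub>p</sub> = R ∗ C<sub>I</sub>, where C<sub>I</sub> is the
known injection wave-form (square wave, bolus, or measured). R is expanded
in piecewise-linear basis elements B<sub>k</sub> with non-negative
coefficients θ, which makes R automatically non-negative and
non-increasing. The ROI measurement model is

    z(t_i) = (1 − π)·(R ∗ C_I)(t_i − Δ) + π·(E_φ ∗ R ∗ C_I)(t_i − Δ) + α₃·S(t_i) + ε_i,

with E<sub>φ</sub> a mono-exponential dispersion kernel, S a background
(spillover) pattern — by default the Patlak-style cumulative integral of
the injection — and frame-dependent weights w<sub>i</sub> ∝ Δ<sub>i</sub>
e<sup>−τ t<sub>i</sub></sup>. For fixed (π, φ, Δ) the coefficients solve a
non-negative, equality-constrained weighted least-squares problem by
quadratic programming; the reduced objective is then minimised over
(π, φ, Δ).

With dispersion or spillover present the normalised R is not identifiable
from ROI data alone. Identifiability is restored by two linear equality
constraints: a known mean residence time μ₁ = ∫tR/∫R and a contrast ratio
μ₂ = R(T_b)/R(T_a). Both are calibrated from a population of directly
sampled arterial curves, which also yields a prior (μ<sub>θ</sub>,
Σ<sub>θ</sub>) used in a Mahalanobis penalty

    ℓ_λ(θ, π, φ, Δ) = WRSS + λ (θ − μ_θ)' Σ_θ⁻¹ (θ − μ_θ),

with λ chosen by generalised cross-validation. Per-ROI estimates can be
pooled by inverse-variance weighting, and the extracted (shape-only) AIF
is scaled to activity units by a blood sample, by physiologic expectation
for a vascular ROI, or by injected dose per unit blood volume (Nadler).

A simulation framework generates ground-truth AIFs for water-like and
FDG-like tracer archetypes, contaminates them with controlled dispersion
and spillover, adds PET-like frame noise, and scores extraction methods by
root mean integrated squared error (RMISE).

## Worked example

Simulate a contaminated water-study ROI, build a population prior from 20
simulated arterial curves, and extract the AIF with constraints and a
GCV-chosen penalty:

```r
library(aifx)

arch  <- builtin_archetypes()$h2o         # 5 s injection, 41-frame schedule
truth <- make_true_aif(arch, seed = 42)   # ground-truth AIF (kBq/ml)
ct    <- contaminate(truth$curve,
                     contamination_spec(p_d = 0.4, p_b = 0.75,
                                        phi_d = arch$phi_d),
                     arch$schedule)
roi   <- simulate_roi(ct, arch$schedule, seed = 43)

pr    <- archetype_prior(arch, seed = 99)  # 20 arterial-mode fits
sel   <- gcv_select(roi, arch$injection, pr$knots,
                    constraints_from_prior(pr$prior), pr$prior,
                    background = "prior_aif")
sel$fit
#> AIF fit (roi mode): WRSS = 67.4754, pi = 0.000, phi = 0.50 s,
#>   delta = -6.40 s, alpha3 = 0.6491, lambda = 0.000856

aif    <- aif_curve(sel$fit)
scaled <- scale_blood_sample(aif, t_B = 120,
                             d_B = truth$aif_fun(120))
rmise(scaled$curve, truth$curve)
#> [1] 42.93514
```

The fit reports the dispersed fraction `pi`, the dispersion time constant
`phi` (seconds), the temporal alignment `delta` and the spillover
coefficient `alpha3`; with the GCV-selected penalty this particular fit
leans on the population prior and the spillover column (the nuisance
parameters carry no information about the AIF itself), and
`aif_curve()` returns the extracted curve, which the single blood sample
at 120 s puts onto the absolute activity scale (kBq/ml). Reading the raw
ROI curve directly as the AIF and rescaling it through the same blood
sample gives an RMISE of 55.3 on the same data, about 30% worse;
`run_experiment()` quantifies that comparison systematically over
contamination levels and shows the gap widening sharply as contamination
grows.

## Package layout

* `tac_io` — TAC/prior/fit readers and writers, frame-schedule arithmetic,
  default weights (`read_tac`, `default_weights`, `write_prior`, ...)
* `ir_model` — knots, piecewise-linear basis, convolution with injection
  profiles, dispersion and shift operators (`make_knots`, `basis_eval`,
  `convolve_with_injection`, `disperse`, ...)
* `constrained_fit` — constraint matrix, design matrix, QP and the nested
  nonlinear fit (`build_constraints`, `qp_solve`, `fit_roi`)
* `regularization` — Mahalanobis penalty and GCV (`penalized_fit`,
  `gcv_select`)
* `population_prior` — arterial-mode fits, prior construction, circulation
  percentiles, effective dimension (`fit_arterial_curve`, `build_prior`,
  `ir_percentiles`, `effective_dimension`)
* `pool_scale` — pooling and the three scaling rules (`pool_fits`,
  `scale_blood_sample`, `scale_physiologic`, `nadler_bv`, `scale_dose_bv`)
* `synthetic_data` — archetypes, contamination, noise, RMISE and the
  simulation driver (`builtin_archetypes`, `contaminate`, `simulate_roi`,
  `run_experiment`)
* `inst/cli/aifx` — a thin command-line front end
  (`aifx extract --tac roi.csv --injection square:60 --prior prior.json
  --lambda auto`)

See `vignettes/aif-extraction.Rmd` for the methods account: model
assumptions, parameter choices, numerical decisions and known limitations.
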