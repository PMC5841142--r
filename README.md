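# cthmap

Voxel-wise vascular modelling of dynamic susceptibility contrast (DSC)
MR perfusion, centred on **capillary transit time heterogeneity (CTH)**
— a marker of disturbed microvascular flow in white matter disease —
together with blood–brain barrier leakage, oxygen extraction capacity,
and lesion-zone analysis for inflammatory demyelination.

## Who this is for

Researchers analysing bolus-tracking perfusion MRI who want more than
the classical CBF/MTT maps: the package fits a parametric vascular model
per voxel and derives the transit-time *distribution*, from which flow
heterogeneity and oxygen-delivery limits follow. Because clinical DSC
data can rarely be shared, the package also ships a full synthetic-study
layer (phantoms with known ground truth, lesion geometries, longitudinal
cohorts) so every stage of the pipeline is testable and reproducible
end-to-end without any patient data.

## The model

The tissue contrast concentration `c(t)` is modelled as

    kappa * c(t) = CBF * (Ca ⊛ R)(t - delay) + K_app * ∫₀ᵗ Ca(τ) dτ

where `Ca(t)` is the arterial input function, `R(t) = 1 - F(t; α, β)`
is the residue function — the complement of a cumulative gamma
distribution of capillary transit times — and `K_app` is an apparent
leakage rate capturing contrast extravasation across the blood–brain
barrier (sign-unconstrained). From the fitted gamma law:

* `MTT = α·β` — mean transit time (s)
* `CTH = √α·β` — transit time heterogeneity, the SD of the transit
  time distribution (s)
* `OEC = ∫ Q(τ) h(τ|α,β) dτ` — oxygen extraction capacity, the
  expectation of the Bohr–Kety–Crone–Renkin single-capillary extraction
  `Q(τ)` over the transit-time law
* `CMRO2max = CBF · OEC` — the theoretical upper bound on the cerebral
  metabolic rate of oxygen

Fitting is bounded multistart Levenberg–Marquardt least squares over
`(CBF, log α, log β, K_app)` with the bolus delay handled by exhaustive
grid search; `kappa` is set to unity, so CBF is in arbitrary units on
the ml/100 ml/min scale unless calibrated.

## Worked example

Simulate one voxel with known ground truth, add noise, and fit:

```r
library(cthmap)
acq <- acquisition_params()          # TR 1.5 s, TE 40 ms, 80 frames
tg  <- frame_times(acq)
aif <- make_aif(aif_model(), tg)
truth <- ground_truth_voxel(cbf = 55, alpha = 2, beta = 2.3, k_app = 8e-5)
conc  <- forward_tissue_curve(aif, truth, acq, tg)
sig   <- concentration_to_signal(conc, s0 = 100, te = acq$te,
                                 noise_sigma = 0.2, seed = 1)
fit <- fit_voxel(signal_to_concentration(sig, acq), aif, tg,
                 fit_options(n_multistart = 3, delay_grid = 0))
fit
#> Vascular model fit (gamma residue + leakage)
#>   CBF   51.28 a.u. (ml/100 ml/min scale)
#>   MTT   4.795 s   CTH 2.482 s   RTH 0.5177
#>   K_app 0.003123 /min   delay 0 s
#>   RSS 0.1534 over 80 frames; converged: TRUE (3 restarts)
oec(fit$transit)                     # 0.3159435
cmro2max(coef(fit)[["cbf"]], oec(fit$transit))   # 16.20238
```

The generating values were CBF 55, MTT 4.6 s, CTH 3.25 s: at this noise
level a single voxel carries visible estimation error, which is why the
study-level functions average over phantom cohorts. `fit_volume()`
applies the same fit across a masked 4D series and returns aligned
`perfusion_maps`; `oxygen_maps()` fills in OEC and CMRO2max;
`segment_lesion_zones()` builds the five concentric lesion compartments
(core, enhancing rim, leading edge, perilesional and distant
normal-appearing white matter) from T2/enhancement/WM masks;
`build_probability_atlas()`, `roi_mean()`, `relative_value()`,
`compare_groups()` and `first_last_contrast()` cover the atlas, ROI and
cohort statistics.

A command-line pipeline over NIfTI inputs is installed at
`inst/cli/cthmap` (subcommands `simulate`, `fit`, `zones`, `cohort`,
`all`, driven by a YAML config; see `default_config()`).

## Vignette

`vignettes/vascular-model.Rmd` documents the model and its assumptions,
the committed phantom calibration, the numerical choices (discrete
convolution, delay-degeneracy handling, BKCR integration) and the
limitations of synthetic validation.
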