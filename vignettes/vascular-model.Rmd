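---
title: "The vascular model behind cthmap: transit time heterogeneity, leakage and oxygen extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vascular model behind cthmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cthmap)
```

## The problem

In bolus-tracking (DSC) perfusion MRI, the classical deconvolution
outputs — CBF and MTT — summarise capillary flow by its mean. But
microvascular pathology in inflammatory white matter disease shows up
first as a *widening* of the transit time distribution: when capillary
flows fail to homogenise (for example through leucocyte adhesion to
activated endothelium), some capillaries run fast and others slow, and
oxygen extraction suffers even at preserved mean flow. The quantity of
interest is therefore the standard deviation of the transit-time
distribution — capillary transit time heterogeneity, CTH — alongside an
apparent blood–brain barrier leakage rate, and the downstream oxygen
quantities they imply.

## The model

Tissue concentration is modelled as

$$\kappa\,c(t) = \mathrm{CBF}\int_0^{t} C_a(\tau)\,
R(t-\delta-\tau)\,d\tau \;+\; K_\mathrm{app}\int_0^{t} C_a(\tau)\,d\tau$$

with $R(t) = 1 - F(t;\alpha,\beta)$ the residue function, the
complement of a cumulative gamma distribution of transit times. The
gamma law gives $\mathrm{MTT}=\alpha\beta$ and
$\mathrm{CTH}=\sqrt{\alpha}\,\beta$. The second term is an additive
leakage flux: with $K_\mathrm{app}=0$ the curve returns toward baseline
after bolus passage; with $K_\mathrm{app}\neq 0$ it stays offset by
$K_\mathrm{app}$ times the accumulated arterial integral.
$K_\mathrm{app}$ is deliberately unconstrained in sign — small negative
fitted values occur in practice and are reported as-is, since their
physiological interpretation is unresolved. The kernel is the residue
function (not the transit-time density): convolving the input with the
survival function of the transit law is the standard indicator-dilution
form, and is what makes $c$ proportional to CBF at early times.

$\kappa$, which absorbs haematocrit and tissue-density factors, is set
to one; CBF is therefore on the ml/100 ml/min *scale* but in arbitrary
units unless an external calibration factor is supplied.

### Units

| quantity | unit | internal conversion |
|---|---|---|
| CBF | ml/100 ml/min | divided by 6000 to give s$^{-1}$ |
| MTT, CTH, delay | s | — |
| $K_\mathrm{app}$ | min$^{-1}$ | divided by 60 |
| concentration | s$^{-1}$ ($\Delta R_2^*$) | — |

## Signal model and noise

The acquisition is single-echo gradient-echo EPI, so the package adopts
$S(t) = S_0 e^{-TE\,\Delta R_2^*(t)}$ with concentration identified
with $\Delta R_2^*$ (relaxivity absorbed into the arbitrary
concentration units), and inverts it per voxel with $S_0$ estimated
from the pre-bolus frames (frame 1 is excluded from the baseline when
possible, as the signal has not reached steady state). Synthetic noise
is additive zero-mean Gaussian on the signal. At DSC signal-to-noise
levels the difference from Rician noise is negligible, and the additive
model keeps the transform exactly invertible at zero noise, which the
test suite exploits as a round-trip oracle.

The generator's `snr` parameter is a *contrast-to-noise* specification:
the noise SD is the mean bolus-induced signal excursion divided by
`snr`. This is the quantity that actually governs parameter
identifiability, and it is invariant to the arbitrary units of the
synthetic arterial input. A consequence worth knowing: in a phantom
containing regions of very different bolus depth, a single study-wide
noise level means the shallower regions are fitted at lower effective
SNR.

## Fitting

`fit_voxel()` minimises the residual sum of squares over
$(\mathrm{CBF}, \log\alpha, \log\beta, K_\mathrm{app})$ with bounded
Levenberg–Marquardt (minpack.lm), from `n_multistart` quantile-spaced
initial (MTT, RTH) pairs (default 5). Positivity of $\alpha,\beta$ is
enforced structurally by optimising on the log scale; CBF is bounded
below by zero; $K_\mathrm{app}$ is free.

**Discretisation.** The convolution is a trapezoid rule on a grid
upsampled by an integer factor (default 4) relative to the frame grid,
then decimated to the frames; the same operator serves the generator
and the fitter, so discretisation is a shared approximation rather than
a fitting bias. This is the single source of discretisation tolerance
in the package.

**Delay.** The bolus delay is fit by exhaustive search over a grid
(default 0–5 s in TR/2 steps), refitting the continuous parameters at
each point. Delay and transit-time dispersion are nearly degenerate:
under noise an unconstrained arg-min happily trades a spurious delay
for a sharper residue function, which we measured as a large upward
CBF bias on zero-delay phantoms. The search therefore applies a
parsimony rule — among delays whose residual sum of squares is within
`delay_rss_tol` (default 5%) of the minimum, the smallest delay wins.
On noiseless data a true delay improves the RSS by orders of magnitude,
so exact recovery is untouched. For the committed phantom studies the
delay grid is pinned at zero (`fit_options(delay_grid = 0)`): the
generator introduces no voxel-level arrival dispersion (bolus timing
lives in the arterial input's arrival parameter), and even the
parsimonious search admits rare large-CBF outliers that a synthetic
recovery study has no reason to accept. Clinical-style fits should keep
the full grid.

**Missing data.** Voxels with non-positive baselines are marked missing
at the concentration stage and stay missing in every derived map.

## Oxygen model

Along a single capillary of transit time $\tau$, haemoglobin
saturation follows
$dS/dx = -k\,\tau\,(P(S) - P_t)$ on normalised length $x\in[0,1]$,
with the inverse Hill binding curve
$P(S) = P_{50}\,(S/(1-S))^{1/h}$. The committed defaults are
$P_{50}=26$ mmHg, $h=2.8$, tissue tension $P_t=25$ mmHg and arterial
saturation $S_a=0.95$ — the published parametrisation of the
Bohr–Kety–Crone–Renkin single-capillary model — with the effective rate
constant $k=4.5\times10^{-3}$ mmHg$^{-1}$s$^{-1}$ chosen once so that
the control white-matter transit moments yield an extraction capacity
near the classical resting value (OEC $\approx 0.30$). All of these are
configurable through `oxygen_params()`.

Numerically the ODE is separable: with
$G(S)=\int_S^{S_a} dS'/(P(S')-P_t)$ the outflow saturation solves
$G(S_\mathrm{out}) = k\tau$, so `capillary_extraction()` inverts a
single tabulated monotone quadrature (12 000-point log-spaced grid with
a Hyman monotone spline). This is exact up to tabulation error
(validated against a stiff ODE solver to $\sim 10^{-7}$) and remains
stable for arbitrarily large $k\tau$, where fixed-step forward
integration would be stiff. The extraction saturates at
$Q_{\max} = 1 - S_t/S_a \approx 0.50$, where $P(S_t)=P_t$.

`oec()` takes the expectation of $Q$ over the fitted gamma law by
adaptive Gauss–Kronrod quadrature *on the probability scale*
($\tau = F^{-1}(u)$, $u\in(0,1)$), which removes both the infinite
upper limit and the density weight. An `exponential` mode
($Q = 1-e^{-k\tau}$) exists purely as a numerics oracle: its
expectation has the closed form $1-(1+k\beta)^{-\alpha}$, which the
test suite checks to $10^{-10}$. Because $Q$ is concave, OEC is bounded
by $Q(\mathrm{MTT})$ (Jensen) and decreases with CTH at fixed MTT —
the mechanism by which flow heterogeneity limits oxygen delivery.
`CMRO2max = CBF × OEC × content` with the arterial oxygen content
factor defaulting to 1, so the product is reported on the CBF scale;
the unit convention behind published ml/100 ml/min values is not
stated with the model, so the factor is exposed rather than guessed.

## The synthetic study

The phantom generator is the package's substitute for patient data, and
its defaults *are* the study conditions:

* **Whole white matter.** Hemizygote: MTT 4.5 s, CTH 3.20 ± 0.44 s,
  $K_\mathrm{app}$ 0.08 ± 0.03 ×10⁻³/min; control: MTT 4.0 s, CTH
  1.83 ± 0.15 s, $K_\mathrm{app}$ 0.07 ± 0.01 ×10⁻³/min. The printed
  group spreads are interpreted as between-voxel SDs. Ground-truth CBF
  is *calibrated*: given the committed oxygen defaults, CBF is chosen
  so that CBF × OEC equals the group CMRO2max value (15.78 / 29.18
  ml/100 ml/min), making the oxygen chain testable end-to-end. The MTT
  values themselves are not published for these groups; 4–4.5 s are
  plausible white-matter means, with the hemizygote value slightly
  longer in line with the observed MTT–CTH mismatch.
* **Nine-region survey.** Regional CTH means interpolate linearly from
  the splenium (4.00 ± 0.60 s, most frequently lesioned) to the frontal
  white matter (2.92 ± 0.27 s, least) along the lesion-probability
  ranking, at the group's fixed RTH; the thalamic reference region
  (CTH 0.8 s) supports rCTH normalisation. Only the two endpoint values
  are published; the interpolation and the thalamic value are
  calibration choices.
* **Lesion zones.** Zone D (perilesional NAWM) is a mixture of a
  converting sector (CTH 4.09 ± 0.87 s) and a non-converting sector
  (2.62 ± 0.57 s) with the converting fraction chosen so the mixture
  mean equals the zone value 3.01 s; distant NAWM is 2.20 ± 0.26 s.
  Zone C splits into an enhancing-on-follow-up sector
  ($K_\mathrm{app} = -0.04$ ×10⁻³/min, the published progressing-sector
  value, negative as printed) and a non-enhancing sector
  (0.02 ×10⁻³/min); the construction test therefore compares
  $|K_\mathrm{app}|$ between sectors. Zone A/B interior values and the
  Zone C/distant-NAWM leakage gradient (0.04 vs 0.01 ×10⁻³/min) are
  calibration choices consistent with the reported ordering.
* **Cohorts.** Hemizygote splenium CTH follows a Gaussian age bump
  (base 1.3 s + 2.9 s·exp(−((age−7)/5)²)), peaking in the 5–10-year
  window of highest conversion risk; controls are flat in age. Bolus
  arrival is a free generator parameter (no per-subject injection
  timing is published); the default arrival of 12 s leaves the eight
  baseline frames strictly pre-bolus at TR 1.5 s.

Zone geometry is mask algebra: B = enhancement ∩ lesion; A = the
non-enhancing component enclosed by B (26-connected flood fill from the
lesion centroid; empty when B is empty); C = the remaining lesion;
D = a 2-voxel dilation ring (Chebyshev metric) restricted to white
matter; E = white matter beyond a 6-voxel margin. The dilation
distances separating "adjacent" from "distant" NAWM are not published;
2 and 6 voxels are package defaults, configurable per call. Hand-drawn
bilateral ROIs are replaced by deterministic fixed-size ROIs (default
24 voxels) centred on region centroids.

## What the synthetic studies show — and what they do not

`scripts/acceptance.R` (and the mirror tests) verify that the full
pipeline — GRE signal with noise at contrast-to-noise 20, automatic or
supplied AIF, voxel-wise fitting, oxygen mapping, zone segmentation,
cohort averaging — returns the generating group values within two
standard errors of the published group sizes: noiseless recovery is
exact to well under 1% over a 64-condition grid, and cohort-mean CTH
bias at CNR 20 is about −2 to −3%. Study sizes are 10 subjects with
24-voxel region blocks for the whole-WM and regional cohorts (the
regional survey averages ROI means over subjects, as the published
regional values are group statistics), and a 26×26×3 lesion phantom
with a 312-voxel Zone D.

These are *internal-consistency* results: the generator and fitter
share the forward model, so they demonstrate estimator correctness,
noise robustness and the integrity of the derived-quantity chain — not
the physiological validity of the vascular model. Real data add
effects the phantoms deliberately omit: motion, registration error,
field inhomogeneity, Rician noise, T1-shortening leakage effects
(the additive $K_\mathrm{app}$ term captures neither dual-echo
separation nor the intra/extravascular compartment mixture), partial
volume, and arterial input functions measured rather than known.
Fitted residue functions average hundreds of capillary beds per voxel.

## Degenerate inputs and tie-breaks

* All-zero or non-positive-baseline voxels → missing, never an error.
* All-missing curves → a missing fit object (`converged = FALSE`).
* Multistart ties → lowest RSS, then the earlier delay (within the
  parsimony tolerance), then the lower restart index.
* Paired comparisons with zero difference variance → exact-difference
  report: statistic 0 / p 1 when the common difference is zero,
  otherwise a signed infinite statistic with p 0, flagged `degenerate`.
* Zones of an empty lesion → empty masks with a warning; enhancement
  outside the lesion is clipped with a warning.
* An AIF selection with no arterial-like candidate fails with an error
  advising a manual AIF rather than silently averaging tissue curves.

## Known limitations

* CBF is relative (κ = 1); absolute calibration is out of scope.
* The delay grid is coarse (TR/2) and the delay–dispersion degeneracy
  is resolved by parsimony, not by modelling arterial dispersion.
* $K_\mathrm{app}$ at the published magnitudes (10⁻⁴–10⁻⁵ /min) is far
  below the noise floor of a single voxel at CNR 20; leakage recovery
  is only quantitative on noiseless or high-CNR data, which is why no
  noisy-recovery claim is made for it.
* Mixed-effects age/probability regressions, ICC reader statistics and
  power calculations on patient data are outside the package's scope;
  the cohort layer stops at paired/unpaired contrasts and summaries.
* Repeated-measures ANOVA with post-hoc corrections for the five-zone
  comparisons is not re-implemented; zone-wise paired contrasts are
  reported instead.
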