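---
title: "Voxel-based theranostic dosimetry: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based theranostic dosimetry: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In theranostic radionuclide therapy a tumour-targeting vector is first
imaged with a surrogate gamma emitter (here In-111, physical half-life
67.3 h) and, if the biodistribution is favourable, the same vector is
injected labelled with a therapeutic beta emitter (Y-90, half-life
64.05 h, pure beta decay to stable Zr-90). Because Y-90 is essentially
invisible to the gamma camera, the absorbed dose the therapy *would*
deliver must be predicted from the surrogate images. `voxdosim`
implements that prediction as a pipeline over a time series of
registered, reconstructed SPECT/CT images:

1. **Calibration** of SPECT counts to absolute activity,
2. **Kinetics**: VOI and voxel time-activity curves, mono-exponential
   tail fits, time-integrated activity (TIA),
3. **Decay substitution** from the imaging to the therapy radionuclide,
4. **Absorbed dose** from a beta transport simulation, in cGy per
   injected MBq,
5. **Lesion grading** against mediastinal blood-pool and liver
   reference uptake.

All stages are exercised end-to-end on a synthetic phantom with
closed-form ground truth (`synthesizeStudy()`), so every quantitative
claim in the test suite is checked against an analytic value.

# Calibration

The camera has no absolute calibration. Instead, the total counts
$C$ of the 1 h SPECT are tied to the known injected activity
$A_\mathrm{inj}$, decay-corrected to the acquisition time (the 1 h
scans precede any urination, so the whole injected activity is still in
the body), weighted by the fraction of activity inside the limited
axial SPECT field of view (FAF):

$$ \mathrm{cf} = \frac{C}{A_\mathrm{inj}\,e^{-\lambda t_\mathrm{acq}}\cdot \mathrm{FAF}},
\qquad \mathrm{FAF} = \frac{\text{planar counts inside the projected FOV}}{\text{total planar counts}}. $$

The FAF comes from the 1 h whole-body planar image with the SPECT FOV
projected onto it as an axial band (nearest-pixel rounding of the band
boundaries; no attenuation weighting — the definition is a pure count
ratio). The calibration factor is expressed in counts per MBq for the
fixed-duration acquisition; dividing by the acquisition duration in
seconds gives cps/MBq. Later time points inherit the 1 h factor.

# Kinetics and time-integrated activity

For a VOI $h$, $A_h(t) = \sum_{x \in h} A_x(t)$, with the voxel-level
dispersion reported as the *population standard deviation* of the voxel
values. (A literal reading of the dispersion as
$\sqrt{\sum A_x^2 - A_h^2}$ with $A_h$ the sum is negative for any
multi-voxel VOI; the population SD is the only non-degenerate reading
of "activity heterogeneity within the VOI" and is what the fit weights
use.)

Lesions use the **peak** metric (analogue of PET SUV-peak): frames are
convolved with a spherical mean kernel of 1 cc (radius
$(3\cdot1000/4\pi)^{1/3} \approx 6.2$ mm), the per-frame argmax
positions inside the lesion are averaged into one fixed centre, and the
curve is the sphere mean at that centre. The method assumes the peak
location is stable over time; the centre-position SD is returned so
that assumption can be checked (on synthetic hot spots it is well below
the voxel size; noise moves it by a few mm).

TIA is computed in two steps:

* **Trapezoid** over the measured curve on $[0, t_\mathrm{last}]$ with
  $A(0)=0$ prepended — activity is injected at $t=0$, so the uptake
  segment is a straight line from the origin to the first sample.
* **Analytic tail** $\frac{A_0}{\lambda}e^{-\lambda t_\mathrm{last}}$
  from a weighted Levenberg–Marquardt fit of $A_0 e^{-\lambda t}$
  (`minpack.lm::nlsLM`, at most 100 iterations, weights $1/\mathrm{SD}$
  with SDs floored at $10^{-6}$ of the curve maximum) to the selected
  tail points.

Tail-point selection: the last three measured points, unless the curve
maximum falls at or after the third-from-last point, in which case only
the last two are used (a decay is never fitted through a rising
segment). If the final point still exceeds its predecessor, an
artificial point is appended at $t_\mathrm{last} + 60$ h with half the
maximum activity to force a decreasing tail; the event is logged and
flagged. The "+60 h" reading is deliberate: an absolute 60 h would
precede the last measurement and could not terminate a rising curve. A
two-point tail that does not decay is flagged degenerate and falls back
to the physical decay constant of the current radionuclide context — a
conservative physical floor.

**Decay substitution.** Assuming identical biological kinetics for both
members of the pair, each measured activity is multiplied by
$e^{(\lambda_\mathrm{In}-\lambda_\mathrm{Y})t}$ (decay-correct to the
biological curve, then re-decay with Y-90) *before* tail fitting and
integration; substituting the whole curve (not only the tail) keeps the
trapezoid part consistent with the therapy decay. The Y-90 half-life is
bundled as 64.05 h from standard nuclear data.

**Voxelwise TIA** applies the same selection/fit/integration rules per
voxel, vectorised by grouping voxels by selection case; voxel fits are
unweighted (a single voxel has no within-VOI SD). Two guards keep the
map robust: voxels whose curve maximum is below $10^{-6}$ of the image
maximum get a zero tail (QC flag 3), and a fitted tail half-life longer
than ten times the physical half-life — which at realistic lung-level
counts is always fit noise, and whose analytic tail would dominate the
organ total — falls back to the physical decay constant (QC flag 2).
The per-VOI route and the voxel route agree to $10^{-6}$ relative on
noise-free single-voxel phantoms (tested).

Effective half-lives are reported as $\ln 2/\lambda$ from the
imaging-radionuclide fit; for a region with biological clearance
$\lambda_b$ the analytic value is $\ln 2/(\lambda_b + \lambda_\mathrm{phys})$.

# Absorbed dose

The TIA map (MBq h per voxel, per injected MBq) is converted to a
number of disintegrations ($3.6\times10^9$ per MBq h) and used as the
source map of a beta transport simulation written for this package:

* emission voxel sampled proportional to TIA, position uniform inside
  the voxel (avoids grid artifacts), direction isotropic;
* energy from the bundled Y-90 spectrum by inverse-CDF sampling;
* straight-line continuous-slowing-down transport: the electron's
  residual water-equivalent range decreases by $\rho\,ds$ per geometric
  step (default 1 mm; range scales as $1/\rho$, densities floored at
  0.001 g/cc so ranges stay finite in air), and the energy released
  over a step — the difference of the range–energy table at the old and
  new residual range — is deposited in the current voxel. Because
  deposits telescope along the track, deposited + escaped energy equals
  emitted energy to rounding, which the tests assert to $<0.1\%$.

The water range–energy table is built at run time by integrating the
Berger–Seltzer collision stopping power (mean excitation energy 75 eV,
$Z/A = 0.55509$); it reproduces reference water CSDA ranges to about 1%
over 0.1–2.3 MeV. Radiative (bremsstrahlung) losses are not
transported — at Y-90 energies they are a percent-level effect in soft
tissue and their photons mostly leave the body; the corresponding
energy simply stays on the electron track. The rare 2.186 MeV/511 keV
photon emissions of Y-90 ($<0.01\%$ yield) are neglected entirely. The
CT is mapped to density only (piecewise-linear anchors at air, lung,
adipose, water, muscle and bone); elemental composition is
unobservable in this transport model, so a full stoichiometric
calibration would add nothing.

A closed-form **local-deposition mode** (each disintegration deposits
the spectrum's mean energy, 942.3 keV from the bundled table, in its
source voxel) serves as the analytic reference: under charged-particle
equilibrium the two modes agree, and the test suite verifies this in
the interior of a uniform cube within three batch standard errors.

The statistical uncertainty is estimated from history batches (default
10): per-voxel relative standard errors, plus an optional region tally
(`tallyMask`) that gives a proper Monte Carlo error bar for a VOI mean
dose (per-voxel errors cannot be combined into one without the
between-voxel covariance). The per-voxel uncertainty summary follows
the convention of reporting the maximum among voxels above 25% of the
maximum dose. Mean VOI dose is mass-weighted: total deposited energy in
the VOI divided by total VOI mass.

The Y-90 spectrum fixture is computed from Fermi beta-decay theory for
the unique first-forbidden $2^- \to 0^+$ transition ($Q = 2280.1$ keV,
$Z = 40$ daughter): relativistic point-charge Fermi function, shape
factor $q^2 + p^2$, Wilkinson finite-nuclear-size correction and the
order-$\alpha$ Sirlin radiative correction. Its tabulated mean,
942.3 keV, is within 1% of the 933.7 keV reference value for this
spectrum; each correction term moves the mean toward the reference and
is standard nuclear physics rather than a fitted adjustment.

# Lesion grading

Grades 0–IV compare a lesion metric (default: transport mean absorbed
dose) to the mediastinal blood pool and the liver: 0 below 20% of
mediastinum, I below 80%, II between 80 and 120% of mediastinum, III
above 120% of mediastinum and below 80% of liver, IV above 120% of
liver. Two boundary conventions are made explicit: inequalities are
strict and evaluated in the order 0, I, II, III, IV; and the
80–120%-of-liver band above the mediastinal threshold, which the scale
leaves unassigned, maps to grade III (grade IV strictly requires more
than 120% of liver) and is flagged. `concordance()` compares visual and
computed grade lists into a discordance count and a 5×5 confusion
matrix. A reference grading table of 19 lesions ships as a plain-text
fixture; one typographically garbled row is documented in the file
header, and the unambiguous invariant — exactly five discordant
lesions, all with a computed grade below the visual one — is what the
tests key on.

# The synthetic phantom

`defaultPhantomSpec()` describes a compact torso (ellipsoid semi-axes
95 × 70 × 160 mm) with lungs, heart (the mediastinal blood-pool
reference), liver, spleen, kidneys, an L2–L4 vertebral bone-marrow
block, and eight spherical lung lesions of 12–28 mm diameter. Grids
follow the acquisition geometry: CT at 0.976562 × 0.976562 × 1.25 mm
(voxel volume 1.19 mm³), SPECT at 4.18 mm isotropic, six acquisitions
at 1, 5, 24, 48, 72 and 144 h. The axial FOV (260 mm) covers all organs
but not the caudal body, so the FAF is below 1 by a known amount.

Kinetics are region-piecewise-constant so closed forms exist:
$A_r(t) = f_r A_\mathrm{inj}(e^{-\lambda_b t} - e^{-\lambda_u t})e^{-\lambda_\mathrm{phys} t}$,
giving $\tilde A_r = f_r A_\mathrm{inj}[(\lambda_b+\lambda_\mathrm{phys})^{-1} - (\lambda_u+\lambda_\mathrm{phys})^{-1}]$.
Defaults emulate antibody biodistribution: liver uptake peaking near
19 h (between the 5 h and 24 h acquisitions), fast blood-pool clearance
from the heart, monotone washout for the other organs, lesions peaking
around 24–48 h. Uptake fractions put a quarter of the injected activity
in the liver at peak; everything the explicit regions do not hold stays
in a circulating **remainder** compartment (mass balance), so the
whole-body activity is exactly the injected activity under physical
decay — the premise of the calibration — and the tracer is never
excreted. Consequently at $t = 0$ the explicit regions are empty and
the remainder holds everything, and the whole-body effective half-life
equals the physical one. The lungs shape anatomy, kinetics and density
but are not quantified VOIs (organ dosimetry in this setting is for
liver, spleen, heart, kidneys and bone marrow; lungs only host the
lesions).

Because the phantom body holds the full injected activity in 4.5 L
instead of a patient's ~70 kg, absolute concentrations and absorbed
doses per injected MBq are an order of magnitude higher than clinical
values; recovery tests compare against the phantom's own closed forms,
and only ratios (lesion grading) should be read as clinically shaped.

What the generator does and does not emulate: it produces
reconstructed-like images directly (Gaussian system blur, default FWHM
10 mm, Poisson counting noise, limited FOV) — there is no
projection-domain simulation, scatter window, attenuation or
reconstruction artefact; anatomy is ellipsoids; kinetics have no
intra-organ gradients (a `hotspot` option adds a Gaussian bump for
peak-localisation tests). Recovery tests therefore demonstrate the
correctness of the estimation chain under its own assumptions, not
robustness to reconstruction physics. In particular the end-to-end
recovery checks run blur-free: the pipeline contains no partial-volume
correction (the clinical acquisition relied on resolution-recovery
reconstruction), so with a 10 mm PSF small organs are under- and lungs
over-estimated — that behaviour is visible but is not a recovery claim.

# Problem sizes and numerical choices in the tests

The test suite runs the full pipeline on the default phantom
(63 × 34 × 63 SPECT FOV grid, ~135k voxels) with $10^6$ transport
histories — a few seconds per run on one core; energy-conservation and
equilibrium checks use $10^6$ and $4\times10^5$ histories on water
cubes. Monte Carlo assertions use batch standard errors (3 SE), CLT or
Kolmogorov–Smirnov bounds rather than fixed fudge factors. Determinism
is asserted bitwise for fixed seeds: the transport kernel draws from
R's RNG stream, so `set.seed` reproduces entire studies and dose maps.

Known limitations: straight-line CSDA ignores multiple scattering (dose
kernels are slightly too long-ranged and forward-peaked); no
bremsstrahlung transport; density-only tissue model; no registration
algorithm (deformation fields are inputs; identity is accepted); no
projection-domain SPECT physics; the grading fixture reflects a single
study's lesions.
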