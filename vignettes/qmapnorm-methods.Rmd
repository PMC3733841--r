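---
title: "Normalized quantitative MRI brain mapping with qmapnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized quantitative MRI brain mapping with qmapnorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmapnorm)
```

## The problem

Conventional MRI contrast is relative: the same tissue produces different
intensities across scanners, coils and sessions, so deviating tissue can only
be judged qualitatively. Quantitative MRI (qMRI) instead measures physical
tissue parameters directly — the longitudinal relaxation rate $R_1 = 1/T_1$
(s$^{-1}$), the transverse relaxation rate $R_2 = 1/T_2$ (s$^{-1}$) and the
proton density PD (% of pure water at 37 °C). Once every brain is mapped into
a common stereotactic space, these absolute values can be averaged across a
healthy cohort into voxelwise *reference maps*, and a single patient's maps
can be tested voxel by voxel for significant deviation from the group.

`qmapnorm` implements this chain end to end:

1. **Relaxometry** — fit $R_1$, $R_2$ and PD per voxel from a multi-delay,
   multi-echo saturation-recovery acquisition.
2. **Synthesis** — compute a synthetic T2-weighted image from the maps.
3. **Normalization** — estimate a 12-parameter affine transform from the
   synthetic image to a template by SSD minimization and apply it to the
   quantitative maps, re-gridding to 2 mm isotropic.
4. **Reference atlas** — voxelwise mean, SD and coefficient of variation
   (CoV = $\sigma$/mean) over the normalized cohort.
5. **Deviation mapping** — normalized difference maps
   $z_p = (p_s - p_\mathrm{mean})/\sigma_p$, significance thresholds from the
   $t$ distribution, and the combined vector-sum magnitude
   $S = \sqrt{z_{R_1}^2 + z_{R_2}^2 + z_{PD}^2}$.
6. **Regional statistics** — atlas-ROI means, age regressions, and brain
   parenchymal / lateral ventricle volume fractions (BPF, LVF).
7. **Digital phantom** — a parametric brain-like simulator that makes every
   stage testable without patient data.

## The signal model and its fit

The acquisition is modelled as an ideal saturation-recovery spin-echo
experiment with complete spoiling and mono-exponential transverse decay:

$$ S(\mathrm{TD}, \mathrm{TE}) \;=\; M_0 \,
   \bigl(1 - e^{-\mathrm{TD}\, R_1}\bigr)\, e^{-\mathrm{TE}\, R_2} $$

with saturation delay TD and echo time TE entered in ms and converted to
seconds once at the boundary. The default protocol uses 4 delays
(100, 400, 1380, 2860 ms), 5 echoes (14, 28, 42, 56, 70 ms) and TR = 2950 ms,
i.e. a 4 × 5 = 20-image matrix per slice. No B1 or saturation-efficiency
correction is attempted: the model is deliberately the reproducible textbook
form. Real saturation pulses are imperfect, so absolute accuracy on scanner
data would require the vendor-specific corrections that are out of scope
here; on the package's own simulator the model is exact by construction.

The per-voxel fit is a variable-projection Levenberg–Marquardt: for any
$(R_1, R_2)$ the optimal $M_0$ is a closed-form linear projection, so only
two parameters are iterated, in log space (positivity is structural, no
constraints needed). Initialization is deterministic — $R_2$ from the
log-linear echo regression at the longest delay, $R_1$ from a Newton solve of
the two-point recovery ratio — and the iteration stops at $10^{-8}$ relative
parameter change or 200 iterations. The objective is smooth and unimodal over
the physiological range ($R_1 \in [0.2, 2]$, $R_2 \in [2, 20]$ s$^{-1}$), so
no restarts are used and the whole fit is reproducible bit for bit. Voxels
with unusable signal are flagged with NaN plus a validity mask — never
silently zeroed — and the normalized RMS misfit is kept as a per-voxel
quality map.

PD calibration maps the median $M_0$ inside a free-water reference region to
100 %. The package's choice of reference is ventricular CSF, the only
free-water pool reliably present in every head; note that CSF's true PD is
slightly below pure water, so this convention carries a known scale factor of
roughly 100/94.3 relative to a pure-water phantom. The phantom simulator
defines its $M_0$ directly on the PD-percent scale, so fits of simulated data
are already calibrated and the pipeline leaves calibration optional
(`calibrate = "none"` by default in `runConfig()`).

## Synthetic contrast and smoothing

Registration needs a source image with conventional T2-weighted contrast;
it is synthesized from the fitted maps with the spin-echo equation
$S = \mathrm{PD}\, e^{-\mathrm{TE}\,R_2}\,(1 - e^{-\mathrm{TR}\,R_1})$ at
TE = 100 ms, TR = 4500 ms (an inversion-recovery variant is available but off
by default). Whether the original contrast used a spin-echo or
saturation-recovery readout is not critical: only the relative tissue
ordering matters for SSD registration, and CSF is by far the brightest class
at these settings under either form.

Both the synthetic image and the template are smoothed with the same 8 mm
FWHM Gaussian before registration so that the two sides carry comparable
spatial frequency content. Smoothing is separable with the kernel specified
in mm and converted per axis (anisotropic voxels are honoured), with
replicate-edge boundaries — zero padding would darken the brain rim and bias
the SSD toward shrinking transforms. A masked normalized-convolution variant
is available so NaN-flagged voxels never bleed into their neighbours.

## Affine normalization

The transform is the standard 12-parameter affine — translation (mm),
rotation (rad), zoom and shear — composed as
$T\,R_z\,R_y\,R_x\,\mathrm{Shear}\,\mathrm{Zoom}$ acting on world (mm, RAS)
coordinates. The convention string is stored in every transform file, and
params → matrix → params round-trips to $10^{-9}$.

Estimation minimizes the mean squared difference between the
intensity-standardized source (resampled through the transform) and template,
over the template's Otsu-derived foreground mask, with a multiresolution
pyramid at 8, 4 and 2 mm. The optimizer is BFGS with an analytic gradient
obtained by the chain rule through the trilinear interpolation weights and
the parameter derivatives of the matrix product above. Initialization is the
identity plus a center-of-mass translation; there are no random restarts, so
registration is deterministic. A final safeguard keeps whichever of
{initialization, optimum} has the lower objective on the finest level, which
makes the "SSD never increases" contract unconditional.

Quantitative maps are resampled with trilinear interpolation; validity masks
and atlas labels with nearest-neighbour (categorical data must not be
averaged). Invalid voxels are zero-filled before trilinear resampling so the
NaN sentinel does not erode the brain rim; edge voxels then carry the same
partial-volume dilution for every subject, which is exactly the variance
source the CoV maps are designed to expose. Out-of-field voxels are NaN.
No affine regularization prior toward typical head sizes is used: the
phantom cohorts are centred and scaled realistically, and the prior's
weighting such toolkits apply is not part of this model.

## Reference atlas and deviation statistics

The atlas stores, per parameter and voxel, the sample mean, the sample SD
with the $n-1$ denominator, and CoV = sd/mean. The $n-1$ choice matches the
significance machinery: a subject drawn independently of a reference group
of $n$ subjects satisfies
$(x - \bar{x})/(s\sqrt{1 + 1/n}) \sim t_{n-1}$, and the package's two-sided
critical value `significanceThreshold(31, 0.05)` = 2.04 (the Gaussian limit
is 1.96). CoV is reported only where the mean exceeds 1 % of the parameter's
cohort-median in-brain value — below that the ratio is numerically
meaningless — and per-voxel subject counts (coverage) are kept so that
partially covered edge voxels use their own degrees of freedom,
coverage − 1, in the threshold.

Deviation maps are signed ($z > 0$ means the subject lies above the
reference mean) and thresholded two-sided; the clinically typical direction
(lower $R_1$, $R_2$, higher PD) is a display convention, not a statistical
one. The vector-sum magnitude $S$ squares the signed components, so it is
invariant under sign flips. Under the null with independent standard-normal
components, $S$ follows the 3-df chi distribution; the tail probability of
$S > 5$ is about $1.3\times10^{-4}$ under that null and about
$5.7\times10^{-7}$ per component under the Gaussian reading. Both tails are
computable via `expectedFalsePositives()`; for a 256 × 256 slice, an
$\alpha = 0.05$ per-voxel test leaves over 3000 chance pixels while a
threshold of 5 leaves fewer than 0.5, which is why the combined map uses 5.
No multiple-testing correction is applied — the expected-false-positive
count is reported instead, and FDR-style control is an explicit non-goal.

## The digital phantom

The phantom is parametric-geometric: a white-matter core inside a cortical
ribbon whose outer surface is sinusoidally folded (amplitude 6 % of the
radius), a subarachnoid CSF shell, paired thalamus/caudate/putamen
ellipsoids, and paired lateral-ventricle ellipsoids whose radii are solved
analytically so the ventricles occupy a target 1.1 % of the intracranial
volume. Geometric primitives give analytic volume oracles; overlaps resolve
by a fixed priority (ventricles > deep nuclei > lesions > white matter >
cortex > CSF shell). Tissue classes carry published in-vivo means and
between-subject SDs (e.g. white matter 1.38/11.79/70.0 with SDs
0.05/0.26/1.0); the CSF class's large nominal SD reflects partial-volume
averaging in vivo, so draws are truncated to physiological ranges.

Between-subject variation has three sources, mirroring what real reference
maps integrate: per-tissue Gaussian draws of the class values (published-scale
SDs), voxelwise within-tissue texture (half the class SD — within-ROI
heterogeneity so that voxels are not perfectly correlated within a
subject), and affine anatomical jitter. Acquisition noise is additive
Gaussian on magnitude images (clipped at zero) by default, with a Rician
option; at brain SNR the two agree to better than 1 %, which is the regime
where the Gaussian fitting assumption is sound. Lesions are spheres confined
to white matter with MS-like contrast — $R_1 - 0.35$, $R_2 - 3.0$ s$^{-1}$,
PD + 10 % relative to white matter — chosen from typical in-vivo lesion
relaxometry; this is several times the per-voxel reference SD, so detection
at $S > 5$ is expected and observed.

All randomness flows from named seeds through one seeding helper; a cohort
directory regenerated from the same master seed is byte-identical.

What the phantom does *not* emulate: realistic cortical folding complexity,
bias fields, motion/ghosting artifacts, partial-volume tissue mixtures
beyond interpolation, or nonlinear anatomical variability. Passing tests
therefore demonstrate the statistical machinery and the affine pipeline, not
robustness to every property of scanner data.

## Validation design and problem sizes

The package validates itself on simulated cohorts at three grid scales,
chosen as a deliberate trade-off between Monte-Carlo stability and run time:

- **4 mm (24 × 28 × 22)** for unit-level round trips and the 100-replicate
  age-slope recovery (injected frontal-WM-like decline of −0.004 s$^{-1}$
  per year over ages 26–67; the 95 % CI covers the truth in ≈ 93 % of
  replicates).
- **3 mm (32 × 38 × 30)** for the statistical cohorts: a 31-subject fitted
  reference atlas, 50 held-out subjects whose per-parameter $|z|$ exceedance
  at the 2.04 threshold averages ≈ 0.05 (individual subjects scatter widely
  because the tissue-level draw moves all voxels of a class together — an
  intended feature of the generator), and lesion patients whose lesion
  voxels show $S \approx 11$.
- **2 mm (48 × 58 × 44)**, the default and the normalized-output grid, for
  registration: 20 random affine perturbations (|rotation| ≤ 10°, zoom
  0.9–1.1, |translation| ≤ 10 mm, |shear| ≤ 0.1) are recovered to well under
  one voxel mean in-brain displacement.

Statistical cohorts are generated without anatomical jitter and compared on
the shared grid, isolating the deviation statistics from registration error;
registration accuracy is validated separately by the perturbation-recovery
experiments. The CoV edge pattern (low CoV in deep white matter, high in a
shell around the ventricles and at the brain periphery) is reproduced with a
jittered cohort.

## Numerical choices and degenerate inputs

- Rates are stored in s$^{-1}$; protocol times in ms, converted once.
- Unfittable voxels: NaN in all maps + FALSE in the validity mask + a
  diagnostic code (1 = unusable input, 2 = iteration limit).
- Constant (degenerate) registration inputs raise an error before any
  optimization; empty water-reference or intracranial masks are errors.
- The fit's log-space parameters are clamped to $[10^{-3}, 10^{3}]$
  s$^{-1}$ to keep pathological voxels finite.
- Tissue classification thresholds (CSF: PD > 85 %, $R_1 < 0.6$ s$^{-1}$)
  are config-exposed; they separate the phantom's generating values exactly
  and approximate in-vivo free-water boundaries.
- Transform JSON stores full-precision doubles (`digits = NA`), so its
  round trip is exact.

## Known limitations

Affine-only normalization leaves residual anatomical mismatch at cortex and
ventricle boundaries (visible as high CoV there); nonlinear refinement is
future work. The ideal saturation-recovery model omits B1 inhomogeneity and
saturation efficiency, so absolute rates from real scanners will be biased
without vendor correction. The deviation statistics are voxel-marginal; no
spatial or multivariate model is applied. Group-versus-group comparison
(Welch $t$ per voxel) is a straightforward extension but outside the current
surface.
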