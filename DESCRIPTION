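Package: qmapnorm
Title: Normalized Quantitative MRI Brain Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative MRI brain characterization: fitting of
    longitudinal relaxation rate (R1), transverse relaxation rate (R2) and
    proton density (PD) maps from multi-delay multi-echo saturation-recovery
    acquisitions, synthesis of contrast-weighted images from the fitted maps,
    affine spatial normalization to a template by sum-of-squared-differences
    minimization, construction of voxelwise normative reference atlases
    (mean, SD, coefficient of variation) over a cohort, and detection of
    significant single-subject tissue deviations via normalized difference
    (z) maps and their combined vector-sum statistic. Includes a parametric
    digital brain phantom simulator so the whole pipeline can be exercised
    and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'qmapnorm-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'relaxometry.R'
    'synthesis.R'
    'registration.R'
    'reference.R'
    'deviation.R'
    'roi.R'
    'phantom.R'
    'io.R'
    'pipeline.R'
    'show-methods.R'
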