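Package: breathfield
Title: Respiratory-Trace-Based Correction of Breathing-Induced B0
    Fluctuations in Multi-Shot Spinal Cord MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Retrospective correction of breathing-induced B0 field
    fluctuations in multi-shot T2*-weighted spinal cord MRI. A short
    phase-sensitive FLASH calibration scan is used to fit, per axial slice,
    a linear coupling between a respiratory bellows trace and the field
    offset inside the spinal cord. During later scans the field is predicted
    from the trace and removed by demodulating the acquired k-space data
    before image reconstruction. Includes Cartesian CG-SENSE and FFT
    reconstruction, EPI reference-line (odd/even) phase correction,
    voxel-wise monoexponential T2* mapping, temporal SNR maps, a ghosting
    metric, and a full acquisition simulator (digital cervical-cord phantom,
    quasi-periodic respiratory trace, multi-echo gradient-echo and 4-shot
    interleaved EPI) that retains ground truth so the whole pipeline can be
    validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
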