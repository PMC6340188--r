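Package: fetalflow
Title: Simulation, Reconstruction and Quantification of Fetal 4D Flow
    Phase-Contrast CMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for volumetric, cardiac-resolved phase-contrast (4D flow)
    velocity data in the fetal circulation. Provides an analytic pulsatile
    flow phantom on a fetal-like vessel network (umbilical vein, ductus
    venosus, caval veins, foramen ovale, great arteries and the ductus
    arteriosus) with exact flux oracles and MR phase encoding at multiple
    velocity encodings (VENCs); reconstruction of wrapped multi-VENC phase
    volumes into corrected velocity fields (static-tissue background phase
    correction, temporal-spatial phase unwrapping, dual-VENC merging,
    PC angiogram segmentation); through-plane flow quantification with
    combined ventricular output, flow distribution, and conservation-of-mass
    consistency checks; Bland-Altman method comparison; and pathline
    integration with source-to-sink streaming quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
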