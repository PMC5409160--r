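Package: swei4d
Title: Multidimensional Directional Filtering and Shear Wave Speed
    Reconstruction for Shear Wave Elasticity Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shear wave elasticity imaging (SWEI) processing on
    4-D (x, y, z, t) axial-displacement volumes. Includes a seeded synthetic
    wavefield generator for Gaussian acoustic radiation force impulse (ARFI)
    excitations in phantoms with a spherical inclusion (incident, transmitted
    and impedance-scaled reflected shear waves), 2-D/3-D/4-D Fourier-domain
    directional filters that separate waves by propagation direction, 2-D and
    3-D time-of-flight shear wave speed reconstruction by normalized
    cross-correlation with parabolic subsample lag estimation and
    correlation/distance-weighted component fusion, and lesion image-quality
    metrics (contrast-to-noise ratio and within-lesion percent bias).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
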