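Package: resmyo
Title: Residually Stressed Passive Myocardium Mechanics at Cylinder Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constitutive modelling of passive ventricular myocardium with
    residual stress. Implements the Holzapfel-Ogden orthotropic strain-energy
    function extended with residual-stress invariants (simple and extended
    formulations), two estimators of the residual Cauchy stress in the
    unloaded left-ventricular wall (from measured transmural Euler-Almansi
    residual strains, and by the opening-angle method for a radially cut
    ring), a desk-scale residually stressed thick-walled-cylinder surrogate
    of the left ventricle inflated through diastolic pressures, and a
    backward-displacement fixed-point recovery of the unloaded configuration
    from a loaded geometry. All profile-level interfaces take and return
    tibbles; fitted objects have tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
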