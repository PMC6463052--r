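Package: oftflow
Title: Embryo-Specific Outflow Tract Hemodynamics from Non-Gated 4-D Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a beating embryonic heart outflow tract from
    non-gated cross-sectional image sequences and computes its hemodynamics.
    Provides a synthetic phantom generator emulating 4-D optical coherence
    tomography acquisition of a peristaltically deforming tube with paired
    Doppler (beam-axis) velocity planes; cardiac-cycle synchronization by
    string-length period estimation, m-mode pooling, circular phase alignment
    and cumulative-phase smoothing; radial edge-based lumen segmentation;
    structured hexahedral O-grid tube meshing with smooth inlet/outlet
    extensions; a quasi-steady incompressible viscous flow solver (mixed
    Q1-Q1 stabilized finite elements) with traction boundary conditions and
    an inverse loop fitting the inlet traction to measured velocities; and
    hemodynamic post-processing: wall shear stress vectors, oscillatory shear
    index, flow rates, forward/backward flow volumes, stroke volume, cardiac
    efficiency, area-motion matrices and unrolled endocardium maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    dplyr,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
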