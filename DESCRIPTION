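Package: valveverify
Title: Verification Toolkit for Aortic-Valve Fluid-Structure Interaction
    Models Against Mock-Loop Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for verifying aortic-stenosis
    fluid-structure interaction (FSI) models against bench mock-loop
    experiments. Generates synthetic mock-loop data (cyclic transvalvular
    pressure and flow traces, endoscope-like frame stacks, 3D leaflet point
    clouds) with known ground truth; computes haemodynamic statistics
    (cycle averaging, ejection-window mean flow and pressure drop, stroke
    volume, inter-cycle variability, measurement-uncertainty bounds);
    extracts aortic valve area from video frames (threshold, morphology,
    two-largest-components) and from projected 3D leaflet meshes
    (150x150 rasterisation with resolution envelopes); implements a 2D
    partitioned FSI scheme (fractional-step incompressible Navier-Stokes
    with ALE mesh motion, Neo-Hookean solid with implicit Newmark
    integration, strong coupling with line search and added-mass
    stabilisation, Smagorinsky eddy viscosity and the Pope LES quality
    criterion); calibrates leaflet shear modulus by stroke-volume matching;
    and assembles the simulation-versus-experiment comparison table with
    symmetric percent errors and within-uncertainty flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
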