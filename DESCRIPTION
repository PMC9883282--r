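Package: veinpress
Title: Central Venous Pressure Estimation from Force-Coupled Ultrasound of the Internal Jugular Vein
Version: 0.1.0
Authors@R: person("veinpress", "developers", role = c("aut", "cre"), email = "dev@example.org")
Description: Tools for estimating central venous pressure (CVP) from
    force-coupled ultrasound compression sweeps of the internal jugular
    vein (IJV). Provides synthetic cine/force phantoms with known
    ground-truth pressure and lumen area, synchronization of force traces
    to ultrasound frames by event alignment of an optical-flow position
    signal, multi-stage lumen segmentation (region growing, radial
    gradient refinement, shape optimization, periodic spline contour),
    collapse-force estimation with cardiac-cycle and segmentation
    uncertainty components, calibration of collapse force against jugular
    venous pulsation height with Bland-Altman agreement and tilt/Valsalva
    perturbation summaries, and inverse estimation of a venous-pressure
    waveform by downhill-simplex optimization of a collapsible-tube
    forward model against segmented areas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
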