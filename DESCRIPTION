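Package: cbctmotion
Title: Motion-Induced CT Number Artifacts in Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of how one-dimensional target motion
    distorts CT number (Hounsfield unit) distributions in cone-beam computed
    tomography. Implements a first-order projection-occupancy model in which
    each projection deposits a constant CT number increment into the imaging
    window containing the displaced voxel, a continuous-time occupancy
    oracle, profile metrics (support extent, elongation, level drop,
    splitting, percentage normalized root mean square difference), inverse
    estimation of motion amplitude from blurred profiles, a synthetic
    measured-profile generator, motion-parameter sweep runners, and profile
    CSV / configuration / coronal-rendering input-output with a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
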