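Package: ttfplan
Title: Tumor Treating Fields Array-Layout Planning on Voxel Head Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and comparison of Tumor Treating Fields (TTFields)
    transducer-array configurations for posterior fossa tumors. Generates
    synthetic voxelized head phantoms with a dorsal midline cerebellar tumor,
    places 3x3 transducer-disc arrays on the scalp for seven named montages,
    solves the 200 kHz quasi-static volume-conductor problem with a voxel
    finite-volume discretization and preconditioned conjugate gradients, and
    summarizes the resulting electric-field and current-density distributions
    as volume histograms (EVH/CDVH) and plan-quality metrics (field-volume
    AUC, percentile intensities, volume-at-threshold) over tumor and
    cerebellum regions of interest. Includes cross-configuration comparison
    reports and anatomy/field overlay export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    png,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
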