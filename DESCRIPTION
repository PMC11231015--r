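Package: sonocomplete
Title: Ultrasound-Consistent Occlusion Simulation and Probabilistic Shape
    Completion for Lumbar Vertebrae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for completing occluded three-dimensional vertebra shapes
    from ultrasound-like partial views. Provides a physics-based synthetic
    occlusion generator (incidence-angle-aware ray-casting, acoustic
    shadowing, scattering emulation, per-vertebra masking and neighboring
    cloud fusion), a probabilistic coarse-to-fine point-cloud completion
    model (dual-path variational encoder with a relational multi-scale
    refiner, trained with a Kullback-Leibler plus Chamfer composite loss),
    anatomy-aware evaluation metrics (Chamfer distance, Earth Mover's
    Distance, F-score, spinous-process centerline distance, facet-joint
    center distance), mesh and point-cloud input/output in standard formats,
    procedural lumbar-spine fixtures, rigid spine-curvature augmentation,
    and Poisson surface reconstruction for visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
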