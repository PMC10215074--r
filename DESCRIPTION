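Package: tkaplan
Title: Pre-Operative Implant Position Planning for Total Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based pre-planning of femoral and tibial component
    position in cruciate-retaining total knee arthroplasty. Provides a
    quasi-static rigid-body model of unloaded knee extension (60 to 0 degrees)
    with eight ligament bundles and per-condyle articular contact, tibiofemoral
    kinematics in the Grood-Suntay joint coordinate system, a nine-parameter
    implant placement model relative to mechanical alignment, five surgical-target
    objective functions comparing post-operative to pre-diseased kinematic and
    ligament-strain curves, a CMA-ES search over the placement space with
    clinically-motivated optimum selection, a synthetic-patient generator for
    end-to-end benchmarking, and RMSD-based reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
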