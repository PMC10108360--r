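Package: membscreen
Title: Orientation-Based Membrane Screening of C1-Domain Ligand Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and screening analysis for molecular-dynamics
    trajectories of ligand candidates embedded in lipid bilayers. Computes
    tilt-angle/depth population heat maps, partial mass-density profiles along
    the membrane normal, geometric hydrogen-bond statistics, Shrake-Rupley
    solvent-accessible surface areas and transient ligand-cluster time series,
    with time-block error estimation, and classifies each candidate's membrane
    orientation as correct (hydroxy group toward the lipid-water interface) or
    incorrect (flipped, buried). Includes a synthetic bilayer-trajectory
    generator with known ground truth so the full pipeline is testable without
    running molecular dynamics, plus readers and writers for GRO coordinate
    frames and NDX index groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
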