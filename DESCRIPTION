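Package: nasoaero
Type: Package
Title: Lagrangian Aerosol Transport and Olfactory Dosimetry in Bi-Directional Nasal Airflow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale Euler-Lagrange modelling of aerosol delivery through a
    bi-directional (one nostril in, other nostril out) nasal flow path. Builds
    parameterized synthetic nasal-surrogate geometries (watertight triangulated
    surfaces with labelled wall regions including olfactory patches),
    voxelizes them into structured flow grids, prescribes steady or pulsatile
    (45 Hz sinusoidal) duct flows, transports Lagrangian parcels with
    Schiller-Naumann drag and gravity using an exact per-substep integrator,
    detects stick-on-touch wall deposition, accumulates the two-way-coupling
    momentum source, evolves a passive ventilation tracer, and provides
    localized dynamic k-equation subgrid-scale diagnostics and an LES
    resolution-quality index. Endpoints are regional deposition efficiency,
    dose per epithelial area, right/left and steady/pulsatile ratio tables,
    impaction-parameter curves and mass-balance audits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
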