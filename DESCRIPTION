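Package: helixpmf
Title: Potential of Mean Force and Ion-Atmosphere Analysis for Parallel
    Nucleic Acid Helices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-simulation analysis toolkit for ion-mediated interactions
    between two parallel double-stranded nucleic acid helices.  Builds
    reduced-representation fiber-model A-RNA, B-DNA and A-DNA duplexes,
    estimates mean forces from pseudo-spring separation time series and
    integrates them into potentials of mean force (with an umbrella
    sampling/WHAM cross-check), analyses the surrounding ion atmosphere
    (cylindrical radial concentration profiles, groove partitioning,
    internal/external binding occupancies, 3D charge-density grids,
    ion-bridge detection, water-dipole ordering), calibrates ion numbers
    to target bulk concentrations with a simplified primitive-model Monte
    Carlo, and converts pairwise PMFs into osmotic pressure curves for
    hexagonal aggregates.  Ships synthetic-trajectory generators with
    known ground truth so the whole pipeline is testable without
    cluster-scale molecular dynamics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
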