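Package: tkaremod
Title: Strain-Adaptive Periprosthetic Bone Remodeling Simulation for Total Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates long-term periprosthetic bone remodeling in the proximal
    tibia after cemented total knee arthroplasty over a synthetic subject
    cohort.  Generates parametric proximal-tibia tetrahedral meshes with
    cortical shell and alignment-dependent cancellous density, performs a
    virtual tray-keel-cement implantation, solves linear-elastic finite-element
    models under activity peak loads, advances element densities with a
    strain-adaptive remodeling law (35% lazy zone, free-surface scaled rate,
    30 computer time units per year), projects virtual AP DEXA images, and
    evaluates periprosthetic regions of interest and population statistics
    (two-tailed Z-tests, Pearson correlations, alignment and sex subgroups).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
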