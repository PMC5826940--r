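Package: tdcsim
Title: Forward Modeling of Transcranial Direct Current Stimulation Electric
    Fields and Target Engagement Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the electric field induced in the head by transcranial
    direct current stimulation (tDCS). Segmented volume-conductor head models
    (skin, skull, cerebrospinal fluid, gray matter, white matter, air) are
    represented on voxel grids; sponge electrode montages placed by 10-20
    scalp coordinates inject current, and the quasi-static current
    conservation (Laplace) equation div(sigma grad phi) = 0 is solved with a
    cell-centered finite-volume discretization and a Jacobi-preconditioned
    conjugate gradient solver. From the field the package derives two
    target-engagement measures for a bilateral network of regions of
    interest: peak field magnitude per region and the percentage of network
    volume where the field exceeds a neuronal modulation threshold. Current
    amplitude sweeps, coefficient-of-variation summaries across head models,
    and montage-comparison statistics (one-way ANOVA, Bonferroni-corrected
    pairwise tests, Cohen's d) complete the analysis. Multi-shell spherical
    head phantoms with analytic verification oracles are included so the
    whole pipeline runs without any external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
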