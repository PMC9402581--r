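Package: corallux
Title: Corallite-Scale Light Capture and Photosynthesis Models for Depth-Generalist Corals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric voxel models of corallite-scale coral architecture
    (skeleton, contracted tissue, seawater) for shallow and mesophotic
    Stylophora pistillata morphotypes, Monte Carlo photon transport with
    Henyey-Greenstein scattering to estimate per-voxel fluence rates, a peaked
    photosynthesis-irradiance model scoring light use per tissue voxel, and a
    scenario engine crossing morphotypes, irradiances, optical variants and
    structural knock-outs/trait exchanges. Also provides a synthetic
    morphometric trait-table generator and the matching statistical surface:
    colony-blocked permutation tests, principal coordinates analysis,
    PERMANOVA, SIMPER and Pearson correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
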