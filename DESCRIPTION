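Package: cryosire
Title: Forward Simulation of Cryopreserved Semen Use in a Selected Cattle Breed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time, pedigree-explicit stochastic simulation of a
    closed dairy cattle selection scheme with two negatively correlated
    polygenic traits. Implements the bivariate additive infinitesimal model
    with inbreeding-adjusted Mendelian sampling, simulated estimated breeding
    values at fixed accuracy, truncation selection on the four parent paths,
    exact cohort-wise coancestry propagation, gene dropping and exact expected
    gene contributions, French-style cryobank sampling rules for young bulls,
    and stage-two scenarios in which frozen semen from cryobank bulls is used
    either to redirect the selection goal towards a deteriorated functional
    trait or to restore genetic diversity, with male-line conservation as an
    additional management option. Includes a replicate/experiment layer that
    aggregates trajectories of genetic means, inbreeding and average kinship
    across replicates and computes across-scenario Welch contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
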