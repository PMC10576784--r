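Package: fepbench
Title: Benchmarking Relative Binding Free Energy Predictions and Assay
    Reproducibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying how reproducible experimental relative
    binding free energies (ddG) are across pairs of affinity assays, and for
    scoring alchemical free energy predictions laid out on perturbation
    graphs. Converts measured affinities (Kd, Ki, IC50, pKi) to binding free
    energies, infers graph-consistent per-ligand dG values by weighted least
    squares (cycle closure), computes pairwise and edgewise error metrics
    with weighted aggregation and bootstrap confidence intervals, fits
    heavy-tailed Student-t error models to symmetrized pairwise error
    distributions, and simulates congeneric assay series and perturbation
    graphs with configurable noise, inter-assay offsets and detection-limit
    censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    graphics,
    igraph,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
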