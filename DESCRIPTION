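Package: fatds
Title: Agent-Based Simulation of Fat-Dachsous Polarity and Growth in the Drosophila Wing Disc
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An off-lattice, agent-based simulator of planar cell polarization and
    proliferation in the Drosophila wing imaginal disc. Cells carry discrete pools of
    the protocadherins Fat (Ft) and Dachsous (Ds), phosphorylated or not by the Golgi
    kinase Four-jointed (Fj), and form stochastic phosphorylation-weighted Ft-Ds
    heterodimer bonds with their Delaunay neighbors. A radially decaying, exponentially
    amplifying morphogen drives a Hill-type Ds expression rule whose steep transition
    region (the Ds front) sweeps outward over the growing disc; the asymmetry of each
    cell's bound-Ft distribution sets Dachs polarization and, through an adapting
    growth law, the cell division rate. The package includes genotype and clone
    scenarios, moving and stationary front variants, snapshot input/output, and
    tidyverse-style analysis of radial profiles, smoothed polarization maps, and
    disc-size comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
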