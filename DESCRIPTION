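Package: mdpost
Title: Statistical Post-Processing of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns atomistic molecular dynamics trajectories into
    statistically qualified observables. Provides autocorrelation- and
    block-averaging-based standard errors for scalar observables,
    self-diffusion coefficients from windowed mean-square displacements
    with sub-window error bars, partial radial distribution functions
    under periodic boundary conditions with arbitrary index selections,
    coordination numbers with fixed, RDF-derived, and van der Waals
    cutoffs, geometric hydrogen-bond detection with graph-based network
    statistics, per-frame DBSCAN cluster-dynamics time series,
    farthest-point-sampling subsampling of structure sets, and
    volumetric atomic probability densities. Ships seeded synthetic
    trajectory generators with analytic ground truth and a command-line
    front end reading extended-XYZ trajectories and writing CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
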