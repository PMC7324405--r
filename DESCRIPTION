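Package: ilsflux
Title: Implicit Ligand Sampling Landscapes and Reactive-Flux Analysis of
    Gas Permeation in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps permeation of small apolar diatomics (molecular oxygen in
    particular) through protein matrices. Computes implicit-ligand-sampling
    (Widom test-particle) free-energy landscapes on 3D grids from ensembles
    of aligned configurations, decomposes landscapes into watershed basins
    with saddle points and steepest-descent path networks, builds a
    basin-level Markov model directly from the landscape, and applies
    transition path theory (committors, effective and net reactive fluxes,
    bottleneck pathway decomposition) to rank entry pathways towards a
    target site such as a hydrogenase active centre. Also provides
    explicit-ligand occupancy maps, internalization counting, residue
    mapping along high-flux pathways, OpenDX grid I/O, and synthetic-data
    generators (analytic Gaussian-well landscapes, fluctuating
    Lennard-Jones cavity ensembles, Metropolis ligand walks) that exercise
    every stage with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
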