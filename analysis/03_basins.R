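#!/usr/bin/env Rscript
## Stage 3: watershed decomposition of the cavity landscape.
##
## Every unmasked voxel is linked to its lowest 26-neighbour until a local
## minimum is reached; basins are the attraction regions of the minima.
## Saddle points between neighbouring basins (min-max over boundary voxel
## pairs) and the steepest-descent minima network follow.

library(ilsflux)

land <- read_volumetric("results/cavity_landscape.dx")
thermo <- thermo_params(300)

basins <- watershed(land, thermo)
print(basins)
saddles <- find_saddles(land, basins)
network <- build_network(land, basins, saddles)
print(network)

## deepest minima are the pocket and the channel vestibule
ord <- order(basins$minima$energy)
cat("five lowest minima:\n")
print(basins$minima[ord[1:5], c("basin", "x", "y", "z", "energy")],
      row.names = FALSE)

write_basin_labels(basins, "results/cavity_basins.dx")
write_network_edges(network, land$grid, "results/cavity_network_edges.tsv")
cat("-> results/cavity_basins.dx, results/cavity_network_edges.tsv\n")
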