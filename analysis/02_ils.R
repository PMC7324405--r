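#!/usr/bin/env Rscript
## Stage 2: implicit-ligand-sampling free-energy landscape of the cavity
## ensemble.
##
## O2 is inserted at random positions and orientations in every voxel of a
## 17 x 15 x 15 grid (1 A spacing) covering the cavity and its exterior;
## the Boltzmann-averaged insertion energy over all frames gives the
## potential of mean force per voxel. The exterior is vacuum here, so no
## water referencing is applied (the bulk reference is 0 by construction).

library(ilsflux)

frames <- read_frameset("results/cavity_frames.xyz")
grid <- grid_spec(c(-8.5, -7, -7), 1, c(17, 15, 15))
thermo <- thermo_params(300)

t0 <- Sys.time()
land <- ils_landscape(frames, default_o2_model(), grid,
                      insertions_per_voxel = 100, thermo = thermo,
                      seed = 42L, cutoff = 12)
cat(sprintf("ILS: %d voxels x 100 insertions x %d frames in %.1f s\n",
            n_voxels(grid), length(frames$coords),
            as.numeric(difftime(Sys.time(), t0, units = "secs"))))

land <- apply_energy_cutoff(land, 40)
cat(sprintf("energy cutoff 40 kJ/mol masks %d voxels (protein core/walls)\n",
            sum(land$mask)))
v <- land$values[!land$mask]
cat(sprintf("landscape range: [%.2f, %.2f] kJ/mol; global minimum %.2f\n",
            min(v), max(v), min(v)))
write_volumetric(land, "results/cavity_landscape.dx")
cat("-> results/cavity_landscape.dx\n")
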