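#!/usr/bin/env Rscript
## Stage 1: generate the synthetic study inputs.
##
## Two data sets are produced: (a) a fluctuating 38-atom Lennard-Jones
## "cavity protein" ensemble whose single +x channel and interior pocket
## are known by construction, standing in for the solvent-only MD frames an
## implicit-ligand-sampling run consumes; (b) an analytic two-well
## landscape with a 4:1 Boltzmann population ratio used to validate the
## Metropolis walk and occupancy analyses.

library(ilsflux)
dir.create("results", showWarnings = FALSE)

seed <- 42L

## (a) cavity ensemble: 100 frames, 0.2 A thermal jitter
frames <- make_cavity_frames(n_frames = 100, jitter = 0.2, seed = seed)
write_frameset(frames, "results/cavity_frames.xyz")
cat("cavity ensemble:", length(frames$coords), "frames x",
    nrow(frames$coords[[1]]), "atoms -> results/cavity_frames.xyz\n")

## (b) two-well landscape: wells of equal width, depths differing by
## kT ln 4 at 300 K, so the deep:shallow equilibrium occupancy is 4:1
kT <- 0.0083145 * 300
g2 <- grid_spec(c(0, 0, 0), 1, c(21, 9, 9))
two_well <- make_landscape(g2, list(
  gaussian_well(c(5, 4, 4), depth = 10, width = 1.5),
  gaussian_well(c(15, 4, 4), depth = 10 + kT * log(4), width = 1.5)))
write_volumetric(two_well, "results/two_well.dx")
minima <- attr(two_well, "minima")
cat("two-well landscape minima (analytic):\n")
print(minima)
cat("-> results/two_well.dx\n")
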