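---
title: "Mapping gas permeation: implicit ligand sampling, basin Markov models, and reactive flux"
author: "ilsflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gas permeation: implicit ligand sampling, basin Markov models, and reactive flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilsflux)
```

## The problem

Small apolar diatomics such as molecular oxygen reach buried protein sites
— e.g. the bimetallic active centre of [NiFe]- and [NiFeSe]-hydrogenases —
through transient packing defects rather than a single static channel.
Explicit-ligand simulation rarely samples the deep interior on accessible
timescales, so this package takes the complementary landscape route:

1. **Implicit ligand sampling (ILS).** From an ensemble of ligand-free,
   aligned configurations, the potential of mean force of placing the
   ligand at grid position $r$ is estimated by Widom-style test-particle
   insertion,
   $$\mathrm{PMF}(r) = -k_BT \,\ln \frac{1}{MC}\sum_{m=1}^{M}\sum_{k=1}^{C}
   e^{-\beta\,\Delta E(r_k,\,q_m,\,\Omega_k)},$$
   where $\Delta E$ is the purely van der Waals insertion energy of the
   rigid diatomic at a random position $r_k$ inside the voxel cube with a
   random orientation $\Omega_k$, in configuration $q_m$.
2. **Watershed decomposition.** Each voxel is linked to its lowest
   26-neighbour until a local minimum; basins, inter-basin saddles
   (min–max over adjacent cross-basin voxel pairs), and the
   steepest-descent minima network describe the landscape topology.
3. **Landscape Markov model.** The basin-to-basin transition probability is
   $$T_{ij} = \frac{1}{Z_i\,(3^D-1)}\sum_{x\in i}\ \sum_{\substack{y\in j\\
   y\sim x}} \min\{e^{-\beta E(x)},\,e^{-\beta E(y)}\},\qquad
   Z_i = \sum_{x\in i} e^{-\beta E(x)},$$
   with $D = 3$ (26 neighbours), self-transitions absorbing the row
   remainder, and basin pairs whose saddle energy is $\ge$ 40 kJ/mol
   removed. The symmetric numerator puts the chain in detailed balance
   with $\pi_i \propto Z_i$ exactly.
4. **Transition path theory (TPT).** With the bulk solvent merged into a
   single source state and basins in contact with marked target atoms as
   products, the forward committor, effective flux
   $f_{ij}=\pi_i q^-_i T_{ij} q^+_j$, net flux
   $f^+_{ij}=\max(0, f_{ij}-f_{ji})$, and total reactive flux $F$ rank the
   entry pathways. Flux is per (undefined) lag step: values are comparable
   between systems treated identically, never absolute rates.

## Parameters that matter

| parameter | unit | default | role |
|---|---|---|---|
| temperature | K | 300 | sets $\beta$ everywhere ($k_B$ = 0.0083145 kJ/(mol·K)) |
| grid spacing | Å | 1 | voxel size of all maps |
| insertions per voxel $C$ | – | 400 | ILS sampling effort |
| energy clamp | kJ/mol | $10^4$ | cap on $\Delta E$ before exponentiation |
| saddle cutoff | kJ/mol | 40 | admits transitions with saddle energy strictly below |
| water reference | kJ/mol | 8.30 | $\Delta G_{vac\to wat}$ subtracted to reference maps to solution |
| pathway fraction | – | 0.5 | keep pathways with $\ge$ this fraction of the top pathway flux |
| contact distance | Å | 3.32 | closed-ball contact for product basins and lining residues (Se:O-like) |
| mask sentinel | kJ/mol | 999 | on-disk value of excluded voxels, far above any cutoff |

The default O2 model (`default_o2_model()`: bond 1.21 Å, per-site
$\sigma$ 3.00 Å, $\epsilon$ 0.40 kJ/mol, no charges) is a placeholder in
the range of published two-site models; users studying a specific force
field should supply its parameters. Ligands with partial charges are
rejected rather than treated approximately, because the insertion energy
is van der Waals only.

## Numerical choices

* **Grid convention.** 0-based indices, voxel positions are cell centers,
  linear order is x-fastest. Maps are exchanged as ASCII OpenDX
  (`gridpositions`, z fastest on disk, 3 values per line).
* **Insertion draws.** One uniform position in the voxel cube plus one
  orientation (normalized Gaussian 3-vector) per draw, drawn *freshly for
  every configuration* — i.e. $M\times C$ independent draws per voxel.
  Sharing the same $C$ draws across all frames has the same expectation
  but leaves the per-voxel Monte-Carlo error at the single-frame level no
  matter how many frames enter; independent draws shrink it by
  $\sqrt{M}$, which is what makes $C = 400$ adequate near repulsive
  walls. Voxels whose average Boltzmann factor underflows to zero are
  masked rather than carrying infinities.
* **LJ combination.** Lorentz–Berthelot by default ($\sigma$ arithmetic,
  $\epsilon$ geometric), with `combine = "geometric"` for force fields
  that combine $\sigma$ geometrically. The rule must be stated for any
  oracle comparison to be meaningful.
* **Tie-breaking.** Equal-energy neighbours are resolved towards the
  smallest linear index; a plateau voxel with no strictly lower neighbour
  points to its smallest-index equal neighbour if that index is smaller
  than its own, else it is a minimum. Flat regions therefore drain to a
  single deterministic label. Grid boundaries are hard walls (no
  periodicity); landscapes are expected to be padded with bulk by
  construction.
* **Saddles.** Defined on voxel *pairs* via min–max of
  $\max(E(x), E(y))$ over adjacent cross-basin pairs, recording the
  higher-energy voxel (smaller index on an exact tie). This guarantees
  saddle $\ge$ both minima. Basin adjacency uses the same 26-neighbourhood
  as the descent; the 40 kJ/mol cutoff is applied to the saddle energy.
* **Stationary distribution.** Chain iteration
  $p_{t+1} = p_t T$ to max-change $< 10^{-12}$, verified against the
  invariance relation and detailed balance. The analytic equilibrium of
  the construction is $Z_i/\sum_k Z_k$; the pipeline starts the iteration
  there, because a solvent start can need $\sim 1/\min(T_{ij})$ steps when
  nearly-isolated basins survive the cutoff, while the iteration from any
  start converges to the same limit on a connected chain.
* **Committors.** Direct dense linear solve of the harmonic system, with
  damped fixed-point iteration as fallback for numerically singular
  cases. Under detailed balance $q^- = 1 - q^+$; this identity is used as
  a cross-check, not assumed.
* **Pathway decomposition.** Classic bottleneck removal: repeatedly
  extract the maximum-bottleneck (widest) source→target path and subtract
  its bottleneck from each edge. The decomposed path fluxes sum to $F$.
  Product basins whose retained pathways share at least half of their
  intermediate states (measured against the smaller set) are grouped as
  one entry pathway; this operationalizes the qualitative notion of
  basins "sharing a reactive network" and is our choice, with the
  threshold exposed.
* **Solvent identification.** A basin is bulk-like when its minimum voxel
  touches the outermost voxel layer *and* its minimum energy is within
  2 kJ/mol of the bulk reference (0 after water referencing). Both
  thresholds are configurable and manual designation overrides the rule.
* **Internalization.** A ligand is internal when axis-parallel rays in all
  six directions hit a protein heavy atom within its van der Waals radius
  plus a 1.4 Å probe. This is a deterministic stand-in for
  surface-based burial definitions; its plateau values on real systems
  need not match methods defined differently.

## The synthetic generators

`make_landscape()` builds analytic Gaussian-well fields whose minima (and
hence basins, saddles, Boltzmann ratios) are known exactly.
`make_cavity_frames()` jitters a documented 38-atom Lennard-Jones wall
template — a closed pocket (8-atom rings of radius 3.8 Å) opening through
a narrow constriction (rings of radius 2.8 Å) into a single +x channel —
emulating a fluctuating protein with one engineered entry pathway.
`make_ligand_walk()` runs Metropolis walkers (26-neighbour proposals,
$\min\{1, e^{-\beta\Delta E}\}$ acceptance) whose long-run occupancy is the
Boltzmann distribution of the landscape.

These generators emulate the *structure* of the real inputs (ensembles of
fluctuating repulsive walls, equilibrated ligand positions) but not their
chemistry: no water, no electrostatics, no bonded terms, Gaussian rather
than conformational fluctuations, and a vacuum exterior (so the water
reference is 0 for the cavity demo rather than 8.30 kJ/mol). Passing
tests therefore demonstrate that the algorithms are implemented correctly
— descent, saddles, Eq.-level transition matrices, committors, fluxes,
occupancies all match independent oracles — not that any particular
protein's landscape is reproduced. Reproducing the published hydrogenase
landscapes would require the original multi-hundred-nanosecond MD
ensembles, which are out of scope; the published per-pathway flux table is
instead used as printed input for the percentage computation it feeds.

## Problem sizes used in the shipped analyses

The analysis scripts and the acceptance checks run the cavity system at
100 frames and 100 insertions per voxel on a 17×15×15 Å grid (the
package's demonstration scale; one ILS evaluation takes tens of seconds on
one core), walks of $10^4$–$10^5$ steps, a $10^7$-step chain simulation
for the flux cross-check, and brute-force oracles on grids up to $8^3$.
Production use on real ensembles scales linearly in voxels × frames ×
insertions.

## Known limitations

* Fluxes are per undefined lag step; only ratios and comparisons between
  identically treated systems are meaningful.
* The Markov construction assumes intra-basin pre-equilibration
  (Kramers-style); fine kinetics within wide basins is not resolved.
* Committor/flux linear algebra is dense; state counts beyond a few
  thousand basins would need sparse solvers.
* No electrostatics: ligands with partial charges are out of scope.
* Sub-voxel saddle refinement and transition-state optimization are not
  attempted; saddle energies carry the grid discretization error.
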