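#' Rigid diatomic ligand model
#'
#' Two identical-or-distinct Lennard-Jones sites a fixed bond length apart.
#' Only apolar ligands are supported: partial charges must be zero (the O2
#' models used for permeation studies carry none), and any nonzero charge
#' is an error rather than a silently neglected electrostatic term.
#'
#' @param bond_length Å, > 0.
#' @param sigma per-site LJ sigma, Å (length 1, recycled to both sites, or 2).
#' @param epsilon per-site LJ epsilon, kJ/mol (length 1 or 2).
#' @param charge per-site partial charge, e; must be 0.
#' @return An object of class `diatomic_model`.
#' @examples
#' o2 <- diatomic_model(1.21, sigma = 3.0, epsilon = 0.40)
#' @export
diatomic_model <- function(bond_length, sigma, epsilon, charge = 0) {
  if (!is.finite(bond_length) || bond_length <= 0)
    stop("bond_length must be > 0")
  sigma <- rep(as.numeric(sigma), length.out = 2L)
  epsilon <- rep(as.numeric(epsilon), length.out = 2L)
  charge <- rep(as.numeric(charge), length.out = 2L)
  if (any(sigma <= 0) || any(epsilon < 0)) stop("require sigma > 0, epsilon >= 0")
  if (any(charge != 0))
    stop("nonzero partial charges are not supported: insertion energies are ",
         "purely van der Waals")
  structure(list(bond_length = bond_length, sigma = sigma, epsilon = epsilon,
                 charge = charge), class = "diatomic_model")
}

#' Default O2 ligand parameters
#'
#' A two-site apolar O2 model (bond length 1.21 Å, per-site sigma 3.00 Å,
#' epsilon 0.40 kJ/mol). These are user-supplied placeholder values in the
#' range of published two-site O2 models; studies of a specific system
#' should substitute the parameters of the O2 model their force field uses.
#'
#' @return A [diatomic_model()].
#' @export
default_o2_model <- function() diatomic_model(1.21, sigma = 3.00, epsilon = 0.40)

#' Thermodynamic parameters
#'
#' @param temperature K, > 0. Default 300.
#' @param kb Boltzmann constant, kJ/(mol K); fixed default 0.0083145.
#' @return Object of class `thermo_params` with fields `temperature`, `kb`,
#'   and `beta = 1/(kb*temperature)`.
#' @export
thermo_params <- function(temperature = 300, kb = 0.0083145) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  structure(list(temperature = temperature, kb = kb,
                 beta = 1 / (kb * temperature)), class = "thermo_params")
}

## combined LJ parameters of ligand site s against all frame atoms
combine_lj <- function(sig_atom, eps_atom, sig_site, eps_site,
                       rule = c("lorentz", "geometric")) {
  rule <- match.arg(rule)
  sigc <- if (rule == "lorentz") (sig_atom + sig_site) / 2
          else sqrt(sig_atom * sig_site)
  list(sigma = sigc, epsilon = sqrt(eps_atom * eps_site))
}

#' Ligand insertion energy in one configuration
#'
#' 12-6 Lennard-Jones interaction of the two ligand sites (placed at
#' `position +/- (bond_length/2) * orientation`) with every atom of the
#' frame, using the chosen combination rule (Lorentz-Berthelot by default:
#' arithmetic-mean sigma, geometric-mean epsilon). No cutoff is applied
#' unless one is given, and no shift is added at the cutoff. Near-singular
#' contacts are clamped to `clamp` rather than returning infinity.
#'
#' @param frame numeric matrix (N x 3) of atom positions, Å.
#' @param sigma,epsilon per-atom LJ parameters (length N).
#' @param ligand a [diatomic_model()].
#' @param position numeric length-3 insertion point, Å.
#' @param orientation numeric length-3 unit vector.
#' @param cutoff pair distance cutoff, Å (default `Inf` = none).
#' @param clamp upper energy clamp, kJ/mol. Default 1e4.
#' @param combine `"lorentz"` (default) or `"geometric"` sigma combination.
#' @return Interaction energy, kJ/mol.
#' @export
insertion_energy <- function(frame, sigma, epsilon, ligand, position,
                             orientation, cutoff = Inf, clamp = 1e4,
                             combine = c("lorentz", "geometric")) {
  stopifnot(inherits(ligand, "diatomic_model"))
  combine <- match.arg(combine)
  frame <- rbind2mat(frame)
  if (nrow(frame) == 0L) return(0)
  orientation <- as.numeric(orientation)
  nrm <- sqrt(sum(orientation^2))
  if (abs(nrm - 1) > 1e-6) stop("orientation must be a unit vector")
  half <- (ligand$bond_length / 2) * orientation
  e <- 0
  for (s in 1:2) {
    site <- as.numeric(position) + if (s == 1L) half else -half
    lj <- combine_lj(sigma, epsilon, ligand$sigma[s], ligand$epsilon[s], combine)
    d2 <- rowSums(sweep(frame, 2L, site)^2)
    keep <- d2 <= cutoff^2
    if (!any(keep)) next
    d2 <- d2[keep]
    if (any(d2 < 1e-12)) return(clamp)
    sr6 <- (lj$sigma[keep]^2 / d2)^3
    e <- e + sum(4 * lj$epsilon[keep] * (sr6^2 - sr6))
  }
  min(e, clamp)
}

#' Implicit-ligand-sampling free-energy landscape
#'
#' Widom-style test-particle insertion on a grid: for every voxel, the
#' potential of mean force of placing the ligand there is
#' `PMF = -kb*T * log( (1/(M*C)) * sum_m sum_k exp(-beta * dE(r_k, q_m, O_k)) )`
#' with `C` insertion draws per voxel (position uniform inside the voxel
#' cube, orientation uniform on the sphere; one position paired with one
#' orientation per draw) evaluated in each of the `M` frames. Voxels whose
#' average Boltzmann factor underflows to zero (deeply buried in repulsive
#' walls) are masked. Deterministic under `seed`.
#'
#' @param frames an aligned [frameset()].
#' @param ligand a [diatomic_model()]. Default [default_o2_model()].
#' @param grid a [grid_spec()].
#' @param insertions_per_voxel draws C per voxel, >= 1. Default 400.
#' @param thermo a [thermo_params()].
#' @param seed integer RNG seed.
#' @param cutoff pair distance cutoff, Å (default `Inf`).
#' @param clamp energy clamp before exponentiation, kJ/mol. Default 1e4.
#' @param combine LJ sigma combination rule, `"lorentz"` or `"geometric"`.
#' @return A [scalar_field()] of PMF values referenced to vacuum
#'   (ΔG vac→prot); see [reference_to_water()] for solution referencing.
#' @export
ils_landscape <- function(frames, ligand = default_o2_model(), grid,
                          insertions_per_voxel = 400,
                          thermo = thermo_params(), seed = 1L,
                          cutoff = Inf, clamp = 1e4,
                          combine = c("lorentz", "geometric")) {
  stopifnot(inherits(frames, "frameset"), inherits(grid, "grid_spec"),
            inherits(thermo, "thermo_params"))
  combine <- match.arg(combine)
  if (insertions_per_voxel < 1) stop("insertions_per_voxel must be >= 1")
  if (any(ligand$charge != 0))
    stop("nonzero partial charges are not supported")
  m <- n_frames(frames); n <- n_atoms(frames)
  if (n == 0L) {
    ## no interactions anywhere: dE = 0, PMF = -kT log(1) = 0
    return(scalar_field(grid, rep(0, n_voxels(grid))))
  }
  coords <- do.call(rbind, frames$coords)
  lj1 <- combine_lj(frames$sigma, frames$epsilon, ligand$sigma[1],
                    ligand$epsilon[1], combine)
  lj2 <- combine_lj(frames$sigma, frames$epsilon, ligand$sigma[2],
                    ligand$epsilon[2], combine)
  sums <- withr_seed(seed, {
    ils_sum_cpp(coords, m, n, lj1$sigma, lj1$epsilon, lj2$sigma, lj2$epsilon,
                ligand$bond_length / 2, grid$origin, grid$spacing, grid$shape,
                as.integer(insertions_per_voxel), thermo$beta,
                if (is.finite(cutoff)) cutoff^2 else Inf, clamp)
  })
  avg <- sums / (m * insertions_per_voxel)
  mask <- avg <= 0
  pmf <- rep(0, length(avg))
  pmf[!mask] <- -thermo$kb * thermo$temperature * log(avg[!mask])
  scalar_field(grid, pmf, mask)
}

#' Vacuum-to-water transfer free energy of the ligand
#'
#' The grand average of an implicit-ligand-sampling landscape computed in
#' bulk water: the arithmetic mean over all unmasked voxels. Subtracting it
#' from a vacuum-referenced protein landscape yields the water-referenced
#' landscape (see [reference_to_water()]). When no water landscape is
#' available the package default of 8.30 kJ/mol is returned, the
#' literature value for the apolar two-site O2 model in SPC water at 300 K.
#'
#' @param water_landscape optional [scalar_field()] from a bulk-water run.
#' @return ΔG vac→wat, kJ/mol.
#' @export
water_reference <- function(water_landscape = NULL) {
  if (is.null(water_landscape)) return(8.30)
  stopifnot(inherits(water_landscape, "scalar_field"))
  v <- water_landscape$values[!water_landscape$mask]
  if (!length(v)) stop("all voxels masked in water landscape")
  mean(v)
}
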