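#' Gaussian well specification
#'
#' One isotropic Gaussian depression of a synthetic free-energy landscape:
#' `depth` (kJ/mol, > 0) is subtracted at the center and decays with an
#' isotropic standard deviation `width` (Å).
#'
#' @param center numeric length-3, Å.
#' @param depth well depth, kJ/mol, > 0.
#' @param width isotropic standard deviation, Å, > 0.
#' @return An object of class `gaussian_well`.
#' @export
gaussian_well <- function(center, depth, width) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (!is.finite(depth) || depth <= 0) stop("well depth must be > 0")
  if (!is.finite(width) || width <= 0) stop("well width must be > 0")
  structure(list(center = center, depth = depth, width = width),
            class = "gaussian_well")
}

#' Analytic multi-well landscape on a grid
#'
#' Evaluates `baseline - sum_w depth_w * exp(-|r - c_w|^2 / (2 width_w^2))`
#' at every voxel center. Because the construction is analytic, the true
#' minima are known: they are attached as attribute `"minima"` (one row per
#' well: center coordinates, analytic value at the center) so basin and
#' Markov results can be checked against ground truth.
#'
#' @param grid a [grid_spec()].
#' @param wells list of [gaussian_well()] objects (possibly empty).
#' @param baseline constant energy far from all wells, kJ/mol. Default 0.
#' @return A [scalar_field()] with attribute `"minima"`.
#' @export
make_landscape <- function(grid, wells = list(), baseline = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (inherits(wells, "gaussian_well")) wells <- list(wells)
  centers <- voxel_center(grid, linear_to_ijk(grid, seq_len(n_voxels(grid))))
  vals <- rep(baseline, n_voxels(grid))
  for (w in wells) {
    stopifnot(inherits(w, "gaussian_well"))
    d2 <- rowSums(sweep(centers, 2L, w$center)^2)
    vals <- vals - w$depth * exp(-d2 / (2 * w$width^2))
  }
  fld <- scalar_field(grid, vals)
  minima <- if (length(wells)) {
    data.frame(x = vapply(wells, function(w) w$center[1], 0),
               y = vapply(wells, function(w) w$center[2], 0),
               z = vapply(wells, function(w) w$center[3], 0),
               value = vapply(wells, function(w) {
                 ## analytic value at the center includes tails of other wells
                 v <- baseline
                 for (u in wells)
                   v <- v - u$depth *
                     exp(-sum((w$center - u$center)^2) / (2 * u$width^2))
                 v
               }, 0))
  } else data.frame(x = numeric(), y = numeric(), z = numeric(),
                    value = numeric())
  attr(fld, "minima") <- minima
  fld
}

#' The 38-atom cavity/channel wall template
#'
#' A fixed arrangement of Lennard-Jones spheres forming a closed pocket
#' connected to the exterior by a single channel along +x, used to exercise
#' the whole pipeline with a known ground-truth entry pathway. Geometry
#' (all atoms sigma 3.0 Å, epsilon 0.5 kJ/mol):
#' one back-cap atom at (-5.2, 0, 0); a 7-atom ring of radius 2.6 Å at
#' x = -4.2; two 8-atom pocket rings of radius 3.8 Å at x = -2.2 and 0.8;
#' a 7-atom constriction ring of radius 2.8 Å at x = 2.6; and a 7-atom
#' channel-mouth ring of radius 2.8 Å at x = 4.4. The pocket interior is
#' centred near (-1, 0, 0); the constriction at x ~ 2.6 creates the barrier
#' separating pocket from exterior.
#'
#' @return data.frame with columns x, y, z, sigma, epsilon.
#' @export
cavity_template <- function() {
  ring <- function(n, radius, x, phase = 0) {
    a <- 2 * pi * seq_len(n) / n + phase
    cbind(x = rep(x, n), y = radius * cos(a), z = radius * sin(a))
  }
  xyz <- rbind(
    c(-5.2, 0, 0),
    ring(7, 2.6, -4.2),
    ring(8, 3.8, -2.2),
    ring(8, 3.8, 0.8, phase = pi / 8),
    ring(7, 2.8, 2.6),
    ring(7, 2.8, 4.4, phase = pi / 7)
  )
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             sigma = 3.0, epsilon = 0.5)
}

#' Fluctuating cavity-protein frame ensemble
#'
#' Emulates an ensemble of protein configurations: each frame is the wall
#' template with i.i.d. Gaussian positional jitter of the given amplitude
#' applied to every atom coordinate. Bit-reproducible under `seed`.
#'
#' @param n_frames number of frames M, >= 1. Default 200.
#' @param template data.frame with x, y, z, sigma, epsilon columns
#'   (default [cavity_template()]).
#' @param jitter Gaussian standard deviation per coordinate, Å. Default 0.2.
#' @param seed integer RNG seed.
#' @return A [frameset()].
#' @export
make_cavity_frames <- function(n_frames = 200, template = cavity_template(),
                               jitter = 0.2, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  base <- as.matrix(template[, c("x", "y", "z")])
  n <- nrow(base)
  coords <- withr_seed(seed, {
    lapply(seq_len(n_frames), function(m)
      base + matrix(stats::rnorm(3L * n, sd = jitter), ncol = 3L))
  })
  frameset(coords, template$sigma, template$epsilon)
}

## evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Metropolis ligand random walks on a landscape
#'
#' Each of `n_ligands` walkers moves on voxel centers: at every step one of
#' the 26 neighbouring voxels is proposed uniformly and accepted with
#' probability `min(1, exp(-beta * dE))`; proposals leaving the grid or
#' entering masked voxels are rejected (the walker stays). The long-run
#' voxel occupancy converges to the Boltzmann distribution of the
#' landscape, so these walks stand in for explicit-ligand trajectories.
#'
#' @param landscape a [scalar_field()].
#' @param n_ligands number of independent walkers. Default 10.
#' @param n_steps number of recorded steps per walker. Default 1000.
#' @param temperature K. Default 300.
#' @param seed integer RNG seed.
#' @param start optional integer matrix (n_ligands x 3) of 0-based start
#'   voxels; default: the unmasked voxel of minimum energy for all walkers.
#' @return A `ligand_trajectory`: data.frame (frame, ligand, x, y, z) with
#'   the grid attached as attribute `"grid"`.
#' @export
make_ligand_walk <- function(landscape, n_ligands = 10, n_steps = 1000,
                             temperature = 300, seed = 1L, start = NULL) {
  stopifnot(inherits(landscape, "scalar_field"))
  ok <- !landscape$mask
  if (!any(ok)) stop("all voxels are masked; no walk region")
  g <- landscape$grid
  if (is.null(start)) {
    lin0 <- which(ok)[which.min(landscape$values[ok])]
    start <- linear_to_ijk(g, lin0)[rep(1L, n_ligands), , drop = FALSE]
  }
  storage.mode(start) <- "integer"
  beta <- 1 / (0.0083145 * temperature)
  vox <- withr_seed(seed, {
    metropolis_walk_cpp(landscape$values, landscape$mask, g$shape,
                        start, as.integer(n_steps), beta)
  })
  ijk <- matrix(vox, ncol = 3L)  # n_steps * n_ligands rows, 0-based
  xyz <- voxel_center(g, ijk)
  traj <- data.frame(
    frame = rep(seq_len(n_steps), times = n_ligands),
    ligand = rep(seq_len(n_ligands), each = n_steps),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  traj <- traj[order(traj$frame, traj$ligand), , drop = FALSE]
  rownames(traj) <- NULL
  attr(traj, "grid") <- g
  class(traj) <- c("ligand_trajectory", "data.frame")
  traj
}

#' Write / read ligand walks as tab-separated text
#'
#' Columns: frame, ligand_id, x, y, z (Å).
#'
#' @param traj a ligand trajectory data.frame as from [make_ligand_walk()].
#' @param path output path.
#' @return `path` invisibly (write); the trajectory data.frame (read).
#' @export
write_walk <- function(traj, path) {
  out <- data.frame(frame = traj$frame, ligand_id = traj$ligand,
                    x = traj$x, y = traj$y, z = traj$z)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_walk
#' @export
read_walk <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  traj <- data.frame(frame = d$frame, ligand = d$ligand_id,
                     x = d$x, y = d$y, z = d$z)
  class(traj) <- c("ligand_trajectory", "data.frame")
  traj
}
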