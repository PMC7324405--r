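#' Occupancy probability map of explicit ligands
#'
#' Bins ligand positions into the grid (voxels are cubes around voxel
#' centers) and normalizes per frame: the voxel value is the mean number
#' of ligands found in that voxel per frame, i.e. an occupancy probability
#' directly comparable to volmap-style probability density maps (the
#' conventional display isosurface for such maps is 0.002). Positions
#' outside the grid are counted into a reported overflow fraction, not
#' dropped silently.
#'
#' @param traj ligand trajectory data.frame with columns `frame`, `ligand`,
#'   `x`, `y`, `z` (see [make_ligand_walk()], [read_walk()]).
#' @param grid a [grid_spec()].
#' @param per_volume divide by voxel volume to get a density per
#'   cubic Å instead of a probability. Default `FALSE`.
#' @return A [scalar_field()] of occupancies with attributes
#'   `"n_frames"` and `"overflow"` (mean out-of-grid ligands per frame).
#' @export
pdf_map <- function(traj, grid, per_volume = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  nfr <- length(unique(traj$frame))
  if (nfr == 0L) stop("trajectory has zero frames")
  ijk <- coord_to_index(grid, as.matrix(traj[, c("x", "y", "z")]))
  out_of_grid <- is.na(ijk[, 1L])
  lin <- ijk_to_linear(grid, ijk[!out_of_grid, , drop = FALSE])
  counts <- tabulate(lin, nbins = n_voxels(grid))
  vals <- counts / nfr
  if (per_volume) vals <- vals / prod(grid$spacing)
  fld <- scalar_field(grid, vals)
  attr(fld, "n_frames") <- nfr
  attr(fld, "overflow") <- sum(out_of_grid) / nfr
  fld
}

## standard van der Waals radii by element (Å); fallback 1.7
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
           P = 1.80, FE = 2.00, NI = 1.63)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Per-frame count of internalized ligands
#'
#' A ligand is classified as internal in a frame when axis-parallel rays
#' cast from its position in all six directions (+/-x, +/-y, +/-z) each
#' intersect at least one protein heavy atom within that atom's contact
#' radius (van der Waals radius plus a probe radius). This deterministic
#' enclosure test captures the intuitive "buried on all sides" notion of
#' internalization.
#'
#' @param traj ligand trajectory data.frame (`frame`, `ligand`, `x`, `y`,
#'   `z`).
#' @param protein data.frame of heavy-atom coordinates `x`, `y`, `z`
#'   (static reference), optionally with an `element` column for per-atom
#'   radii.
#' @param probe probe radius added to each atom's van der Waals radius, Å.
#'   Default 1.4.
#' @param radii optional explicit per-atom contact radii (overrides
#'   `element` + `probe`).
#' @return data.frame: `frame`, `n_internal`, `running_mean`.
#' @export
internalization_series <- function(traj, protein, probe = 1.4, radii = NULL) {
  if (!nrow(protein)) stop("protein reference is empty")
  pxyz <- as.matrix(protein[, c("x", "y", "z")])
  if (is.null(radii)) {
    el <- if ("element" %in% names(protein)) protein$element else "C"
    radii <- vdw_radius(el) + probe
  }
  frames <- sort(unique(traj$frame))
  n_int <- vapply(frames, function(fr) {
    sub <- traj[traj$frame == fr, c("x", "y", "z"), drop = FALSE]
    sum(vapply(seq_len(nrow(sub)), function(l)
      is_enclosed(as.numeric(sub[l, ]), pxyz, radii), TRUE))
  }, 0L)
  data.frame(frame = frames, n_internal = n_int,
             running_mean = cumsum(n_int) / seq_along(n_int))
}

## six-ray enclosure test for a single point
is_enclosed <- function(p, pxyz, radii) {
  d <- sweep(pxyz, 2L, p)
  r2 <- radii^2
  for (ax in 1:3) {
    perp <- rowSums(d[, -ax, drop = FALSE]^2)
    hit <- perp <= r2
    if (!any(hit & d[, ax] > 0) || !any(hit & d[, ax] < 0)) return(FALSE)
  }
  TRUE
}
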