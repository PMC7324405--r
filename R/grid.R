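#' Regular 3D grid geometry
#'
#' A `grid_spec` describes a regular, axis-aligned 3D grid. Indexing is
#' 0-based and voxel positions are cell *centers*: the center of voxel
#' (i, j, k) is `origin + c(i, j, k) * spacing`.
#'
#' @param origin numeric length-3, Å; center of voxel (0, 0, 0).
#' @param spacing numeric length-3 (or scalar, recycled), Å per voxel along
#'   each axis; all components must be > 0.
#' @param shape integer length-3 `(nx, ny, nz)`; all components >= 1.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
#' voxel_center(g, c(1, 2, 3))
#' @export
grid_spec <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(shape) == 3L)
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  if (any(spacing <= 0)) stop("grid spacing components must be > 0")
  if (any(shape < 1L)) stop("grid shape components must be >= 1")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing (%g, %g, %g) A, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a [grid_spec()].
#' @return `prod(grid$shape)`.
#' @export
n_voxels <- function(grid) prod(grid$shape)

#' Voxel centers and index mapping
#'
#' `voxel_center()` maps 0-based voxel indices to Cartesian coordinates;
#' `coord_to_index()` is its inverse under nearest-voxel rounding. Both are
#' vectorized over rows.
#'
#' @param grid a [grid_spec()].
#' @param ijk integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @return `voxel_center()`: numeric matrix (n x 3) of coordinates in Å.
#' @export
voxel_center <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  sweep(sweep(ijk, 2L, grid$spacing, `*`), 2L, grid$origin, `+`)
}

#' @param xyz numeric matrix (n x 3) or length-3 vector of coordinates, Å.
#' @rdname voxel_center
#' @return `coord_to_index()`: integer matrix (n x 3) of 0-based indices;
#'   out-of-grid points yield `NA` rows.
#' @export
coord_to_index <- function(grid, xyz) {
  xyz <- rbind2mat(xyz)
  ijk <- round(sweep(sweep(xyz, 2L, grid$origin, `-`), 2L, grid$spacing, `/`))
  bad <- ijk < 0 | sweep(ijk, 2L, grid$shape, `>=`)
  ijk[rowSums(bad) > 0L, ] <- NA_integer_
  storage.mode(ijk) <- "integer"
  ijk
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else {
    x <- as.matrix(x); storage.mode(x) <- "double"; x
  }
}

#' Linear voxel indexing
#'
#' Converts between 0-based (i, j, k) triplets and the 1-based linear index
#' of the x-fastest (column-major) array layout. The linear order also
#' defines the deterministic tie-breaking used by [watershed()].
#'
#' @param grid a [grid_spec()].
#' @param ijk integer matrix (n x 3) or length-3 vector, 0-based.
#' @return `ijk_to_linear()`: integer vector of 1-based linear indices.
#' @export
ijk_to_linear <- function(grid, ijk) {
  ijk <- rbind2mat(ijk)
  as.integer(1L + ijk[, 1L] + grid$shape[1L] * (ijk[, 2L] + grid$shape[2L] * ijk[, 3L]))
}

#' @param lin integer vector of 1-based linear indices.
#' @rdname ijk_to_linear
#' @return `linear_to_ijk()`: integer matrix (n x 3) of 0-based triplets.
#' @export
linear_to_ijk <- function(grid, lin) {
  lin0 <- as.integer(lin) - 1L
  nx <- grid$shape[1L]; ny <- grid$shape[2L]
  cbind(i = lin0 %% nx, j = (lin0 %/% nx) %% ny, k = lin0 %/% (nx * ny))
}

#' 3D scalar free-energy field
#'
#' Couples a [grid_spec()] with one free-energy value (kJ/mol) per voxel and
#' an exclusion mask. Masked voxels are treated as non-existent by all basin
#' and Markov computations: they are never descended into, never joined to a
#' basin, and contribute nothing to partition functions.
#'
#' @param grid a [grid_spec()].
#' @param values numeric array with `dim == grid$shape` (or a vector of
#'   length `prod(shape)` in x-fastest order), kJ/mol.
#' @param mask logical array of the same shape; `TRUE` marks excluded
#'   voxels. Defaults to all-`FALSE`.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(grid, values, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.numeric(values)
  if (length(values) != n_voxels(grid))
    stop("values length does not match grid shape")
  dim(values) <- grid$shape
  if (is.null(mask)) {
    mask <- array(FALSE, dim = grid$shape)
  } else {
    mask <- as.logical(mask)
    if (length(mask) != n_voxels(grid))
      stop("mask length does not match grid shape")
    dim(mask) <- grid$shape
  }
  if (any(!is.finite(values[!mask])))
    stop("non-finite values in unmasked voxels; mask them or clamp first")
  structure(list(grid = grid, values = values, mask = mask),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf("scalar_field: %d x %d x %d voxels (%d masked)\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], sum(x$mask)))
  if (length(v))
    cat(sprintf("  energy range [%.3f, %.3f] kJ/mol, mean %.3f\n",
                min(v), max(v), mean(v)))
  invisible(x)
}

#' Mask high-energy voxels
#'
#' Excludes every voxel whose energy is `>= cutoff` (strictly lower energies
#' are admitted), mirroring the saddle-pair admission rule used when
#' building the Markov model. Already-masked voxels stay masked.
#'
#' @param field a [scalar_field()].
#' @param cutoff finite energy threshold, kJ/mol. Default 40.
#' @return A `scalar_field` with the enlarged mask; the number of newly
#'   masked voxels is attached as attribute `"n_masked"`.
#' @export
apply_energy_cutoff <- function(field, cutoff = 40) {
  stopifnot(inherits(field, "scalar_field"))
  if (!is.finite(cutoff) && cutoff != Inf) stop("cutoff must be finite or +Inf")
  newmask <- !field$mask & field$values >= cutoff
  out <- field
  out$mask <- field$mask | newmask
  attr(out, "n_masked") <- sum(newmask)
  out
}

#' Shift all unmasked voxel energies by a constant
#'
#' Used to reference a vacuum-based landscape to bulk water: subtracting
#' the vacuum-to-water transfer free energy turns ΔG(vac→prot) maps into
#' ΔG(wat→prot) maps. Masks are preserved.
#'
#' @param field a [scalar_field()].
#' @param dg_vac_to_wat scalar to subtract, kJ/mol (see [water_reference()]).
#' @return The referenced `scalar_field`.
#' @export
reference_to_water <- function(field, dg_vac_to_wat) {
  stopifnot(inherits(field, "scalar_field"), is.finite(dg_vac_to_wat))
  out <- field
  out$values[!out$mask] <- out$values[!out$mask] - dg_vac_to_wat
  out
}
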