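#' Ensemble of aligned configurations with Lennard-Jones parameters
#'
#' A `frameset` holds M configurations of the same N atoms (positions in Å)
#' together with one LJ parameter pair per atom. It is the protein-side
#' input to the implicit-ligand-sampling landscape: the ensemble of
#' configurations the insertion energy is Boltzmann-averaged over.
#'
#' @param coords list of M numeric matrices (N x 3), Å.
#' @param sigma numeric length N, LJ sigma per atom, Å.
#' @param epsilon numeric length N, LJ epsilon per atom, kJ/mol.
#' @return An object of class `frameset`.
#' @export
frameset <- function(coords, sigma, epsilon) {
  if (!is.list(coords) || !length(coords)) stop("coords must be a non-empty list")
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"
    if (ncol(m) != 3L) stop("each frame must be an N x 3 matrix")
    dimnames(m) <- NULL
    m
  })
  n <- nrow(coords[[1L]])
  if (any(vapply(coords, nrow, 0L) != n))
    stop("all frames must have the same atom count")
  sigma <- as.numeric(sigma); epsilon <- as.numeric(epsilon)
  if (length(sigma) != n || length(epsilon) != n)
    stop("sigma/epsilon must have one entry per atom")
  if (n > 0L && (any(sigma <= 0) || any(epsilon < 0)))
    stop("require sigma > 0 and epsilon >= 0")
  structure(list(coords = coords, sigma = sigma, epsilon = epsilon),
            class = "frameset")
}

#' @export
print.frameset <- function(x, ...) {
  cat(sprintf("frameset: %d frames x %d atoms\n",
              length(x$coords), nrow(x$coords[[1L]])))
  invisible(x)
}

n_frames <- function(fs) length(fs$coords)
n_atoms <- function(fs) nrow(fs$coords[[1L]])

#' Rigid-body superposition of every frame onto a reference
#'
#' Least-squares (Kabsch) rotation + translation of each frame onto the
#' reference using the selected atoms, the standard preprocessing before
#' landscape computation (e.g. fitting on C-alpha atoms of a minimized
#' structure). The fit never worsens the selection RMSD.
#'
#' @param frames a [frameset()].
#' @param reference numeric matrix (N x 3): the reference configuration.
#' @param selection integer vector of atom indices (>= 3) used for the fit.
#' @return The aligned `frameset`; per-frame post-fit selection RMSD (Å) is
#'   attached as attribute `"rmsd"`.
#' @export
align_frames <- function(frames, reference, selection = seq_len(n_atoms(frames))) {
  stopifnot(inherits(frames, "frameset"))
  reference <- rbind2mat(reference)
  selection <- as.integer(selection)
  if (length(selection) < 3L)
    stop("selection must contain at least 3 atoms (rotation underdetermined)")
  if (any(selection < 1L) || any(selection > n_atoms(frames)) ||
      any(selection > nrow(reference)))
    stop("selection out of range")
  ref_sel <- reference[selection, , drop = FALSE]
  ref_cen <- colMeans(ref_sel)
  rmsd <- numeric(n_frames(frames))
  out <- frames
  for (m in seq_len(n_frames(frames))) {
    x <- frames$coords[[m]]
    x_sel <- x[selection, , drop = FALSE]
    x_cen <- colMeans(x_sel)
    h <- crossprod(sweep(x_sel, 2L, x_cen), sweep(ref_sel, 2L, ref_cen))
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    xt <- sweep(x, 2L, x_cen) %*% t(rot)
    xt <- sweep(xt, 2L, ref_cen, `+`)
    out$coords[[m]] <- xt
    dd <- xt[selection, , drop = FALSE] - ref_sel
    rmsd[m] <- sqrt(mean(rowSums(dd * dd)))
  }
  attr(out, "rmsd") <- rmsd
  out
}

#' Write / read a frameset as multi-frame XYZ text with an LJ sidecar
#'
#' The trajectory goes to `<path>` in XYZ-like text (per frame: atom count,
#' comment, then `idx x y z` rows); LJ parameters go to `<path>.lj.tsv`
#' (tab-separated: atom_index, sigma_A, epsilon_kJ_mol).
#'
#' @param frames a [frameset()].
#' @param path output path for the trajectory text.
#' @return `path`, invisibly (`write_frameset`); a [frameset()]
#'   (`read_frameset`).
#' @export
write_frameset <- function(frames, path) {
  stopifnot(inherits(frames, "frameset"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- n_atoms(frames)
  for (m in seq_len(n_frames(frames))) {
    writeLines(c(as.character(n), sprintf("frame %d", m)), con)
    x <- frames$coords[[m]]
    writeLines(sprintf("%d %.6f %.6f %.6f", seq_len(n), x[, 1], x[, 2], x[, 3]),
               con)
  }
  lj <- data.frame(atom_index = seq_len(n), sigma_A = frames$sigma,
                   epsilon_kJ_mol = frames$epsilon)
  utils::write.table(lj, paste0(path, ".lj.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frameset
#' @export
read_frameset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lj <- utils::read.table(paste0(path, ".lj.tsv"), sep = "\t", header = TRUE)
  coords <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- as.integer(trimws(lines[pos]))
    if (is.na(n)) stop("malformed frameset file at line ", pos)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    coords[[length(coords) + 1L]] <- m[, 2:4, drop = FALSE]
    pos <- pos + 2L + n
  }
  frameset(coords, lj$sigma_A, lj$epsilon_kJ_mol)
}

#' Load a frameset from a multi-model PDB file
#'
#' Convenience reader for ensembles exchanged as multi-model PDB; the LJ
#' parameter table is supplied separately (tab-separated columns
#' `atom_index`, `sigma_A`, `epsilon_kJ_mol`). Requires the bio3d package.
#'
#' @param pdb_path multi-model PDB file.
#' @param lj_path LJ sidecar table path.
#' @return A [frameset()].
#' @export
read_frameset_pdb <- function(pdb_path, lj_path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_frameset_pdb requires the bio3d package")
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE)
  xyz <- pdb$xyz
  coords <- lapply(seq_len(nrow(xyz)), function(m)
    matrix(xyz[m, ], ncol = 3L, byrow = TRUE))
  lj <- utils::read.table(lj_path, sep = "\t", header = TRUE)
  frameset(coords, lj$sigma_A, lj$epsilon_kJ_mol)
}
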