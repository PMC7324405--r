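#' Pathway polyline with per-segment fluxes
#'
#' @param points numeric matrix (>= 2 rows) of ordered 3D points, Å.
#' @param flux numeric vector of per-segment fluxes (length
#'   `nrow(points) - 1`, or 1, recycled), all >= 0.
#' @param id pathway identifier.
#' @return Object of class `pathway_trace`.
#' @export
pathway_trace <- function(points, flux, id = "path") {
  points <- rbind2mat(points)
  if (nrow(points) < 2L) stop("a pathway trace needs at least 2 points")
  flux <- rep(as.numeric(flux), length.out = nrow(points) - 1L)
  if (any(flux < 0)) stop("segment fluxes must be >= 0")
  structure(list(points = points, flux = flux, id = id),
            class = "pathway_trace")
}

## minimum distance from each point in `xyz` to the segment a--b
point_segment_dist <- function(xyz, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(xyz, 2L, a)^2)))
  t <- pmin(pmax(as.numeric(sweep(xyz, 2L, a) %*% ab) / len2, 0), 1)
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
  sqrt(rowSums((xyz - proj)^2))
}

#' Residues lining high-flux pathway segments
#'
#' Keeps, per pathway, the segments carrying at least `flux_fraction` of
#' that pathway's maximum segment flux, then lists every residue having at
#' least one atom within `contact_distance` (closed ball, atom-to-segment
#' distance) of a retained segment. The default contact distance of
#' 3.32 Å approximates a Se:O van der Waals contact and should be adjusted
#' to the contact chemistry of interest.
#'
#' @param traces list of [pathway_trace()] objects.
#' @param structure data.frame with `x`, `y`, `z`, `chain`, `resno`,
#'   `resid` columns, in the same coordinate frame as the traces.
#' @param contact_distance Å. Default 3.32.
#' @param flux_fraction per-pathway segment retention threshold. Default
#'   0.5.
#' @return data.frame: pathway, chain, resno, resid, min_distance (Å),
#'   sorted by pathway then residue number.
#' @export
lining_residues <- function(traces, structure, contact_distance = 3.32,
                            flux_fraction = 0.5) {
  if (inherits(traces, "pathway_trace")) traces <- list(traces)
  if (!length(traces)) stop("no pathway traces supplied")
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  res <- list()
  for (tr in traces) {
    stopifnot(inherits(tr, "pathway_trace"))
    keep <- which(tr$flux >= flux_fraction * max(tr$flux))
    mind <- rep(Inf, nrow(xyz))
    for (s in keep) {
      d <- point_segment_dist(xyz, tr$points[s, ], tr$points[s + 1L, ])
      mind <- pmin(mind, d)
    }
    hit <- which(mind <= contact_distance)
    if (!length(hit)) next
    df <- data.frame(pathway = tr$id,
                     chain = structure$chain[hit],
                     resno = structure$resno[hit],
                     resid = structure$resid[hit],
                     min_distance = mind[hit])
    agg <- stats::aggregate(min_distance ~ pathway + chain + resno + resid,
                            data = df, FUN = min)
    res[[length(res) + 1L]] <- agg
  }
  out <- if (length(res)) do.call(rbind, res)
    else data.frame(pathway = character(), chain = character(),
                    resno = integer(), resid = character(),
                    min_distance = numeric())
  out <- out[order(out$pathway, out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conservation partition of two residue sets under a correspondence map
#'
#' Residues of set A whose mapped counterpart in set B has the same
#' amino-acid type are "conserved"; a different type is "non-conserved";
#' residues absent from the mapping are reported separately rather than
#' guessed. The correspondence table comes from an external structural
#' alignment.
#'
#' @param set_a,set_b data.frames with `resno` and `resid` columns.
#' @param mapping data.frame with columns `resno_a`, `resno_b`.
#' @return list: `conserved`, `non_conserved` (data.frames with both
#'   residue numbers and types), `unmapped` (resno vector from set A).
#' @export
compare_residue_sets <- function(set_a, set_b, mapping) {
  ia <- match(set_a$resno, mapping$resno_a)
  unmapped <- set_a$resno[is.na(ia)]
  mapped <- set_a[!is.na(ia), , drop = FALSE]
  partner <- mapping$resno_b[ia[!is.na(ia)]]
  type_b <- set_b$resid[match(partner, set_b$resno)]
  out <- data.frame(resno_a = mapped$resno, resid_a = mapped$resid,
                    resno_b = partner, resid_b = type_b)
  same <- !is.na(out$resid_b) & out$resid_a == out$resid_b
  list(conserved = out[same, , drop = FALSE],
       non_conserved = out[!same, , drop = FALSE],
       unmapped = unmapped)
}

#' Read residue-annotated coordinates from a PDB file
#'
#' Thin wrapper (requires bio3d) returning the flat structure table the
#' residue-mapping functions use.
#'
#' @param path PDB file.
#' @param heavy_only drop hydrogens. Default `TRUE`.
#' @return data.frame: chain, resno, resid, elety, element, x, y, z.
#' @export
read_structure_pdb <- function(path, heavy_only = TRUE) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_structure_pdb requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (heavy_only) at <- at[toupper(at$elesy) != "H", , drop = FALSE]
  data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
             elety = at$elety, element = at$elesy,
             x = at$x, y = at$y, z = at$z)
}
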