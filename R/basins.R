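## 26-neighbourhood machinery -------------------------------------------------

neighbor_offsets <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ])
}

## linear indices of the neighbour of every voxel under one offset (NA off-grid)
shift_index <- function(grid, off) {
  ijk <- linear_to_ijk(grid, seq_len(n_voxels(grid)))
  nb <- sweep(ijk, 2L, off, `+`)
  bad <- nb[, 1L] < 0L | nb[, 1L] >= grid$shape[1L] |
         nb[, 2L] < 0L | nb[, 2L] >= grid$shape[2L] |
         nb[, 3L] < 0L | nb[, 3L] >= grid$shape[3L]
  out <- ijk_to_linear(grid, nb)
  out[bad] <- NA_integer_
  out
}

## Descent pointer per voxel: the strictly-lowest 26-neighbour, ties broken by
## smallest linear index (x-fastest layout). A voxel with no strictly lower
## neighbour is its own pointer (a minimum), unless it lies on a plateau and
## has an equal-energy neighbour of smaller linear index, which it points to.
## Masked voxels get pointer NA and are invisible as neighbours.
descent_pointers <- function(field) {
  g <- field$grid
  nvox <- n_voxels(g)
  e <- as.vector(field$values)
  e[as.vector(field$mask)] <- Inf
  best_e <- rep(Inf, nvox)
  best_i <- rep(Inf, nvox)          # numeric so Inf works as "none yet"
  for (r in seq_len(26L)) {
    nb <- shift_index(g, neighbor_offsets()[r, ])
    en <- rep(Inf, nvox)
    okn <- !is.na(nb)
    en[okn] <- e[nb[okn]]
    nbn <- rep(Inf, nvox)
    nbn[okn] <- nb[okn]
    upd <- en < best_e | (en == best_e & nbn < best_i)
    upd[is.na(upd)] <- FALSE
    best_e[upd] <- en[upd]
    best_i[upd] <- nbn[upd]
  }
  v <- seq_len(nvox)
  ptr <- v
  lower <- best_e < e
  ptr[lower] <- as.integer(best_i[lower])
  plateau <- !lower & is.finite(e) & best_e == e & best_i < v
  ptr[plateau] <- as.integer(best_i[plateau])
  ptr[as.vector(field$mask)] <- NA_integer_
  ptr
}

#' Watershed decomposition of a free-energy grid
#'
#' Links every unmasked voxel to its lowest-energy neighbour among the 26
#' adjacent voxels of the surrounding 3x3x3 cube and follows these links
#' until a local minimum is reached; all voxels falling to the same minimum
#' form one basin. Per basin, the partition function
#' `Z_i = sum_{x in i} exp(-beta E(x))` is evaluated at the given
#' temperature. Ties between equal-energy neighbours are broken towards the
#' smallest linear voxel index, which also resolves plateaus
#' deterministically (see the descent-pointer rules in the package source).
#'
#' @param field a [scalar_field()] with at least one unmasked voxel.
#' @param thermo a [thermo_params()]; sets beta for the Z_i.
#' @return An object of class `basin_decomposition`: `labels` (integer array
#'   over the grid, `NA` for masked voxels), `minima` (data.frame: basin,
#'   voxel linear index, i/j/k, x/y/z, energy), `Z` (named numeric), plus
#'   the `grid` and `beta` used.
#' @export
watershed <- function(field, thermo = thermo_params()) {
  stopifnot(inherits(field, "scalar_field"), inherits(thermo, "thermo_params"))
  if (all(field$mask)) stop("all voxels are masked")
  g <- field$grid
  ptr <- descent_pointers(field)
  root <- ptr
  repeat {
    nxt <- root
    ok <- !is.na(root)
    nxt[ok] <- root[root[ok]]
    if (identical(nxt, root)) break
    root <- nxt
  }
  roots <- sort(unique(root[!is.na(root)]))
  labels <- match(root, roots)      # basin ids 1..n in root-index order
  e <- as.vector(field$values)
  ijk <- linear_to_ijk(g, roots)
  xyz <- voxel_center(g, ijk)
  minima <- data.frame(basin = seq_along(roots), voxel = roots,
                       i = ijk[, 1L], j = ijk[, 2L], k = ijk[, 3L],
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       energy = e[roots])
  w <- exp(-thermo$beta * e[!is.na(labels)])
  Z <- as.numeric(tapply(w, labels[!is.na(labels)], sum))
  names(Z) <- as.character(seq_along(roots))
  labels_arr <- array(labels, dim = g$shape)
  structure(list(labels = labels_arr, minima = minima, Z = Z,
                 grid = g, beta = thermo$beta, n_basins = length(roots)),
            class = "basin_decomposition")
}

#' @export
print.basin_decomposition <- function(x, ...) {
  cat(sprintf("basin_decomposition: %d basins over %d unmasked voxels\n",
              x$n_basins, sum(!is.na(x$labels))))
  invisible(x)
}

## All 26-adjacent voxel pairs straddling a basin boundary, each unordered
## pair once. Columns: v, w (linear indices), lab_v, lab_w, e_v, e_w.
boundary_pairs <- function(field, basins) {
  g <- field$grid
  lab <- as.vector(basins$labels)
  e <- as.vector(field$values)
  offs <- neighbor_offsets()
  ## half-space of offsets so each unordered pair appears exactly once
  half <- offs[offs[, 3L] > 0L |
               (offs[, 3L] == 0L & offs[, 2L] > 0L) |
               (offs[, 3L] == 0L & offs[, 2L] == 0L & offs[, 1L] > 0L), ,
               drop = FALSE]
  res <- vector("list", nrow(half))
  v_all <- seq_len(n_voxels(g))
  for (r in seq_len(nrow(half))) {
    nb <- shift_index(g, half[r, ])
    keep <- which(!is.na(nb))
    v <- v_all[keep]; w <- nb[keep]
    good <- !is.na(lab[v]) & !is.na(lab[w]) & lab[v] != lab[w]
    if (!any(good)) next
    v <- v[good]; w <- w[good]
    res[[r]] <- data.frame(v = v, w = w, lab_v = lab[v], lab_w = lab[w],
                           e_v = e[v], e_w = e[w])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(v = integer(), w = integer(), lab_v = integer(),
                      lab_w = integer(), e_v = numeric(), e_w = numeric())
  out
}

#' Saddle points between neighbouring basins
#'
#' For every pair of basins sharing a 26-adjacent boundary, the saddle is
#' determined by the min-max rule over boundary voxel pairs: among all
#' adjacent cross-basin pairs (x, y), the pair minimizing
#' `max(E(x), E(y))` sets the saddle energy, and the higher-energy voxel of
#' that pair is recorded as the saddle point (smaller linear index on an
#' exact tie). The saddle energy is therefore never below either basin
#' minimum.
#'
#' @param field a [scalar_field()].
#' @param basins its [watershed()] decomposition.
#' @return Object of class `saddle_set`: a data.frame with one row per
#'   neighbouring basin pair: `basin_i < basin_j`, `saddle_voxel` (linear
#'   index), `energy`, and the two boundary-pair voxels `voxel_i`,
#'   `voxel_j` on each side.
#' @export
find_saddles <- function(field, basins) {
  bp <- boundary_pairs(field, basins)
  if (!nrow(bp)) {
    out <- data.frame(basin_i = integer(), basin_j = integer(),
                      saddle_voxel = integer(), energy = numeric(),
                      voxel_i = integer(), voxel_j = integer())
    class(out) <- c("saddle_set", "data.frame")
    return(out)
  }
  a <- pmin(bp$lab_v, bp$lab_w)
  b <- pmax(bp$lab_v, bp$lab_w)
  barrier <- pmax(bp$e_v, bp$e_w)
  sv <- ifelse(bp$e_v > bp$e_w, bp$v,
        ifelse(bp$e_w > bp$e_v, bp$w, pmin(bp$v, bp$w)))
  ## voxel on the side of the lower-numbered basin
  vi <- ifelse(bp$lab_v == a, bp$v, bp$w)
  vj <- ifelse(bp$lab_v == a, bp$w, bp$v)
  ord <- order(a, b, barrier, sv)
  key <- paste(a, b)[ord]
  first <- !duplicated(key)
  out <- data.frame(basin_i = a[ord][first], basin_j = b[ord][first],
                    saddle_voxel = sv[ord][first], energy = barrier[ord][first],
                    voxel_i = vi[ord][first], voxel_j = vj[ord][first])
  rownames(out) <- NULL
  class(out) <- c("saddle_set", "data.frame")
  out
}

#' Steepest-descent trace from a voxel to its basin minimum
#'
#' Repeatedly steps to the lowest-energy 26-neighbour (same tie rules as
#' [watershed()]) until a minimum is reached. Masked voxels are never
#' entered.
#'
#' @param field a [scalar_field()].
#' @param start a linear voxel index (1-based) or 0-based (i, j, k) triple;
#'   must be unmasked.
#' @return Numeric matrix of voxel-center coordinates (one row per step,
#'   start included) with the per-step energies attached as attribute
#'   `"energy"` and linear indices as `"voxel"`.
#' @export
steepest_descent_trace <- function(field, start) {
  g <- field$grid
  if (length(start) == 3L) start <- ijk_to_linear(g, start)
  start <- as.integer(start)
  if (is.na(start) || start < 1L || start > n_voxels(g))
    stop("start voxel out of grid")
  if (field$mask[start]) stop("start voxel is masked")
  ptr <- descent_pointers(field)
  path <- integer(0)
  cur <- start
  repeat {
    path <- c(path, cur)
    nxt <- ptr[cur]
    if (is.na(nxt) || nxt == cur) break
    cur <- nxt
  }
  xyz <- voxel_center(g, linear_to_ijk(g, path))
  attr(xyz, "energy") <- as.vector(field$values)[path]
  attr(xyz, "voxel") <- path
  xyz
}

#' Network of minima linked through saddles
#'
#' Nodes are the basin minima; each neighbouring basin pair contributes one
#' edge at its saddle energy, carrying the two steepest-descent polylines
#' from the saddle into each basin's minimum (energies non-increasing along
#' each trace).
#'
#' @param field a [scalar_field()].
#' @param basins its [watershed()] decomposition.
#' @param saddles the [find_saddles()] result.
#' @return Object of class `minima_network`: `nodes` (the minima
#'   data.frame), `edges` (saddle rows plus component membership), and
#'   `traces` (list of two-matrix lists, `to_i` and `to_j`).
#' @export
build_network <- function(field, basins, saddles) {
  traces <- vector("list", nrow(saddles))
  e <- as.vector(field$values)
  for (r in seq_len(nrow(saddles))) {
    s <- saddles$saddle_voxel[r]
    trace_side <- function(side_voxel) {
      tr <- steepest_descent_trace(field, side_voxel)
      if (side_voxel != s) {
        sxyz <- voxel_center(field$grid, linear_to_ijk(field$grid, s))
        tr2 <- rbind(sxyz, tr)
        attr(tr2, "energy") <- c(e[s], attr(tr, "energy"))
        attr(tr2, "voxel") <- c(s, attr(tr, "voxel"))
        tr <- tr2
      }
      tr
    }
    traces[[r]] <- list(to_i = trace_side(saddles$voxel_i[r]),
                        to_j = trace_side(saddles$voxel_j[r]))
  }
  gr <- igraph::graph_from_data_frame(
    d = if (nrow(saddles)) data.frame(from = saddles$basin_i,
                                      to = saddles$basin_j)
        else data.frame(from = integer(), to = integer()),
    directed = FALSE,
    vertices = data.frame(name = basins$minima$basin))
  comp <- igraph::components(gr)$membership
  nodes <- basins$minima
  nodes$component <- comp[as.character(nodes$basin)]
  structure(list(nodes = nodes, edges = saddles, traces = traces),
            class = "minima_network")
}

#' @export
print.minima_network <- function(x, ...) {
  cat(sprintf("minima_network: %d minima, %d saddle edges, %d component(s)\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$component))))
  invisible(x)
}

#' Export basin labels as an integer OpenDX map
#'
#' Masked voxels are written as 0; basin ids start at 1.
#'
#' @param basins a `basin_decomposition`.
#' @param path output `.dx` path.
#' @return `path` invisibly.
#' @export
write_basin_labels <- function(basins, path) {
  lab <- basins$labels
  lab[is.na(lab)] <- 0L
  write_volumetric(scalar_field(basins$grid, lab), path, sentinel = NULL)
}

#' Export a minima network edge list as TSV
#'
#' Columns: basin_i, basin_j, saddle_energy and the saddle coordinates.
#'
#' @param network a `minima_network`.
#' @param grid the [grid_spec()] of the underlying field.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_network_edges <- function(network, grid, path) {
  ed <- network$edges
  xyz <- if (nrow(ed)) voxel_center(grid, linear_to_ijk(grid, ed$saddle_voxel))
         else matrix(numeric(), ncol = 3L)
  out <- data.frame(basin_i = ed$basin_i, basin_j = ed$basin_j,
                    saddle_energy = ed$energy,
                    saddle_x = xyz[, 1L], saddle_y = xyz[, 2L],
                    saddle_z = xyz[, 3L])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a polyline trace as CSV
#'
#' Columns: point, x, y, z, energy.
#'
#' @param trace matrix from [steepest_descent_trace()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(point = seq_len(nrow(trace)), x = trace[, 1L],
                    y = trace[, 2L], z = trace[, 3L],
                    energy = attr(trace, "energy"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
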