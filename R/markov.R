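#' Basin-level Markov model from a free-energy landscape
#'
#' Builds the transition matrix directly from the landscape under the
#' Metropolis/Kramers construction: for two distinct basins i, j,
#' `T_ij = 1/(Z_i (3^D - 1)) * sum over 26-adjacent cross-basin voxel pairs
#' (x in i, y in j) of min{exp(-beta E(x)), exp(-beta E(y))}` with D = 3
#' (denominator 26 Z_i). Pairs of basins whose saddle energy is at or above
#' `saddle_cutoff` are excluded (T_ij = 0), removing very low probability
#' transitions and hard-to-reach states. Self-transitions absorb the row
#' remainder, `T_ii = 1 - sum_{j != i} T_ij`. Because the pairwise
#' numerators are symmetric, the model satisfies detailed balance with
#' respect to `pi_i = Z_i / sum_k Z_k` by construction.
#'
#' @param field a [scalar_field()].
#' @param basins its [watershed()] decomposition.
#' @param saddles the [find_saddles()] result for the same decomposition.
#' @param saddle_cutoff admit only basin pairs with saddle energy strictly
#'   below this value, kJ/mol. Default 40.
#' @param thermo a [thermo_params()]; must match the temperature used for
#'   the basin partition functions.
#' @return Object of class `markov_model`: `states` (character ids), `T`
#'   (row-stochastic matrix), `Z` (per-state partition functions),
#'   `temperature`, `beta`.
#' @export
build_markov_model <- function(field, basins, saddles, saddle_cutoff = 40,
                               thermo = thermo_params()) {
  stopifnot(inherits(basins, "basin_decomposition"))
  n <- basins$n_basins
  beta <- thermo$beta
  if (abs(beta - basins$beta) > 1e-12 * beta)
    stop("thermo temperature differs from the one used for watershed Z_i")
  tm <- matrix(0, n, n)
  bp <- boundary_pairs(field, basins)
  if (nrow(bp)) {
    ## admissible basin pairs under the saddle cutoff
    okpair <- saddles[saddles$energy < saddle_cutoff, c("basin_i", "basin_j")]
    okkey <- paste(okpair$basin_i, okpair$basin_j)
    key <- paste(pmin(bp$lab_v, bp$lab_w), pmax(bp$lab_v, bp$lab_w))
    bp <- bp[key %in% okkey, , drop = FALSE]
    if (nrow(bp)) {
      w <- pmin(exp(-beta * bp$e_v), exp(-beta * bp$e_w))
      num <- tapply(w, list(factor(bp$lab_v, levels = seq_len(n)),
                            factor(bp$lab_w, levels = seq_len(n))), sum)
      num[is.na(num)] <- 0
      num <- num + t(num)  # symmetric numerator over unordered pairs
      tm <- num / (26 * basins$Z)
    }
  }
  off <- rowSums(tm)
  if (any(off > 1 + 1e-9))
    stop("internal error: off-diagonal row sum exceeds 1 (", max(off), ")")
  diag(tm) <- pmax(0, 1 - off)
  states <- as.character(seq_len(n))
  dimnames(tm) <- list(states, states)
  Z <- basins$Z
  names(Z) <- states
  structure(list(states = states, T = tm, Z = Z,
                 temperature = thermo$temperature, beta = beta),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d states at %g K\n",
              length(x$states), x$temperature))
  invisible(x)
}

#' Identify bulk-solvent basins
#'
#' A basin is classified as solvent when its minimum voxel lies in the
#' outermost voxel layer of the grid AND its minimum energy is within
#' `energy_window` of the bulk reference (0 on a water-referenced
#' landscape). Both thresholds are configurable and any automatic choice
#' can be overridden by passing an explicit basin set to
#' [coarse_grain_solvent()].
#'
#' @param basins a [watershed()] decomposition.
#' @param reference bulk energy level, kJ/mol. Default 0.
#' @param energy_window admissible deviation of the basin minimum from the
#'   reference, kJ/mol. Default 2.
#' @return Integer vector of solvent basin ids.
#' @export
identify_solvent_basins <- function(basins, reference = 0, energy_window = 2) {
  m <- basins$minima
  sh <- basins$grid$shape
  on_shell <- m$i == 0L | m$i == sh[1L] - 1L |
              m$j == 0L | m$j == sh[2L] - 1L |
              m$k == 0L | m$k == sh[3L] - 1L
  near_bulk <- abs(m$energy - reference) <= energy_window
  ids <- m$basin[on_shell & near_bulk]
  if (!length(ids))
    stop("no basin satisfies the solvent rule (boundary-shell minimum within ",
         energy_window, " kJ/mol of ", reference,
         "); designate solvent basins manually in coarse_grain_solvent()")
  sort(ids)
}

#' Merge solvent basins into a single state
#'
#' All designated basins are coarse-grained into one `"solvent"` state.
#' The merged outgoing row is the partition-function-weighted average of
#' the member rows (stationary weights within the merged set), and
#' incoming columns are summed; this preserves row-stochasticity and
#' detailed balance exactly, and the merged state's stationary probability
#' equals the sum over members.
#'
#' @param model a [build_markov_model()] result.
#' @param solvent integer/character ids of states to merge (e.g. from
#'   [identify_solvent_basins()]).
#' @return A `markov_model` whose last state is `"solvent"`.
#' @export
coarse_grain_solvent <- function(model, solvent) {
  stopifnot(inherits(model, "markov_model"))
  solvent <- as.character(solvent)
  s <- match(solvent, model$states)
  if (anyNA(s)) stop("unknown solvent state id(s): ",
                     paste(solvent[is.na(s)], collapse = ", "))
  if (!length(s)) stop("empty solvent set")
  keep <- setdiff(seq_along(model$states), s)
  w <- model$Z[s] / sum(model$Z[s])
  tm <- model$T
  n2 <- length(keep) + 1L
  out <- matrix(0, n2, n2)
  if (length(keep)) {
    out[seq_along(keep), seq_along(keep)] <- tm[keep, keep, drop = FALSE]
    out[seq_along(keep), n2] <- rowSums(tm[keep, s, drop = FALSE])
    out[n2, seq_along(keep)] <- as.numeric(w %*% tm[s, keep, drop = FALSE])
  }
  out[n2, n2] <- sum(w * rowSums(tm[s, s, drop = FALSE]))
  states <- c(model$states[keep], "solvent")
  dimnames(out) <- list(states, states)
  Z <- c(model$Z[keep], solvent = sum(model$Z[s]))
  names(Z) <- states
  structure(list(states = states, T = out, Z = Z,
                 temperature = model$temperature, beta = model$beta),
            class = "markov_model")
}

#' Stationary distribution by chain iteration
#'
#' Iterates `p(t + dt) = p(t) %*% T` from the initial condition
#' `p_i(0) = 1` on the solvent state (0 elsewhere; uniform if the model has
#' no `"solvent"` state and no start is given) until
#' `max |p(t+dt) - p(t)| < tolerance`. The result is checked against the
#' invariance relation `pi = pi %*% T` and against detailed balance;
#' strongly disconnected state spaces are reported, since the iteration
#' limit then depends on the start.
#'
#' @param model a `markov_model`.
#' @param tolerance convergence threshold on the max absolute probability
#'   change per iteration. Default 1e-12.
#' @param max_iter iteration cap. Default 1e6.
#' @param p0 optional start distribution (named or in state order).
#' @return Named numeric vector `pi` summing to 1, with the number of
#'   iterations as attribute `"iterations"`.
#' @export
stationary_distribution <- function(model, tolerance = 1e-12,
                                    max_iter = 1e6, p0 = NULL) {
  tm <- model$T
  n <- nrow(tm)
  if (is.null(p0)) {
    p0 <- rep(0, n)
    isolv <- match("solvent", model$states)
    if (is.na(isolv)) p0 <- rep(1 / n, n) else p0[isolv] <- 1
  }
  p0 <- p0 / sum(p0)
  gr <- igraph::graph_from_adjacency_matrix(tm > 0, mode = "directed")
  ncomp <- igraph::components(gr, mode = "strong")$no
  if (ncomp > 1L)
    warning("state space is not strongly connected (", ncomp,
            " components); the stationary limit may depend on the start")
  p <- p0
  it <- 0L
  repeat {
    pn <- as.numeric(p %*% tm)
    it <- it + 1L
    if (max(abs(pn - p)) < tolerance) { p <- pn; break }
    p <- pn
    if (it >= max_iter)
      stop("stationary iteration did not converge in ", max_iter, " steps")
  }
  names(p) <- model$states
  resid <- max(abs(as.numeric(p %*% tm) - p))
  if (resid > 100 * tolerance)
    warning("invariance residual ", signif(resid, 3), " exceeds tolerance")
  flows <- p * tm                      # (i, j) element: pi_i * T_ij
  db <- abs(flows - t(flows))
  scale <- pmax(flows, t(flows))
  rel <- db[scale > 0] / scale[scale > 0]
  if (length(rel) && max(rel) > 1e-8)
    warning("detailed balance violated at relative level ",
            signif(max(rel), 3))
  attr(p, "iterations") <- it
  p
}

#' Select product basins by contact with target atoms
#'
#' A basin is a product state when at least one of its voxel centers lies
#' within the closed ball of radius `contact_distance` around any target
#' atom — the rule used to mark basins in van der Waals contact with the
#' active-site cysteine sulfur/selenium atoms.
#'
#' @param basins a [watershed()] decomposition.
#' @param structure data.frame with columns x, y, z (Å) in the grid's
#'   coordinate frame (plus any residue annotation columns).
#' @param target_atoms integer row indices of the target atoms in
#'   `structure`; default all rows.
#' @param contact_distance Å; default 3.32 (a Se:O van der Waals contact).
#' @return Sorted integer vector of product basin ids (empty, with a
#'   warning, if no voxel is in contact).
#' @export
select_product_basins <- function(basins, structure,
                                  target_atoms = seq_len(nrow(structure)),
                                  contact_distance = 3.32) {
  if (!length(target_atoms)) stop("empty target atom selection")
  lab <- as.vector(basins$labels)
  ok <- which(!is.na(lab))
  xyz <- voxel_center(basins$grid, linear_to_ijk(basins$grid, ok))
  tgt <- as.matrix(structure[target_atoms, c("x", "y", "z"), drop = FALSE])
  hit <- rep(FALSE, length(ok))
  for (a in seq_len(nrow(tgt))) {
    d2 <- rowSums(sweep(xyz, 2L, tgt[a, ])^2)
    hit <- hit | d2 <= contact_distance^2
  }
  ids <- sort(unique(lab[ok[hit]]))
  if (!length(ids))
    warning("no basin voxel within ", contact_distance, " A of the targets")
  ids
}

#' Most distant atom of each residue from a metal centre
#'
#' Implements the residue-level target rule: for each requested residue,
#' the atom farthest from the bonded metal position is returned, to be used
#' as the contact target for product-basin selection.
#'
#' @param structure data.frame with x, y, z and `resno` columns.
#' @param resno residue numbers to process.
#' @param metal_pos numeric length-3, Å.
#' @return Integer row indices into `structure`, one per residue.
#' @export
most_distant_atom <- function(structure, resno, metal_pos) {
  vapply(resno, function(rn) {
    rows <- which(structure$resno == rn)
    if (!length(rows)) stop("residue ", rn, " not present in structure")
    d2 <- rowSums(sweep(as.matrix(structure[rows, c("x", "y", "z")]),
                        2L, as.numeric(metal_pos))^2)
    rows[which.max(d2)]
  }, 0L)
}
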