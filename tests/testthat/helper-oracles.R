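## Independent brute-force oracles used to check the grid algorithms.
## These deliberately use naive per-voxel loops and explicit neighbour
## scans, not the package's vectorized implementations.

oracle_offsets <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
oracle_offsets <- oracle_offsets[rowSums(oracle_offsets == 0) < 3L, ]

## energy of voxel (i,j,k) 0-based with masked/off-grid = Inf
oracle_energy <- function(field, i, j, k) {
  sh <- field$grid$shape
  if (i < 0 || i >= sh[1] || j < 0 || j >= sh[2] || k < 0 || k >= sh[3])
    return(Inf)
  if (field$mask[i + 1, j + 1, k + 1]) return(Inf)
  field$values[i + 1, j + 1, k + 1]
}

oracle_linear <- function(field, ijk) {
  sh <- field$grid$shape
  unname(1 + ijk[1] + sh[1] * (ijk[2] + sh[2] * ijk[3]))
}

## descend one step: strictly-lowest neighbour, ties to smallest linear
## index; on a plateau, the smallest-index equal neighbour if smaller than
## self; otherwise stay (minimum)
oracle_step <- function(field, ijk) {
  e0 <- oracle_energy(field, ijk[1], ijk[2], ijk[3])
  best_e <- Inf; best_lin <- Inf; best_ijk <- NULL
  for (r in seq_len(nrow(oracle_offsets))) {
    nb <- ijk + oracle_offsets[r, ]
    en <- oracle_energy(field, nb[1], nb[2], nb[3])
    if (!is.finite(en)) next
    lin <- oracle_linear(field, nb)
    if (en < best_e || (en == best_e && lin < best_lin)) {
      best_e <- en; best_lin <- lin; best_ijk <- nb
    }
  }
  if (is.null(best_ijk)) return(ijk)
  if (best_e < e0) return(best_ijk)
  if (best_e == e0 && best_lin < oracle_linear(field, ijk)) return(best_ijk)
  ijk
}

## full pointer-chase basin labelling; returns linear index of the minimum
## each voxel falls to (NA for masked)
oracle_fall_to <- function(field) {
  sh <- field$grid$shape
  out <- array(NA_real_, dim = sh)
  for (k in 0:(sh[3] - 1)) for (j in 0:(sh[2] - 1)) for (i in 0:(sh[1] - 1)) {
    if (field$mask[i + 1, j + 1, k + 1]) next
    cur <- c(i, j, k)
    repeat {
      nxt <- oracle_step(field, cur)
      if (all(nxt == cur)) break
      cur <- nxt
    }
    out[i + 1, j + 1, k + 1] <- oracle_linear(field, cur)
  }
  out
}

## all 26-adjacent cross-basin voxel pairs by exhaustive double loop;
## returns min-max saddle energy and saddle voxel per basin pair
oracle_saddles <- function(field, labels) {
  sh <- field$grid$shape
  best <- list()
  for (k in 0:(sh[3] - 1)) for (j in 0:(sh[2] - 1)) for (i in 0:(sh[1] - 1)) {
    l1 <- labels[i + 1, j + 1, k + 1]
    if (is.na(l1)) next
    for (r in seq_len(nrow(oracle_offsets))) {
      nb <- c(i, j, k) + oracle_offsets[r, ]
      if (any(nb < 0) || any(nb >= sh)) next
      l2 <- labels[nb[1] + 1, nb[2] + 1, nb[3] + 1]
      if (is.na(l2) || l2 == l1) next
      e1 <- field$values[i + 1, j + 1, k + 1]
      e2 <- field$values[nb[1] + 1, nb[2] + 1, nb[3] + 1]
      bar <- max(e1, e2)
      sv <- if (e1 > e2) oracle_linear(field, c(i, j, k))
            else if (e2 > e1) oracle_linear(field, nb)
            else min(oracle_linear(field, c(i, j, k)), oracle_linear(field, nb))
      key <- paste(min(l1, l2), max(l1, l2))
      if (is.null(best[[key]]) || bar < best[[key]]$energy ||
          (bar == best[[key]]$energy && sv < best[[key]]$voxel))
        best[[key]] <- list(energy = bar, voxel = sv)
    }
  }
  best
}

## transition matrix by direct enumeration of Eq-style boundary pairs
oracle_transition_matrix <- function(field, labels, beta, saddle_cutoff = Inf,
                                     saddle_energies = NULL) {
  sh <- field$grid$shape
  labs <- sort(unique(as.vector(labels[!is.na(labels)])))
  n <- length(labs)
  Z <- numeric(n)
  for (b in seq_len(n))
    Z[b] <- sum(exp(-beta * field$values[!is.na(labels) & labels == labs[b]]))
  num <- matrix(0, n, n)
  for (k in 0:(sh[3] - 1)) for (j in 0:(sh[2] - 1)) for (i in 0:(sh[1] - 1)) {
    l1 <- labels[i + 1, j + 1, k + 1]
    if (is.na(l1)) next
    for (r in seq_len(nrow(oracle_offsets))) {
      nb <- c(i, j, k) + oracle_offsets[r, ]
      if (any(nb < 0) || any(nb >= sh)) next
      l2 <- labels[nb[1] + 1, nb[2] + 1, nb[3] + 1]
      if (is.na(l2) || l2 == l1) next
      e1 <- field$values[i + 1, j + 1, k + 1]
      e2 <- field$values[nb[1] + 1, nb[2] + 1, nb[3] + 1]
      a <- match(l1, labs); b <- match(l2, labs)
      if (!is.null(saddle_energies)) {
        key <- paste(min(l1, l2), max(l1, l2))
        if (!is.null(saddle_energies[[key]]) &&
            saddle_energies[[key]] >= saddle_cutoff) next
      }
      num[a, b] <- num[a, b] + min(exp(-beta * e1), exp(-beta * e2))
    }
  }
  tm <- num / (26 * Z)
  diag(tm) <- 1 - rowSums(tm)
  list(T = tm, Z = Z, labels = labs)
}

## random test field on a small grid
random_field <- function(seed, shape = c(5, 5, 5), mask_frac = 0) {
  set.seed(seed)
  g <- grid_spec(c(0, 0, 0), 1, shape)
  v <- round(runif(prod(shape), -10, 10), 2)
  mask <- runif(prod(shape)) < mask_frac
  if (all(mask)) mask[1] <- FALSE
  scalar_field(g, v, mask)
}

## two Gaussian wells separated along x; barrier between them
two_well_field <- function(dE = 0, depth = 10, width = 1.5,
                           shape = c(21, 9, 9)) {
  g <- grid_spec(c(0, 0, 0), 1, shape)
  ctr <- (shape - 1) / 2
  make_landscape(g, list(
    gaussian_well(c(5, ctr[2], ctr[3]), depth, width),
    gaussian_well(c(shape[1] - 6, ctr[2], ctr[3]), depth + dE, width)))
}

## Halton low-discrepancy sequence (deterministic quasi-random quadrature)
halton_seq <- function(n, base) {
  r <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1; x <- 0; k <- i
    while (k > 0) { f <- f / base; x <- x + f * (k %% base); k <- k %/% base }
    r[i] <- x
  }
  r
}

## dense-quadrature reference PMF for a single fixed LJ atom: quasi-random
## insertions (3 position dims, 2 orientation dims via z/phi sphere
## parametrization), evaluated with its own LJ formula
halton_matrix <- function(n) {
  cbind(halton_seq(n, 2), halton_seq(n, 3), halton_seq(n, 5),
        halton_seq(n, 7), halton_seq(n, 11))
}

oracle_pmf_single_atom <- function(center, atom, sigma_c, eps_c, bond,
                                   kb, temperature, n = 1e5, clamp = 1e4,
                                   u = NULL) {
  if (is.null(u)) u <- halton_matrix(n)
  pos <- sweep(u[, 1:3] - 0.5, 2, c(1, 1, 1), `*`)
  pos <- sweep(pos, 2, center, `+`)
  z <- 2 * u[, 4] - 1
  phi <- 2 * pi * u[, 5]
  rho <- sqrt(pmax(0, 1 - z^2))
  o <- cbind(rho * cos(phi), rho * sin(phi), z)
  beta <- 1 / (kb * temperature)
  e <- numeric(n)
  for (sgn in c(1, -1)) {
    site <- pos + sgn * (bond / 2) * o
    d2 <- rowSums(sweep(site, 2, atom)^2)
    sr6 <- (sigma_c^2 / d2)^3
    e <- e + 4 * eps_c * (sr6^2 - sr6)
  }
  e <- pmin(e, clamp)
  -kb * temperature * log(mean(exp(-beta * e)))
}

## hand-set reversible 5-state model used by the TPT trajectory oracle
five_state_model <- function() {
  ## symmetric numerators give detailed balance w.r.t. pi proportional to z
  z <- c(4, 1, 2, 1, 3)
  w <- matrix(0, 5, 5)
  w[1, 2] <- 0.30; w[2, 3] <- 0.25; w[3, 4] <- 0.20; w[4, 5] <- 0.28
  w[1, 3] <- 0.10; w[2, 4] <- 0.05
  w <- w + t(w)
  tm <- w / z
  diag(tm) <- 1 - rowSums(tm)
  stopifnot(all(tm >= 0))
  states <- as.character(1:5)
  dimnames(tm) <- list(states, states)
  structure(list(states = states, T = tm, Z = setNames(z, states),
                 temperature = 300, beta = 1 / (0.0083145 * 300)),
            class = "markov_model")
}

## all simple source->target paths and their bottleneck widths (diamond-size
## networks only)
oracle_all_paths <- function(cap, src, tgt) {
  n <- nrow(cap)
  res <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur %in% tgt) {
      w <- Inf
      for (k in seq_len(length(path) - 1L))
        w <- min(w, cap[path[k], path[k + 1L]])
      res[[length(res) + 1L]] <<- list(path = path, width = w)
      return(invisible())
    }
    for (v in which(cap[cur, ] > 0)) if (!(v %in% path)) walk(c(path, v))
  }
  walk(src)
  res
}
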