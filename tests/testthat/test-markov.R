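th300 <- thermo_params(300)

test_that("a single-basin landscape yields the trivial chain T = [[1]]", {
  g <- grid_spec(c(0, 0, 0), 1, c(5, 5, 5))
  f <- make_landscape(g, list(gaussian_well(c(2, 2, 2), 8, 2)))
  b <- watershed(f, th300)
  m <- build_markov_model(f, b, find_saddles(f, b), thermo = th300)
  expect_identical(dim(m$T), c(1L, 1L))
  expect_equal(m$T[1, 1], 1)
})

test_that("transition matrix equals hand enumeration on a 4x1x1 toy field", {
  g <- grid_spec(c(0, 0, 0), 1, c(4, 1, 1))
  f <- scalar_field(g, c(0, 1, 1, 0))
  b <- watershed(f, th300)
  expect_identical(b$n_basins, 2L)
  m <- build_markov_model(f, b, find_saddles(f, b), thermo = th300)
  ## by hand: only cross pair is voxels 2-3 (energies 1, 1);
  ## numerator min(e^-b, e^-b) = e^-b, Z_1 = 1 + e^-b
  beta <- th300$beta
  t12 <- exp(-beta) / (26 * (1 + exp(-beta)))
  expect_equal(m$T["1", "2"], t12, tolerance = 1e-14)
  expect_equal(m$T["2", "1"], t12, tolerance = 1e-14)
  expect_equal(diag(m$T), c("1" = 1 - t12, "2" = 1 - t12), tolerance = 1e-14)
})

test_that("transition matrix matches exhaustive pair enumeration on random fields", {
  for (seed in c(3, 8, 15)) {
    f <- random_field(seed, c(6, 5, 4))
    b <- watershed(f, th300)
    s <- find_saddles(f, b)
    m <- build_markov_model(f, b, s, saddle_cutoff = Inf, thermo = th300)
    oracle <- oracle_transition_matrix(f, b$labels, th300$beta)
    expect_equal(unname(m$T), oracle$T, tolerance = 1e-12)
    expect_equal(unname(m$Z), oracle$Z, tolerance = 1e-12)
  }
})

test_that("saddle pairs at or above the cutoff are excluded from the chain", {
  g <- grid_spec(c(0, 0, 0), 1, c(7, 1, 1))
  f <- scalar_field(g, c(0, 20, 45, 20, 0, 1, 0.5))
  b <- watershed(f)
  s <- find_saddles(f, b)
  expect_true(any(s$energy >= 40))
  m <- build_markov_model(f, b, s, saddle_cutoff = 40, thermo = th300)
  over <- s[s$energy >= 40, ]
  for (r in seq_len(nrow(over))) {
    expect_identical(m$T[over$basin_i[r], over$basin_j[r]], 0)
    expect_identical(m$T[over$basin_j[r], over$basin_i[r]], 0)
  }
  under <- s[s$energy < 40, ]
  for (r in seq_len(nrow(under)))
    expect_gt(m$T[under$basin_i[r], under$basin_j[r]], 0)
})

test_that("built models are row-stochastic and detailed-balanced to 1e-10", {
  for (seed in c(1, 9)) {
    f <- random_field(seed, c(7, 6, 5))
    b <- watershed(f, th300)
    m <- build_markov_model(f, b, find_saddles(f, b), thermo = th300)
    expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
    pi <- m$Z / sum(m$Z)
    flows <- pi * m$T
    denom <- pmax(flows, t(flows))
    rel <- abs(flows - t(flows))[denom > 0] / denom[denom > 0]
    expect_lt(max(c(rel, 0)), 1e-10)
  }
})

test_that("stationary iteration recovers Z_i / sum(Z) from the solvent start", {
  f <- two_well_field(dE = 3)
  b <- watershed(f, th300)
  m <- build_markov_model(f, b, find_saddles(f, b), thermo = th300)
  p0 <- c(1, 0)
  pi_hat <- stationary_distribution(m, p0 = p0)
  expect_equal(as.numeric(pi_hat), unname(m$Z / sum(m$Z)), tolerance = 1e-8)
  ## identity chain: the start is already stationary
  ident <- m; ident$T <- diag(2); dimnames(ident$T) <- dimnames(m$T)
  expect_equal(as.numeric(suppressWarnings(
    stationary_distribution(ident, p0 = c(0.3, 0.7)))), c(0.3, 0.7))
  ## two-state symmetric chain converges to (1/2, 1/2)
  sym <- m
  sym$T <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, dimnames = dimnames(m$T))
  sym$Z <- c("1" = 1, "2" = 1)
  expect_equal(as.numeric(stationary_distribution(sym, p0 = c(1, 0))),
               c(0.5, 0.5), tolerance = 1e-10)
})

test_that("stationary iteration reports non-convergence", {
  m <- five_state_model()
  expect_error(stationary_distribution(m, tolerance = 1e-15, max_iter = 3),
               "converge")
})

test_that("solvent identification needs a bulk-like boundary basin", {
  f <- two_well_field()           # both minima interior, energies ~ -10
  b <- watershed(f, th300)
  expect_error(identify_solvent_basins(b), "manual")
  ## walled pocket between two flat exterior regions: the exterior plateau
  ## basins (boundary-shell minima at the bulk level) qualify as solvent,
  ## the pocket does not
  g <- grid_spec(c(0, 0, 0), 1, c(11, 3, 3))
  prof <- c(0, 0, 30, -5, 30, 0, 0, 0, 0, 0, 0)
  f2 <- scalar_field(g, rep(prof, times = 9))  # x-fastest layout
  b2 <- watershed(f2, th300)
  solv <- identify_solvent_basins(b2)
  pocket <- b2$labels[4, 2, 2]
  expect_false(pocket %in% solv)
  expect_setequal(solv, setdiff(seq_len(b2$n_basins), pocket))
  expect_true(all(abs(b2$minima$energy[solv]) <= 2))
})

test_that("coarse-graining preserves stochasticity, balance, and summed pi", {
  f <- two_well_field(dE = 2)
  ## add a third shallow well so merging two leaves a nontrivial chain
  g <- grid_spec(c(0, 0, 0), 1, c(33, 9, 9))
  f <- make_landscape(g, list(gaussian_well(c(5, 4, 4), 10, 1.4),
                              gaussian_well(c(16, 4, 4), 12, 1.4),
                              gaussian_well(c(27, 4, 4), 9, 1.4)))
  b <- watershed(f, th300)
  expect_identical(b$n_basins, 3L)
  m <- build_markov_model(f, b, find_saddles(f, b), thermo = th300)
  ## merging a single basin only relabels
  m1 <- coarse_grain_solvent(m, "1")
  expect_equal(unname(m1$T), unname(m$T[c(2, 3, 1), c(2, 3, 1)]))
  ## merging two basins
  m2 <- coarse_grain_solvent(m, c("1", "3"))
  expect_identical(m2$states, c("2", "solvent"))
  expect_equal(rowSums(m2$T), c("2" = 1, solvent = 1), tolerance = 1e-12)
  pi_full <- m$Z / sum(m$Z)
  pi_merged <- stationary_distribution(m2, p0 = c(0, 1))
  expect_equal(unname(pi_merged["solvent"]),
               unname(pi_full["1"] + pi_full["3"]), tolerance = 1e-8)
  expect_equal(unname(pi_merged["2"]), unname(pi_full["2"]), tolerance = 1e-8)
  ## detailed balance survives the merge (checked against the analytic
  ## stationary weights, relative to the largest flow)
  pi_z <- as.numeric(m2$Z / sum(m2$Z))
  flows <- pi_z * m2$T
  expect_lt(max(abs(flows - t(flows))) / max(flows), 1e-13)
  expect_error(coarse_grain_solvent(m, "99"), "unknown")
})

test_that("symmetric solvent rows merge to the common transition probability", {
  ## two solvent basins with equal Z and T(s -> b) = 0.1 each
  tm <- matrix(c(0.9, 0.0, 0.1,
                 0.0, 0.9, 0.1,
                 0.05, 0.05, 0.9), 3, 3, byrow = TRUE,
               dimnames = list(c("1", "2", "3"), c("1", "2", "3")))
  m <- structure(list(states = c("1", "2", "3"), T = tm,
                      Z = c("1" = 2, "2" = 2, "3" = 8),
                      temperature = 300, beta = 1 / (0.0083145 * 300)),
                 class = "markov_model")
  mc <- coarse_grain_solvent(m, c("1", "2"))
  expect_equal(mc$T["solvent", "3"], 0.1)
  expect_equal(mc$T["3", "solvent"], 0.1)
})

test_that("product basins are selected by closed-ball voxel contact", {
  f <- two_well_field()
  b <- watershed(f, th300)
  min2 <- b$minima[2, ]
  ## a target atom exactly contact_distance - eps from the basin-2 minimum
  eps <- 1e-9
  tgt <- data.frame(x = min2$x + (2 - eps), y = min2$y, z = min2$z)
  expect_true(2L %in% select_product_basins(b, tgt, contact_distance = 2))
  ## far target: empty with a warning
  far <- data.frame(x = 1e4, y = 0, z = 0)
  expect_warning(ids <- select_product_basins(b, far, contact_distance = 2),
                 "no basin")
  expect_identical(length(ids), 0L)
  expect_error(select_product_basins(b, far, target_atoms = integer(0)),
               "empty")
  ## pocket fixture: a marked atom 2 A from the pocket minimum with 3.3 A
  ## contact selects exactly the pocket basin
  tgt2 <- data.frame(x = min2$x + 2, y = min2$y, z = min2$z)
  sel <- select_product_basins(b, tgt2, contact_distance = 3.3)
  ## brute-force distance oracle over every unmasked voxel
  lab <- as.vector(b$labels)
  ctr <- voxel_center(b$grid, linear_to_ijk(b$grid, seq_len(n_voxels(b$grid))))
  d <- sqrt((ctr[, 1] - tgt2$x)^2 + (ctr[, 2] - tgt2$y)^2 +
              (ctr[, 3] - tgt2$z)^2)
  expect_identical(sel, sort(unique(lab[d <= 3.3])))
})

test_that("most_distant_atom picks the residue atom farthest from the metal", {
  s <- data.frame(resno = c(10, 10, 10, 11),
                  x = c(0, 1, 5, 2), y = 0, z = 0)
  expect_identical(most_distant_atom(s, 10, c(0, 0, 0)), 3L)
  expect_identical(most_distant_atom(s, c(10, 11), c(0, 0, 0)), c(3L, 4L))
  expect_error(most_distant_atom(s, 99, c(0, 0, 0)), "not present")
})
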