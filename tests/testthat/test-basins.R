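test_that("a single monotone well yields one basin holding every voxel", {
  g <- grid_spec(c(0, 0, 0), 1, c(7, 7, 7))
  f <- make_landscape(g, list(gaussian_well(c(3, 3, 3), 10, 3)))
  b <- watershed(f)
  expect_identical(b$n_basins, 1L)
  expect_true(all(b$labels == 1L))
  expect_identical(b$minima$voxel, ijk_to_linear(g, c(3, 3, 3)))
})

test_that("watershed labels match the brute-force descent oracle on random grids", {
  for (seed in 1:6) {
    f <- random_field(seed, shape = sample(3:8, 3, replace = TRUE),
                      mask_frac = if (seed > 4) 0.2 else 0)
    b <- watershed(f)
    fall <- oracle_fall_to(f)
    expect_identical(is.na(fall), is.na(b$labels) | FALSE)
    ## same partition: oracle minima <-> labels are in bijection
    ok <- !is.na(fall)
    expect_identical(as.vector(tapply(b$labels[ok], fall[ok],
                                      function(x) length(unique(x)))),
                     rep(1L, length(unique(fall[ok]))))
    expect_identical(length(unique(fall[ok])), b$n_basins)
    ## each basin's labelled minimum is where the oracle descent ends
    expect_setequal(b$minima$voxel, unique(fall[ok]))
  }
})

test_that("flat plateaus drain to the smallest linear index as one basin", {
  g <- grid_spec(c(0, 0, 0), 1, c(3, 3, 3))
  f <- scalar_field(g, rep(1, 27))
  b <- watershed(f)
  expect_identical(b$n_basins, 1L)
  expect_identical(b$minima$voxel, 1L)
  ## oracle agrees with the documented tie rule
  fall <- oracle_fall_to(f)
  expect_true(all(fall == 1))
})

test_that("watershed is invariant under adding a constant", {
  f <- random_field(11, c(6, 5, 4))
  b1 <- watershed(f)
  f2 <- scalar_field(f$grid, f$values + 123.25, f$mask)
  b2 <- watershed(f2)
  expect_identical(b1$labels, b2$labels)
  expect_identical(b1$minima$voxel, b2$minima$voxel)
})

test_that("basin partition functions sum to the whole-grid partition function", {
  th <- thermo_params(300)
  f <- random_field(21, c(6, 6, 6), mask_frac = 0.15)
  b <- watershed(f, th)
  expect_identical(sum(table(b$labels[!is.na(b$labels)])),
                   sum(!f$mask))
  z_direct <- sum(exp(-th$beta * f$values[!f$mask]))
  expect_equal(sum(b$Z), z_direct, tolerance = 1e-12)
  expect_true(all(b$Z > 0))
  ## each basin minimum is <= all member energies
  for (r in seq_len(b$n_basins))
    expect_true(all(f$values[!is.na(b$labels) & b$labels == r] >=
                      b$minima$energy[r]))
})

test_that("saddles match the exhaustive min-max pair scan", {
  for (seed in c(2, 7, 13)) {
    f <- random_field(seed, c(6, 5, 5))
    b <- watershed(f)
    s <- find_saddles(f, b)
    oracle <- oracle_saddles(f, b$labels)
    expect_identical(nrow(s), length(oracle))
    for (r in seq_len(nrow(s))) {
      key <- paste(s$basin_i[r], s$basin_j[r])
      expect_equal(s$energy[r], oracle[[key]]$energy)
      expect_identical(s$saddle_voxel[r], as.integer(oracle[[key]]$voxel))
      ## saddle energy >= both basin minima
      expect_gte(s$energy[r], b$minima$energy[s$basin_i[r]])
      expect_gte(s$energy[r], b$minima$energy[s$basin_j[r]])
    }
  }
})

test_that("a 1D double well has its saddle at the barrier top", {
  g <- grid_spec(c(0, 0, 0), 1, c(7, 1, 1))
  f <- scalar_field(g, c(0, 2, 4, 6, 3, 1, 0.5))
  b <- watershed(f)
  expect_identical(b$n_basins, 2L)
  s <- find_saddles(f, b)
  expect_identical(nrow(s), 1L)
  expect_equal(s$energy, 6)
  expect_identical(s$saddle_voxel, 4L)
})

test_that("single basin gives an empty saddle set; masked walls split basins", {
  g <- grid_spec(c(0, 0, 0), 1, c(5, 1, 1))
  f1 <- scalar_field(g, c(4, 3, 2, 1, 0))
  b1 <- watershed(f1)
  expect_identical(nrow(find_saddles(f1, b1)), 0L)
  ## two wells separated by a masked wall are not neighbours: no saddle
  f2 <- scalar_field(g, c(0, 1, 50, 1, 0), mask = c(F, F, T, F, F))
  b2 <- watershed(f2)
  expect_identical(b2$n_basins, 2L)
  expect_identical(nrow(find_saddles(f2, b2)), 0L)
})

test_that("steepest-descent traces descend monotonically to the basin minimum", {
  f <- two_well_field()
  b <- watershed(f)
  s <- find_saddles(f, b)
  ## from a minimum: single-point trace
  tr0 <- steepest_descent_trace(f, b$minima$voxel[1])
  expect_identical(nrow(tr0), 1L)
  ## from the saddle: ends at one of the two minima, non-increasing energy
  tr <- steepest_descent_trace(f, s$saddle_voxel[1])
  en <- attr(tr, "energy")
  expect_true(all(diff(en) <= 0))
  expect_true(utils::tail(attr(tr, "voxel"), 1) %in% b$minima$voxel)
  ## trace agrees with the per-step oracle
  vox <- attr(tr, "voxel")
  cur <- linear_to_ijk(f$grid, vox[1])[1, ]
  for (q in seq_along(vox)) {
    expect_equal(oracle_linear(f, cur), vox[q])
    cur <- oracle_step(f, cur)
  }
})

test_that("traces never enter masked voxels", {
  g <- grid_spec(c(0, 0, 0), 1, c(5, 3, 1))
  v <- c(5, 4, 3, 2, 1,
         5, 0, 3, 2, 1,
         5, 4, 3, 2, 1)
  mask <- rep(FALSE, 15); mask[7] <- TRUE  # the 0-energy voxel is masked
  f <- scalar_field(g, v, mask)
  tr <- steepest_descent_trace(f, ijk_to_linear(g, c(0, 0, 0)))
  expect_false(7 %in% attr(tr, "voxel"))
  expect_error(steepest_descent_trace(f, 7), "masked")
})

test_that("minima networks mirror the well topology", {
  ## two wells: 2 nodes, 1 edge
  f2 <- two_well_field()
  b2 <- watershed(f2)
  net2 <- build_network(f2, b2, find_saddles(f2, b2))
  expect_identical(nrow(net2$nodes), 2L)
  expect_identical(nrow(net2$edges), 1L)
  expect_identical(length(unique(net2$nodes$component)), 1L)
  ## three collinear wells: path graph with 2 edges
  g <- grid_spec(c(0, 0, 0), 1, c(31, 7, 7))
  f3 <- make_landscape(g, list(gaussian_well(c(5, 3, 3), 12, 1.2),
                               gaussian_well(c(15, 3, 3), 12, 1.2),
                               gaussian_well(c(25, 3, 3), 12, 1.2)))
  b3 <- watershed(f3)
  expect_identical(b3$n_basins, 3L)
  net3 <- build_network(f3, b3, find_saddles(f3, b3))
  deg <- table(c(net3$edges$basin_i, net3$edges$basin_j))
  expect_identical(sort(as.integer(deg)), c(1L, 1L, 2L))
  ## single well: 1 node, 0 edges
  f1 <- make_landscape(grid_spec(c(0, 0, 0), 1, c(7, 7, 7)),
                       list(gaussian_well(c(3, 3, 3), 10, 2)))
  b1 <- watershed(f1)
  net1 <- build_network(f1, b1, find_saddles(f1, b1))
  expect_identical(nrow(net1$nodes), 1L)
  expect_identical(nrow(net1$edges), 0L)
  ## every edge trace starts at the saddle and ends at its basin minimum,
  ## non-increasing in energy
  for (r in seq_len(nrow(net2$edges))) {
    for (side in c("to_i", "to_j")) {
      tr <- net2$traces[[r]][[side]]
      en <- attr(tr, "energy")
      expect_identical(attr(tr, "voxel")[1], net2$edges$saddle_voxel[r])
      expect_true(all(diff(en) <= 1e-12))
      bas <- if (side == "to_i") net2$edges$basin_i[r] else net2$edges$basin_j[r]
      expect_identical(utils::tail(attr(tr, "voxel"), 1),
                       net2$nodes$voxel[bas])
    }
  }
})

test_that("basin labels export as an integer OpenDX map", {
  f <- two_well_field()
  b <- watershed(f)
  path <- tempfile(fileext = ".dx")
  write_basin_labels(b, path)
  lab2 <- read_volumetric(path, sentinel = NULL)
  expect_equal(as.vector(lab2$values), as.vector(b$labels))
  unlink(path)
})
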