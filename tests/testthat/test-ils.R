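test_that("diatomic model validates geometry and rejects partial charges", {
  expect_error(diatomic_model(0, 3, 0.4), "bond_length")
  expect_error(diatomic_model(1.2, -3, 0.4), "sigma")
  expect_error(diatomic_model(1.2, 3, 0.4, charge = 0.1), "charges")
  o2 <- default_o2_model()
  expect_identical(o2$charge, c(0, 0))
})

test_that("alignment recovers a known rigid transform", {
  fs <- make_cavity_frames(1, jitter = 0, seed = 1)
  ref <- fs$coords[[1]]
  ## identity: frame equal to reference stays put with RMSD 0
  al0 <- align_frames(fs, ref)
  expect_equal(al0$coords[[1]], ref)
  expect_equal(attr(al0, "rmsd"), 0)
  ## rotate + translate by known amounts, then recover
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- frameset(list(ref %*% t(rot) + matrix(c(3, -2, 5), nrow(ref), 3,
                                                 byrow = TRUE)),
                    fs$sigma, fs$epsilon)
  al <- align_frames(moved, ref)
  expect_lt(attr(al, "rmsd"), 1e-6)
  expect_equal(al$coords[[1]], ref, tolerance = 1e-6)
  ## post-fit selection RMSD never exceeds pre-fit
  set.seed(2)
  noisy <- frameset(list(ref + matrix(rnorm(length(ref), sd = 0.3),
                                      ncol = 3)), fs$sigma, fs$epsilon)
  pre <- sqrt(mean(rowSums((noisy$coords[[1]] - ref)^2)))
  expect_lte(attr(align_frames(noisy, ref), "rmsd"), pre)
})

test_that("alignment with fewer than 3 selected atoms is an error", {
  fs <- make_cavity_frames(1, jitter = 0, seed = 1)
  expect_error(align_frames(fs, fs$coords[[1]], selection = c(1, 2)),
               "at least 3")
})

test_that("insertion energy matches the closed-form LJ expression", {
  lig <- diatomic_model(1.0, sigma = 3, epsilon = 0.4)
  sig_c <- (3 + 3) / 2
  eps_c <- sqrt(0.5 * 0.4)
  ## place the single atom equidistant (distance d) from both ligand sites:
  ## atom on the perpendicular bisector of the bond
  for (d in c(sig_c, 2^(1/6) * sig_c, 4)) {
    h <- sqrt(d^2 - 0.5^2)  # bond half-length 0.5
    e <- insertion_energy(matrix(c(0, h, 0), 1, 3), sigma = 3, epsilon = 0.5,
                          lig, position = c(0, 0, 0), orientation = c(1, 0, 0))
    expected <- 2 * 4 * eps_c * ((sig_c / d)^12 - (sig_c / d)^6)
    expect_equal(e, expected, tolerance = 1e-12)
  }
  ## d = sigma_c gives 0; d at the LJ minimum gives -2 eps_c
  h <- sqrt(sig_c^2 - 0.25)
  expect_equal(insertion_energy(matrix(c(0, h, 0), 1, 3), 3, 0.5, lig,
                                c(0, 0, 0), c(1, 0, 0)), 0, tolerance = 1e-12)
  h <- sqrt((2^(1/6) * sig_c)^2 - 0.25)
  expect_equal(insertion_energy(matrix(c(0, h, 0), 1, 3), 3, 0.5, lig,
                                c(0, 0, 0), c(1, 0, 0)), -2 * eps_c,
               tolerance = 1e-12)
})

test_that("insertion energy honors cutoff, clamp, and combination rule", {
  lig <- diatomic_model(1.0, sigma = 3, epsilon = 0.4)
  ## atoms beyond the cutoff contribute nothing
  far <- matrix(c(60, 0, 0), 1, 3)
  expect_identical(insertion_energy(far, 3, 0.5, lig, c(0, 0, 0),
                                    c(1, 0, 0), cutoff = 10), 0)
  ## site coincident with an atom clamps instead of diverging
  onsite <- matrix(c(0.5, 0, 0), 1, 3)
  expect_identical(insertion_energy(onsite, 3, 0.5, lig, c(0, 0, 0),
                                    c(1, 0, 0)), 1e4)
  ## geometric sigma combination differs from Lorentz-Berthelot for
  ## unequal sigmas
  lig2 <- diatomic_model(1.0, sigma = 2, epsilon = 0.4)
  a <- matrix(c(0, 4, 0), 1, 3)
  e_lb <- insertion_energy(a, 3.5, 0.5, lig2, c(0, 0, 0), c(1, 0, 0))
  e_geom <- insertion_energy(a, 3.5, 0.5, lig2, c(0, 0, 0), c(1, 0, 0),
                             combine = "geometric")
  expect_false(isTRUE(all.equal(e_lb, e_geom)))
})

test_that("ILS landscape is zero for an empty frame set and seeded", {
  g <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  fs0 <- frameset(list(matrix(numeric(0), 0, 3)), numeric(0), numeric(0))
  l0 <- ils_landscape(fs0, default_o2_model(), g, 10, thermo_params(), seed = 1)
  expect_true(all(l0$values == 0))
  fs <- frameset(list(matrix(c(1.5, 1.5, 1.5), 1, 3)), 3, 0.5)
  la <- ils_landscape(fs, default_o2_model(), g, 50, thermo_params(), seed = 5)
  lb <- ils_landscape(fs, default_o2_model(), g, 50, thermo_params(), seed = 5)
  lc <- ils_landscape(fs, default_o2_model(), g, 50, thermo_params(), seed = 6)
  expect_identical(la$values, lb$values)
  expect_false(identical(la$values, lc$values))
  expect_error(ils_landscape(frameset(list(), 1, 1), grid = g), "non-empty")
})

test_that("degenerate single-draw PMF reproduces the insertion energy", {
  ## M = 1, C = 1 on a vanishingly small voxel with a point-like ligand:
  ## PMF = -kT log(exp(-beta dE)) = dE at the voxel center
  g <- grid_spec(c(0, 0, 0), 1e-9, c(1, 1, 1))
  fs <- frameset(list(matrix(c(2.8, 0, 0), 1, 3)), 3, 0.5)
  lig <- diatomic_model(1e-9, sigma = 3, epsilon = 0.4)
  l <- ils_landscape(fs, lig, g, insertions_per_voxel = 1,
                     thermo = thermo_params(), seed = 2)
  expected <- insertion_energy(fs$coords[[1]], 3, 0.5, lig, c(0, 0, 0),
                               c(0, 0, 1))
  expect_equal(l$values[1, 1, 1], expected, tolerance = 1e-5)
})

test_that("landscape is invariant under joint translation of frames and grid", {
  fs <- frameset(list(matrix(c(2, 2, 2), 1, 3),
                      matrix(c(2.2, 1.9, 2.1), 1, 3)), 3, 0.5)
  g <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  l1 <- ils_landscape(fs, default_o2_model(), g, 60, thermo_params(), seed = 3)
  shift <- c(11.5, -4, 7.25)
  fs2 <- frameset(lapply(fs$coords, function(x)
    sweep(x, 2, shift, `+`)), fs$sigma, fs$epsilon)
  g2 <- grid_spec(shift, 1, c(4, 4, 4))
  l2 <- ils_landscape(fs2, default_o2_model(), g2, 60, thermo_params(), seed = 3)
  ## same draws, same geometry; equality up to floating-point associativity
  ## of the shifted coordinate differences
  expect_equal(l1$values, l2$values, tolerance = 1e-12)
  expect_identical(l1$mask, l2$mask)
})

test_that("PMF vanishes far from atoms and is positive in repulsive cores", {
  fs <- frameset(list(matrix(c(0, 0, 0), 1, 3)), 3, 0.5)
  g <- grid_spec(c(14, -1, -1), 1, c(3, 3, 3))  # 13+ A away from the atom
  l <- ils_landscape(fs, default_o2_model(), g, 100, thermo_params(), seed = 4,
                     cutoff = 10)
  expect_true(all(abs(l$values) < 0.05))
  gc <- grid_spec(c(0, 0, 0), 1, c(1, 1, 1))    # on top of the atom
  lc <- ils_landscape(fs, default_o2_model(), gc, 100, thermo_params(), seed = 4)
  expect_true(lc$mask[1, 1, 1] || lc$values[1, 1, 1] > 0)
})

test_that("per-voxel PMF scatter across seeds shrinks as C grows", {
  fs <- frameset(list(matrix(c(2.5, 2.5, 2.5), 1, 3)), 3, 0.5)
  g <- grid_spec(c(0, 0.5, 0.5), 1, c(4, 4, 4))
  spread <- sapply(c(25, 400), function(C) {
    reps <- sapply(1:10, function(s)
      ils_landscape(fs, default_o2_model(), g, C, thermo_params(),
                    seed = s)$values[2, 3, 3])
    sd(reps)
  })
  expect_lt(spread[2], spread[1])
})

test_that("M identical frames agree in mean with one frame at M*C draws", {
  fs1 <- frameset(list(matrix(c(2, 2, 2), 1, 3)), 3, 0.5)
  fsM <- frameset(rep(fs1$coords, 10), 3, 0.5)
  g <- grid_spec(c(3.5, 1.5, 1.5), 1, c(2, 2, 2))
  a <- sapply(1:6, function(s)
    ils_landscape(fsM, default_o2_model(), g, 40, thermo_params(),
                  seed = s)$values[1, 1, 1])
  b <- sapply(1:6, function(s)
    ils_landscape(fs1, default_o2_model(), g, 400, thermo_params(),
                  seed = 10 + s)$values[1, 1, 1])
  se <- sqrt(var(a) / 6 + var(b) / 6)
  expect_lt(abs(mean(a) - mean(b)), 4 * se + 1e-3)
})

test_that("water reference averages unmasked voxels with 8.30 default", {
  expect_identical(water_reference(), 8.30)
  g <- grid_spec(c(0, 0, 0), 1, c(3, 1, 1))
  expect_equal(water_reference(scalar_field(g, c(1, 2, 3))), 2)
  uni <- scalar_field(g, rep(8.30, 3))
  expect_equal(water_reference(uni), 8.30)
  allmask <- scalar_field(g, c(1, 2, 3), mask = rep(TRUE, 3))
  expect_error(water_reference(allmask), "masked")
})
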