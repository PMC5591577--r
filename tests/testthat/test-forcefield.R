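test_that("OPLS Fourier torsion energy matches hand values and is periodic", {
  expect_equal(torsion_energy(180, 1, 0, 0), 0)
  expect_equal(torsion_energy(0, 1, 0, 0), 1)
  expect_equal(torsion_energy(90, 0, 2, 0), 2)
  set.seed(1)
  for (k in 1:20) {
    V <- runif(3, -2, 2)
    th <- runif(1, -720, 720)
    expect_equal(torsion_energy(th, V[1], V[2], V[3]),
                 torsion_energy(th + 360, V[1], V[2], V[3]),
                 tolerance = 1e-12)
  }
  # non-negative when all amplitudes are non-negative
  th <- seq(0, 359.5, by = 0.5)
  expect_true(all(torsion_energy(th, 0.7, 1.3, 0.2) >= 0))
})

test_that("nonbonded pair energy reproduces LJ and Coulomb landmarks", {
  # LJ vanishes at r = sigma, reaches -eps at the 2^(1/6) sigma minimum
  expect_equal(nonbonded_pair_energy(3.2, 0, 0, 3.2, 3.2, 0.2, 0.2), 0)
  expect_equal(nonbonded_pair_energy(2^(1 / 6) * 3.2, 0, 0, 3.2, 3.2,
                                     0.2, 0.2), -0.2)
  # bare Coulomb: 332.06 * 0.25 / 5
  expect_equal(nonbonded_pair_energy(5, 0.5, 0.5, 3, 3, 0, 0), 16.603)
  # 1-4 scaling halves both terms
  expect_equal(nonbonded_pair_energy(5, 0.5, 0.5, 3, 3, 0.1, 0.1, 0.5),
               0.5 * nonbonded_pair_energy(5, 0.5, 0.5, 3, 3, 0.1, 0.1))
  expect_error(nonbonded_pair_energy(0, 0, 0, 3, 3, 0.1, 0.1),
               "overlap")
  # decays to zero at long range
  expect_lt(abs(nonbonded_pair_energy(60, 0, 0, 3.4, 3.4, 0.3, 0.3)), 1e-6)
  expect_lt(abs(nonbonded_pair_energy(500, 0.2, -0.2, 3.4, 3.4, 0.3, 0.3)),
            0.03)
})

test_that("region decomposition conserves the brute-force total energy", {
  for (seed in 1:60) {
    sys <- random_system(n_extra = 5, seed = seed)
    dec <- total_energy(sys)
    expect_equal(dec$e_ss + dec$e_sw + dec$e_ww, dec$total)
    expect_equal(dec$total, brute_total(sys), tolerance = 1e-9)
  }
})

test_that("pure-environment and mixed two-atom systems decompose correctly", {
  sys <- random_system(seed = 3)
  sys$atoms$region[] <- "ENVIRONMENT"
  sys <- toy_system(sys$atoms, sys$fragments, sys$torsions,
                    sys$exclusions, sys$pairs14)
  dec <- total_energy(sys)
  expect_equal(dec$e_ss, 0)
  expect_equal(dec$e_sw, 0)

  two <- data.frame(x = c(0, 4), y = 0, z = 0, charge = c(0.2, -0.2),
                    sigma = 3.2, epsilon = 0.15,
                    region = c("LIGAND", "ENVIRONMENT"), mobile = TRUE)
  s2 <- toy_system(two, list(1L, 2L))
  d2 <- total_energy(s2)
  expect_equal(d2$e_ss, 0)
  expect_equal(d2$e_ww, 0)
  expect_equal(d2$e_sw,
               nonbonded_pair_energy(4, 0.2, -0.2, 3.2, 3.2, 0.15, 0.15))
})

test_that("total energy is invariant under rigid motion of the whole system", {
  for (seed in 1:10) {
    sys <- random_system(seed = seed)
    e0 <- total_energy(sys)$total
    moved <- transform_atoms(sys, shift = c(3.1, -2.2, 0.7),
                             axis = c(1, 2, 3), angle = 67,
                             center = c(0.5, 0.5, 0.5))
    expect_equal(total_energy(moved)$total, e0, tolerance = 1e-9)
  }
})

test_that("overlapping atoms raise an error", {
  two <- data.frame(x = c(1, 1), y = 2, z = 3, charge = 0, sigma = 3,
                    epsilon = 0.1, region = "LIGAND", mobile = TRUE)
  s <- toy_system(two, list(1L, 2L))
  expect_error(total_energy(s), "overlap")
})

test_that("toy_system enforces its invariants", {
  a <- data.frame(x = 1:4, y = 0, z = 0, charge = 0, sigma = 3,
                  epsilon = 0.1, region = "LIGAND", mobile = TRUE)
  expect_error(toy_system(a, list(1:2)), "partition")
  bad <- a; bad$sigma[2] <- -1
  expect_error(toy_system(bad, list(1:2, 3:4)), "sigma")
  expect_error(
    toy_system(a, list(1:2, 3:4),
               exclusions = rbind(c(1, 4)), pairs14 = rbind(c(1, 4))),
    "disjoint")
  # rotatable bond must join two fragments
  expect_error(
    toy_system(a, list(1:4),
               torsions = data.frame(a1 = 1, a2 = 2, a3 = 3, a4 = 4,
                                     V1 = 1, V2 = 0, V3 = 0)),
    "two different rigid fragments")
})

test_that("set_torsion reaches the requested dihedral and moves only one side", {
  sys <- make_rotor(1, 0.5, 0.2, angle = 45)
  expect_equal(unname(torsion_angles(sys)[1]), 45, tolerance = 1e-9)
  s2 <- set_torsion(sys, 1, 300)
  expect_equal(unname(torsion_angles(s2)[1]), 300, tolerance = 1e-9)
  expect_equal(as.matrix(s2$atoms[1:2, c("x", "y", "z")]),
               as.matrix(sys$atoms[1:2, c("x", "y", "z")]))
})
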