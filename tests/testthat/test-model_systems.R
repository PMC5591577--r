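test_that("the isolated rotor's energy is exactly its torsion term", {
  sys <- make_rotor(1.1, 0.3, 0.7, angle = 25)
  expect_equal(total_energy(sys)$total, torsion_energy(25, 1.1, 0.3, 0.7))
  flat <- make_rotor(0, 0, 0)
  for (a in c(0, 77, 191, 304))
    expect_equal(total_energy(set_torsion(flat, 1, a))$total, 0)
  # the 2-fold well has its minima at 0 and 180 and maxima at 90/270
  dbl <- make_rotor(0, 2, 0)
  e <- vapply(c(0, 90, 180, 270),
              function(a) total_energy(set_torsion(dbl, 1, a))$total,
              numeric(1))
  expect_equal(e, c(0, 2, 0, 2))
})

test_that("rotor quadrature oracle: identity, uniformity, Bessel closed form", {
  orc <- rotor_oracle(c(1, 2, 0.5), c(1, 2, 0.5))
  expect_equal(orc$dG, 0)
  flat <- rotor_oracle(c(0, 0, 0), c(0, 0, 0))
  expect_equal(flat$density_A, rep(1 / 360, length(flat$theta)),
               tolerance = 1e-9)
  # V1-only: dG(0 -> V1) = V1/2 - kT ln I0(V1 / 2kT)
  for (V1 in c(0.8, 1.7, 3.0)) {
    closed <- V1 / 2 - kT(298.15) * log(besselI(V1 / (2 * kT(298.15)), 0))
    expect_equal(rotor_oracle(c(0, 0, 0), c(V1, 0, 0))$dG, closed,
                 tolerance = 1e-7)
  }
})

test_that("quadrature converges: halving the grid moves dG below 1e-8", {
  VA <- c(1.3, 0.4, 0.9); VB <- c(0.2, 1.1, 0.1)
  d1 <- rotor_oracle(VA, VB, grid_deg = 0.1)$dG
  d2 <- rotor_oracle(VA, VB, grid_deg = 0.05)$dG
  expect_lt(abs(d1 - d2), 1e-8)
})

test_that("pocket complexes are deterministic with the documented atom count", {
  s1 <- make_pocket_complex(substituent = "F", seed = 3)
  s2 <- make_pocket_complex(substituent = "F", seed = 3)
  expect_identical(s1$atoms, s2$atoms)
  s3 <- make_pocket_complex(substituent = "F", seed = 4)
  expect_false(identical(s1$atoms, s3$atoms))
  # 2 rings of 6 + substituent + 3-site rotor + cage
  spec <- pocket_spec()
  expect_equal(nrow(s1$atoms), 2 * 6 + 1 + 3 + spec$n_cage_sites)
  expect_equal(sum(s1$atoms$region == "LIGAND"), 13)
  expect_equal(sum(s1$atoms$region == "HOT_RESIDUE"), 3)
  expect_equal(rownames(s1$torsions), c("phi", "chi"))
  expect_error(make_pocket_complex(substituent = "XX"), "unknown")
})

test_that("every substituent's landscape has two minima behind a > 2 kT barrier", {
  for (sub in substituent_table()$label) {
    sys <- make_pocket_complex(substituent = sub, seed = 1)
    chk <- check_pocket_landscape(sys, min_barrier_kT = 2, step = 10)
    expect_true(chk$ok)
    expect_gte(nrow(chk$minima), 2)
    # the low-lying side-chain rotamers lie near chi = 60 or 180
    top <- chk$minima[chk$minima$energy <= min(chk$minima$energy) + 1, ]
    circ <- function(a, b) pmin(abs(a - b), 360 - abs(a - b))
    expect_true(all(pmin(circ(top$chi, 60), circ(top$chi, 180)) <= 40))
  }
})

test_that("the unbound ligand keeps only the ligand and its linker torsion", {
  sys <- make_pocket_complex(substituent = "CL", seed = 1)
  unb <- unbound_ligand(sys)
  expect_equal(nrow(unb$atoms), 13)
  expect_true(all(unb$atoms$region == "LIGAND"))
  expect_equal(nrow(unb$torsions), 1)
  # energies of ligand-internal terms are preserved
  e_unb <- total_energy(unb)$total
  lig <- which(sys$atoms$region == "LIGAND")
  p <- sys$pairs
  keep <- p$i %in% lig & p$j %in% lig
  pos <- as.matrix(sys$atoms[, c("x", "y", "z")])
  e_pairs <- sum(restfep:::pair_energy_from_table(
    restfep:::pair_table(sys)[keep, , drop = FALSE],
    rowSums((pos[p$i[keep], , drop = FALSE] -
               pos[p$j[keep], , drop = FALSE])^2)))
  e_phi <- torsion_energy(torsion_angles(sys)[1], sys$torsions$V1[1],
                          sys$torsions$V2[1], sys$torsions$V3[1])
  expect_equal(e_unb, e_pairs + unname(e_phi), tolerance = 1e-9)
})

test_that("substituent parameters are monotone in size for the halogen series", {
  tab <- substituent_table()
  halo <- tab[match(c("H", "F", "CL", "BR"), tab$label), ]
  expect_true(all(diff(halo$sigma) > 0))
})
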