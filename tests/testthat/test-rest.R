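test_that("REST2 scaling reproduces hand values and rejects bad ratios", {
  d <- energy_decomposition(10, 4, 2)
  expect_equal(scaled_energy(d, 1), 16)
  expect_equal(scaled_energy(d, 0.25), 0.25 * 10 + 0.5 * 4 + 2)
  d0 <- energy_decomposition(0, 0, 7)
  expect_equal(scaled_energy(d0, 0.3), scaled_energy(d0, 1))
  expect_error(scaled_energy(d, 0), "beta_ratio")
  expect_error(scaled_energy(d, 1.2), "beta_ratio")
})

test_that("swap acceptance matches the hand-enumerated two-replica case", {
  # two configurations with known decompositions on rungs r = 1 and 0.25
  xm <- energy_decomposition(3.0, 1.0, 5.0)   # held by replica m (r = 1)
  xn <- energy_decomposition(1.0, 2.0, 5.0)   # held by replica n (r = 0.25)
  rm_ <- 1; rn <- 0.25
  Em <- function(d, r) r * d$e_ss + sqrt(r) * d$e_sw + d$e_ww
  delta_hand <- (Em(xn, rm_) - Em(xm, rm_) + Em(xm, rn) - Em(xn, rn)) /
    kT(298.15)
  res <- attempt_swap(list(decomp = xm, r = rm_), list(decomp = xn, r = rn),
                      draw = 0)
  expect_equal(res$delta, delta_hand)
  # acceptance frequency over draws equals exp(-delta)
  set.seed(4)
  acc <- mean(replicate(20000, attempt_swap(
    list(decomp = xm, r = rm_), list(decomp = xn, r = rn))$accepted))
  expect_lt(abs(acc - min(1, exp(-delta_hand))),
            3 * sqrt(0.25 / 20000) + 0.01)
  # accepted swaps exchange the configurations
  expect_equal(res$state_m$decomp$e_ss, 1.0)
  expect_equal(res$state_n$decomp$e_ss, 3.0)
})

test_that("swap probability is symmetric and identical states always swap", {
  set.seed(9)
  for (k in 1:25) {
    dm <- energy_decomposition(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5))
    dn <- energy_decomposition(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5))
    rm_ <- runif(1, 0.2, 1); rn <- runif(1, 0.2, 1)
    d1 <- attempt_swap(list(decomp = dm, r = rm_),
                       list(decomp = dn, r = rn), draw = 0)$delta
    d2 <- attempt_swap(list(decomp = dn, r = rn),
                       list(decomp = dm, r = rm_), draw = 0)$delta
    expect_equal(d1, d2, tolerance = 1e-12)
    # environment-environment energy cancels exactly
    dm2 <- dm; dm2$e_ww <- dm$e_ww + 100
    d3 <- attempt_swap(list(decomp = dm2, r = rm_),
                       list(decomp = dn, r = rn), draw = 0)$delta
    expect_equal(d1, d3, tolerance = 1e-9)
  }
  same <- list(decomp = energy_decomposition(1, 2, 3), r = 0.5)
  expect_true(attempt_swap(same, same, draw = 1 - 1e-12)$accepted)
})

test_that("a single-replica REST run follows the same path as plain MC", {
  sys <- make_rotor(0.8, 0.6, 0.4)
  cfg <- chain_config(4000, seed = 13, record_every = 5)
  plain <- run_chain(sys, cfg)
  rest1 <- run_rest(sys, cfg, replica_ladder(n_replicas = 1))
  expect_identical(plain$frames, rest1$trajectory$frames)
})

test_that("equal effective temperatures accept every swap", {
  sys <- make_rotor(0.5, 1, 0)
  lad <- replica_ladder(n_replicas = 3, t_max = 1200, swap_every = 50)
  lad$r[] <- 1
  lad$effective_temperatures[] <- lad$effective_temperatures[1]
  rr <- run_rest(sys, chain_config(2000, seed = 2), lad)
  expect_true(all(rr$swap_log$accepted == 1))
})

test_that("REST demux recovers the thermal Boltzmann marginal across ladder sizes", {
  V <- c(0.8, 1.2, 0)
  p <- rotor_bin_probs(V, breaks = seq(0, 360, 30))
  for (nrep in c(2, 4)) {
    rr <- run_rest(make_rotor(V[1], V[2], V[3]),
                   chain_config(80000, seed = 30 + nrep, record_every = 20),
                   replica_ladder(nrep, t_max = 900, swap_every = 100))
    h <- dihedral_histogram(rr$trajectory, 1, 30)
    expect_gt(chisq_pval(h$fraction, h$n, p), 0.01)
  }
})

test_that("the permutation history is a bijection at every epoch", {
  rr <- run_rest(make_rotor(0, 6, 0),
                 chain_config(5000, seed = 77, record_every = 50),
                 replica_ladder(4, t_max = 1200, swap_every = 100))
  perm <- rr$permutation
  expect_gt(nrow(perm), 0)
  for (e in seq_len(nrow(perm)))
    expect_setequal(perm[e, ], 1:4)
})

test_that("an empty hot region is rejected", {
  two <- data.frame(x = c(0, 4), y = 0, z = 0, charge = 0, sigma = 3,
                    epsilon = 0.1, region = "ENVIRONMENT", mobile = TRUE)
  sys <- toy_system(two, list(1L, 2L))
  expect_error(run_rest(sys, chain_config(10, seed = 1)), "hot region")
})
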