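test_that("Zwanzig estimator handles degenerate and closed-form sample sets", {
  kt <- kT(298.15)
  expect_equal(zwanzig(rep(0, 100))$dG, 0)
  expect_equal(zwanzig(rep(1.7, 50))$dG, 1.7)
  expect_equal(zwanzig(rep(1.7, 50))$stderr, 0)
  # alternating {0, kT ln 4}: <exp(-dE/kT)> = (1 + 1/4)/2
  de <- rep(c(0, kt * log(4)), 500)
  expect_equal(zwanzig(de)$dG, kt * log(1.6), tolerance = 1e-12)
  # huge gaps must not overflow thanks to the max-shift guard
  expect_true(is.finite(zwanzig(c(-5000, -4999))$dG))
  expect_error(zwanzig(numeric(0)), "sample")
  expect_error(zwanzig(1, temperature = 0), "temperature")
})

test_that("lambda schedules must ascend strictly from 0 to 1", {
  expect_equal(length(lambda_schedule(11)), 11)
  expect_error(lambda_schedule(values = c(0, 0.5, 0.9)), "ascend")
  expect_error(lambda_schedule(values = c(0.1, 0.5, 1)), "ascend")
  expect_error(lambda_schedule(values = c(0, 0.5, 0.5, 1)), "ascend")
})

test_that("a null mutation yields identically zero perturbation energies", {
  sys <- make_rotor(1, 0.5, 0)
  map <- rotor_map(c(1, 0.5, 0), c(1, 0.5, 0))
  cfg <- chain_config(2000, seed = 3, record_every = 10)
  win <- run_window(sys, map, 0.5, c(0, 1), cfg)
  expect_true(all(win$de_fwd == 0))
  expect_true(all(win$de_bwd == 0))
  leg <- run_leg(sys, map, lambda_schedule(3), cfg)
  expect_equal(leg$total, 0)
  expect_equal(leg$hysteresis, 0)
})

test_that("window boundaries only store the available direction", {
  sys <- make_rotor(0.5, 0, 0)
  map <- rotor_map(c(0.5, 0, 0), c(1.5, 0, 0))
  cfg <- chain_config(1000, seed = 5, record_every = 10)
  w0 <- run_window(sys, map, 0, c(NA, 0.5), cfg)
  expect_null(w0$de_bwd)
  expect_false(is.null(w0$de_fwd))
  expect_error(run_window(sys, alchemical_map(), 0, c(NA, 0.5), cfg),
               "empty")
})

test_that("stored perturbation energies equal a full-energy recomputation", {
  sys <- make_pocket_complex(substituent = "F", seed = 1)
  map <- substituent_map(sys, "F", "CL")
  cfg <- chain_config(300, seed = 21, record_every = 20,
                      equil_fraction = 0, record_positions = TRUE)
  win <- run_window(sys, map, 0.4, c(0.2, 0.6), cfg)
  tr <- win$trajectory
  for (f in seq_len(nrow(tr$frames))) {
    s2 <- sys
    s2$atoms[, c("x", "y", "z")] <- matrix(tr$positions[f, ], ncol = 3,
                                           byrow = TRUE)
    e_i <- total_energy(s2, map, 0.4)$total
    expect_equal(win$de_fwd[f], total_energy(s2, map, 0.6)$total - e_i,
                 tolerance = 1e-7)
    expect_equal(win$de_bwd[f], total_energy(s2, map, 0.2)$total - e_i,
                 tolerance = 1e-7)
  }
})

test_that("leg assembly adds window increments and flags schedule gaps", {
  mkwin <- function(lam, lp, ln, fwd, bwd) {
    structure(list(lambda = lam, lambda_prev = lp, lambda_next = ln,
                   de_fwd = fwd, de_bwd = bwd), class = "fep_window")
  }
  # two constant-increment windows: total = 2c exactly
  c0 <- 0.35
  wins <- list(mkwin(0, NA, 0.5, rep(c0, 40), NULL),
               mkwin(0.5, 0, 1, rep(c0, 40), rep(-c0, 40)),
               mkwin(1, 0.5, NA, NULL, rep(-c0, 40)))
  leg <- assemble_leg(wins)
  expect_equal(leg$forward, 2 * c0)
  expect_equal(leg$backward, -2 * c0)
  expect_equal(leg$total, 2 * c0)
  expect_equal(leg$hysteresis, 0)
  expect_error(assemble_leg(wins, schedule = lambda_schedule(11)),
               "contiguous")
  broken <- wins
  broken[[2]]$de_fwd <- NULL
  expect_error(assemble_leg(broken), "gap")
})

test_that("rotor FEP agrees with the quadrature oracle", {
  set.seed(31)
  for (k in 1:2) {
    VA <- runif(3, -1, 1.5); VB <- runif(3, -1, 1.5)
    sys <- make_rotor(VA[1], VA[2], VA[3])
    leg <- run_leg(sys, rotor_map(VA, VB), lambda_schedule(6),
                   chain_config(20000, seed = 40 + k, record_every = 10))
    exact <- rotor_oracle(VA, VB)$dG
    expect_lt(abs(leg$total - exact), 3 * leg$stderr + 0.01)
    expect_lt(leg$hysteresis, 3 * sqrt(2) * leg$stderr + 0.01)
  }
})

test_that("binding ddG is antisymmetric under reversing the mutation", {
  cfg <- chain_config(12000, seed = 51, record_every = 10)
  lad <- replica_ladder(4, t_max = 1200, swap_every = 100)
  sysF <- make_pocket_complex(substituent = "F", seed = 1)
  ab <- run_binding_cycle(sysF, substituent_map(sysF, "F", "CL"), cfg,
                          lambda_schedule(6), ladder = lad)
  sysC <- make_pocket_complex(substituent = "CL", seed = 1)
  cfg2 <- cfg; cfg2$seed <- 52
  ba <- run_binding_cycle(sysC, substituent_map(sysC, "CL", "F"), cfg2,
                          lambda_schedule(6), ladder = lad)
  expect_lt(abs(ab$ddg + ba$ddg),
            3 * sqrt(ab$stderr^2 + ba$stderr^2) + 0.03)
})

test_that("ddg_binding validates schedules and subtracts the legs", {
  mk <- function(tot, se, lam = c(0, 1)) {
    structure(list(leg = "X", windows = data.frame(lambda = lam),
                   total = tot, stderr = se), class = "free_energy_result")
  }
  cyc <- ddg_binding(mk(-0.5, 0.1), mk(0, 0.2))
  expect_equal(cyc$ddg, -0.5)
  expect_equal(cyc$stderr, sqrt(0.01 + 0.04))
  expect_error(ddg_binding(mk(0, 0.1), mk(0, 0.1, lam = c(0, 0.5, 1))),
               "schedule")
})
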