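test_that("dihedral histograms bin circularly and normalize", {
  h <- dihedral_histogram(rep(185, 50), bin_width = 10)
  expect_equal(h$fraction[19], 1)   # the [180, 190) bin
  expect_equal(sum(h$fraction), 1)
  set.seed(2)
  hu <- dihedral_histogram(runif(20000, 0, 360), bin_width = 10)
  expect_gt(chisq.test(hu$fraction * hu$n)$p.value, 0.01)
  # angles outside [0, 360) wrap
  hw <- dihedral_histogram(c(-10, 350, 710), bin_width = 10)
  expect_equal(hw$fraction[36], 1)
  expect_error(dihedral_histogram(numeric(0)), "no angles")
  expect_error(dihedral_histogram(1:10, bin_width = 7), "divide")
})

test_that("random histograms always tile the circle and sum to one", {
  set.seed(33)
  for (k in 1:20) {
    w <- sample(c(5, 10, 20, 30, 45), 1)
    h <- dihedral_histogram(runif(200, -720, 720), bin_width = w)
    expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
    expect_equal(h$breaks[1], 0)
    expect_equal(h$breaks[length(h$breaks)], 360)
    expect_equal(diff(h$breaks), rep(w, 360 / w))
  }
})

test_that("mode populations and the symmetric-mode entropy term", {
  m1 <- mode_populations_entropy(rep(178, 100), 180)
  expect_equal(m1$population, 1)
  expect_equal(m1$TdS, 0)
  # two equally populated modes: TdS = kT ln 2 = 0.411 kcal/mol
  m2 <- mode_populations_entropy(c(rep(0, 50), rep(180, 50)), c(0, 180))
  expect_equal(m2$population, c(0.5, 0.5))
  expect_equal(m2$TdS, kT(298.15) * log(2), tolerance = 1e-12)
  expect_equal(round(m2$TdS, 3), 0.411)
  # maximal entropy iff uniform over M modes
  m3 <- mode_populations_entropy(c(rep(10, 30), rep(130, 30), rep(250, 30)),
                                 c(10, 130, 250))
  expect_equal(m3$TdS, kT(298.15) * log(3), tolerance = 1e-12)
  skew <- mode_populations_entropy(c(rep(10, 60), rep(130, 20), rep(250, 10)),
                                   c(10, 130, 250))
  expect_lt(skew$TdS, m3$TdS)
  # nearest-center assignment is circular; ties go to the first center
  m4 <- mode_populations_entropy(c(359, 1), c(0, 180))
  expect_equal(m4$population, c(1, 0))
  m5 <- mode_populations_entropy(90, c(0, 180))
  expect_equal(m5$assignment, 1L)
  expect_error(mode_populations_entropy(numeric(0), 0), "no angles")
  expect_error(mode_populations_entropy(1:5, numeric(0)), "mode center")
})

test_that("IC50 converts to the relative free energy scale", {
  expect_equal(experimental_dg(1), 0)
  expect_equal(experimental_dg(289) - experimental_dg(75.9), 0.79,
               tolerance = 0.005)
  expect_equal(experimental_dg(10, temperature = 298.15),
               0.0019872 * 298.15 * log(10))
  expect_error(experimental_dg(-1), "positive")
})

test_that("benchmark statistics: exact agreement, offset invariance", {
  rec <- data.frame(compound = 1:4, ddg_kcal = c(-1, 0, 0.5, 1.2),
                    ic50_uM = exp(c(-1, 0, 0.5, 1.2) / kT(298.15)))
  st <- benchmark_stats(rec)
  expect_equal(st$mue, 0, tolerance = 1e-12)
  expect_equal(st$rmse, 0, tolerance = 1e-12)
  expect_equal(st$pearson_r, 1)
  # adding any constant to the computed values changes nothing
  shifted <- rec; shifted$ddg_kcal <- rec$ddg_kcal + 3.7
  st2 <- benchmark_stats(shifted)
  expect_equal(st2$mue, st$mue, tolerance = 1e-12)
  expect_equal(st2$rmse, st$rmse, tolerance = 1e-12)
  expect_equal(st2$pearson_r, st$pearson_r)
  expect_error(benchmark_stats(rec[1, ]), "two complete")
})

test_that("the packaged benchmark fixture reproduces its frozen statistics", {
  path <- system.file("extdata", "fragment_series_benchmark.csv", package = "restfep")
  rec <- read_benchmark(path)
  expect_equal(nrow(rec), 10)
  st <- benchmark_stats(rec)
  expect_equal(st$n, 8)   # two compounds lack measured IC50
  # frozen by independent spreadsheet-style recomputation of the fixture
  expect_equal(st$mue, 0.2670209, tolerance = 1e-6)
  expect_equal(st$rmse, 0.3383575, tolerance = 1e-6)
  expect_equal(st$pearson_r, 0.848377, tolerance = 1e-6)
})

test_that("starting-structure consistency compares totals against tolerance", {
  same <- starting_structure_consistency(c(-0.5, -0.5), tol_kcal = 0.01)
  expect_true(same$pass)
  expect_equal(same$spread, 0)
  near <- starting_structure_consistency(c(-0.73, -0.80), tol_kcal = 0.15)
  expect_true(near$pass)
  expect_equal(near$spread, 0.07)
  far <- starting_structure_consistency(c(0, 1), tol_kcal = 0.1)
  expect_false(far$pass)
  expect_error(starting_structure_consistency(0.5), "two results")
  # default tolerance: three times the combined stderr
  mk <- function(tot, se) structure(list(total = tot, stderr = se),
                                    class = "free_energy_result")
  auto <- starting_structure_consistency(list(mk(0, 0.05), mk(0.1, 0.05)))
  expect_equal(auto$tol, 3 * sqrt(2 * 0.05^2))
  expect_true(auto$pass)
})
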