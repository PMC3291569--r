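test_that("steady-state age distribution is correctly normalized and integrable", {
  expect_equal(age_pdf(0), 2 * log(2))
  expect_equal(age_pdf(1 - 1e-12), log(2), tolerance = 1e-9)
  expect_equal(stats::integrate(age_pdf, 0, 1 - 1e-12)$value, 1, tolerance = 1e-6)
  expect_equal(age_cdf(0), 0)
  expect_equal(age_cdf(1), 1)
  # CDF is the exact integral of the PDF
  for (a in c(0.1, 0.25, 0.5, 0.5857, 0.9)) {
    expect_equal(age_cdf(a), stats::integrate(age_pdf, 0, a)$value,
                 tolerance = 1e-9)
  }
  expect_equal(age_cdf(0.5), 2 * (1 - 2^(-0.5)), tolerance = 1e-12)
  expect_error(age_pdf(1), class = "replicycle_domain_error")
  expect_error(age_pdf(-0.1), class = "replicycle_domain_error")
  expect_error(age_cdf(1.01), class = "replicycle_domain_error")
})

test_that("marker-frequency relations reproduce measured cell-cycle ratios", {
  # wild-type rich-medium parameters: ori/ter ~3.54, ~7 origins per cell
  wt <- cell_cycle_params(tau = 24.02, c_period = 43.8, d_period = 23.7)
  expect_equal(ori_ter_ratio(wt), 3.54, tolerance = 0.005)
  expect_equal(origins_per_cell(wt), 7.0, tolerance = 0.01)
  expect_equal(c_period_from_ratio(3.54, 24.02), 43.8, tolerance = 0.003)
  # degenerate and exact-doubling cases
  expect_equal(c_period_from_ratio(2, 25), 25)
  expect_equal(c_period_from_ratio(1, 25), 0)
  expect_warning(p0 <- cell_cycle_params(25, 0, 0))
  expect_equal(ori_ter_ratio(p0), 1)
  expect_error(c_period_from_ratio(0.9, 25), class = "replicycle_measurement_error")
})

test_that("D period from origins per cell matches published reconstructions", {
  # wild type: 7.0 origins, tau 24.02, C 43.8 -> D ~23.6 (printed 23.7)
  expect_equal(d_period_from_origins(7.0, 24.02, 43.8), 23.7, tolerance = 0.1)
  # pgm small-size mutant row: 5.5 origins, tau 24.98, C 34.3 -> 27.2
  expect_equal(d_period_from_origins(5.5, 24.98, 34.3), 27.2, tolerance = 0.1)
  expect_warning(d <- d_period_from_origins(1.5, 20, 30), "negative")
  expect_lt(d, 0)
})

test_that("period inversions are exact inverses over random parameter sets", {
  for (p in random_params(1000, seed = 42)) {
    expect_equal(c_period_from_ratio(ori_ter_ratio(p), p$tau), p$c_period,
                 tolerance = 1e-12)
    expect_equal(
      suppressWarnings(d_period_from_origins(origins_per_cell(p), p$tau, p$c_period)),
      p$d_period, tolerance = 1e-12)
    expect_equal(tau_from_ratio(ori_ter_ratio(p), p$c_period), p$tau,
                 tolerance = 1e-9)
  }
})

test_that("model initiation age agrees with a lineage-simulation oracle", {
  wt <- cell_cycle_params(24.02, 43.8, 23.7)
  expect_equal(model_initiation_age(wt),
               lineage_initiation_age(24.02, 43.8, 23.7), tolerance = 1e-9)
  expect_equal(model_initiation_age(wt), 0.19, tolerance = 0.005)
  # exact-integer (C+D)/tau initiates at birth; half-integer at midcycle
  expect_equal(model_initiation_age(cell_cycle_params(20, 25, 15)), 0)
  expect_equal(model_initiation_age(cell_cycle_params(20, 20, 10)), 0.5)
  for (p in random_params(100, seed = 7)) {
    expect_equal(model_initiation_age(p),
                 lineage_initiation_age(p$tau, p$c_period, p$d_period),
                 tolerance = 1e-9)
  }
})

test_that("per-age replication state enumerates rounds correctly", {
  # single-round regime: two origins and one fork pair just after initiation
  p1 <- cell_cycle_params(tau = 60, c_period = 30, d_period = 15)
  ai <- model_initiation_age(p1)
  st <- state_at_age(ai + 1e-6, p1)
  expect_equal(st$origins, 2L)
  expect_equal(st$fork_pairs, 1L)
  # multifork wild type: 8 origins at midcycle
  wt <- cell_cycle_params(24.02, 43.8, 23.7)
  expect_equal(state_at_age(0.5, wt)$origins, 8L)
  # origins non-decreasing within a cycle and double exactly once
  for (p in random_params(50, seed = 11)) {
    ages <- seq(0, 0.999, length.out = 200)
    o <- state_at_age(ages, p)$origins
    expect_true(all(diff(o) >= 0))
    expect_equal(max(o), 2L * min(o))
  }
})

test_that("DNA content doubles across division and is continuous in age", {
  for (p in random_params(25, seed = 13)) {
    g0 <- state_at_age(1e-9, p)$genome_equivalents
    g1 <- state_at_age(1 - 1e-9, p)$genome_equivalents
    expect_equal(g1, 2 * g0, tolerance = 1e-5)
    g <- state_at_age(seq(0, 0.999, length.out = 500), p)$genome_equivalents
    expect_true(all(abs(diff(g)) < 0.05 * max(g)))
    expect_true(all(g >= 1))
  }
})

test_that("closed-form mean DNA content matches quadrature and Monte Carlo", {
  wt <- cell_cycle_params(24.02, 43.8, 23.7)
  quad <- stats::integrate(function(a) {
    age_pdf(a) * state_at_age(a, wt)$genome_equivalents
  }, 0, 1 - 1e-9, subdivisions = 500L, stop.on.error = FALSE)$value
  expect_equal(mean_genome_equivalents(wt), quad, tolerance = 1e-4)
  ages <- sample_ages(1e5, seed = 99)
  mc <- mean(state_at_age(ages, wt)$genome_equivalents)
  expect_equal(mc / mean_genome_equivalents(wt), 1, tolerance = 0.01)
  # instantaneous replication limits
  expect_equal(mean_genome_equivalents(cell_cycle_params(30, 30, 0)),
               1 / log(2), tolerance = 1e-12)
  expect_equal(suppressWarnings(
    mean_genome_equivalents(cell_cycle_params(30, 0, 0))), 1)
})

test_that("marker-structure frequency inverts to the period start age", {
  expect_equal(period_from_frequency(1), 0)
  expect_equal(period_from_frequency(0), 1)
  # ~80% ring frequency places ring assembly at age ~0.15
  expect_equal(period_from_frequency(0.8), 0.152, tolerance = 1e-3)
  # numeric inversion oracle: frequency = fraction of cells older than a1
  for (f in c(0.1, 0.4, 0.7, 0.95)) {
    a1 <- period_from_frequency(f)
    expect_equal(1 - age_cdf(a1), f, tolerance = 1e-9)
  }
  expect_error(period_from_frequency(1.2), class = "replicycle_domain_error")
})

test_that("age_distance is circular", {
  expect_equal(age_distance(0.98, 0.02), 0.04)
  expect_equal(age_distance(0.25, 0.25), 0)
  expect_equal(age_distance(0.93, 0.08), 0.15)
})
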