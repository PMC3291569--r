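test_that("noiseless spike histograms decompose exactly", {
  x <- 1:24
  cnt <- rep(0, 24)
  cnt[x == 5] <- 300
  cnt[x == 10] <- 700
  fit <- fit_ploidy_mixture(data.frame(fluorescence = x, count = cnt))
  expect_equal(nrow(fit$classes), 2)
  expect_equal(fit$classes$chromosomes[2], 2 * fit$classes$chromosomes[1])
  expect_equal(fit$classes$fraction, c(0.3, 0.7), tolerance = 1e-3)
  # component means sit on the spikes regardless of the class labels chosen
  expect_equal(fit$classes$mean_fluorescence, c(5, 10), tolerance = 0.05)

  single <- rep(0, 24)
  single[x == 8] <- 1000
  fit1 <- fit_ploidy_mixture(data.frame(fluorescence = x, count = single))
  expect_equal(nrow(fit1$classes), 1)
  expect_equal(fit1$classes$fraction, 1.0)
})

test_that("simulated run-out histograms recover the generating class fractions", {
  # target uninitiated fraction 0.22 -> a_i ~0.1697 -> C from r = 3 - a_i
  ai <- initiation_age_from_fraction(0.22)
  cfg <- sim_config(seed = 1, tau = 24, c_period = (3 - ai) * 24 - 23.7,
                    d_period = 23.7, n_cells = 20000, fluorescence_cv = 0.06)
  h <- simulate_runout_histogram(cfg)
  fit <- fit_ploidy_mixture(h, unit_fluorescence = 100)
  expect_equal(fit$classes$chromosomes, c(4L, 8L))
  expect_equal(fit$classes$fraction, c(0.22, 0.78), tolerance = 0.02)
  expect_lt(abs(fit$cv - 0.06), 0.005)
})

test_that("mixture fractions are stable under histogram bin refinement", {
  cfg <- sim_config(seed = 3, n_cells = 20000)
  f <- lapply(c(128, 512), function(nb) {
    fit <- fit_ploidy_mixture(simulate_runout_histogram(cfg, n_bins = nb),
                              unit_fluorescence = 100)
    fit$classes$fraction
  })
  expect_equal(sum(f[[1]]), 1, tolerance = 1e-9)
  expect_equal(sum(f[[2]]), 1, tolerance = 1e-9)
  expect_equal(f[[1]], f[[2]], tolerance = 0.01)
})

test_that("histogram invariants are enforced", {
  expect_error(fit_ploidy_mixture(data.frame(fluorescence = 1:5, count = rep(1, 5))),
               class = "replicycle_domain_error")
  expect_error(fit_ploidy_mixture(data.frame(fluorescence = c(1:7, 7), count = rep(1, 8))),
               class = "replicycle_domain_error")
  expect_error(fit_ploidy_mixture(data.frame(fluorescence = 1:10, count = rep(0, 10))),
               class = "replicycle_domain_error")
})

test_that("uninitiated fraction reads the lower class of a two-peak profile", {
  expect_equal(fraction_uninitiated(make_mixture(c(4, 8), c(0.22, 0.78))), 0.22)
  expect_equal(fraction_uninitiated(make_mixture(c(2, 4), c(0.5, 0.5))), 0.5)
  # three run-out peaks cannot be reduced to one uninitiated fraction
  expect_error(fraction_uninitiated(make_mixture(c(4, 8, 16), c(0.2, 0.5, 0.3))),
               class = "replicycle_profile_error")
  expect_error(fraction_uninitiated(make_mixture(8, 1)),
               class = "replicycle_profile_error")
  expect_error(fraction_uninitiated(make_mixture(c(4, 16), c(0.5, 0.5))),
               class = "replicycle_profile_error")
})

test_that("initiation age inverts the steady-state age CDF", {
  # round trip across the whole domain
  for (a in seq(0, 0.99, by = 0.03)) {
    expect_equal(initiation_age_from_fraction(age_cdf(a)), a, tolerance = 1e-9)
  }
  # uninitiated fractions consistent with measured initiation ages
  expect_equal(initiation_age_from_fraction(0.2223), 0.17, tolerance = 0.005)
  expect_equal(initiation_age_from_fraction(0.556), 0.47, tolerance = 0.005)
  expect_equal(initiation_age_from_fraction(0), 0)
  expect_error(initiation_age_from_fraction(1), class = "replicycle_domain_error")
})

test_that("mean chromosome number is the fraction-weighted class mean", {
  expect_equal(mean_chromosomes(make_mixture(8, 1)), 8)
  expect_equal(mean_chromosomes(make_mixture(c(8, 16), c(0.75, 0.25))), 10)
  expect_equal(mean_chromosomes(make_mixture(c(4, 8), c(0.5, 0.5))), 6)
})

test_that("initiation size maps age rank onto the size distribution", {
  sizes <- c(2, 5, 3, 9, 4)
  expect_equal(initiation_size(0, sizes), min(sizes))
  expect_equal(initiation_size(1 - 1e-12, sizes), max(sizes), tolerance = 1e-6)
  # exponential growth law: size 2^a on an age grid drawn from the age
  # distribution recovers 2^(a_i) at the initiation age
  p <- seq(0.0005, 0.9995, by = 0.001)
  ages <- -log2(1 - p / 2)  # inverse age CDF
  sizes <- 2^ages
  expect_equal(initiation_size(0.17, sizes), 2^0.17, tolerance = 0.002)
  # monotone in a_i
  s <- vapply(seq(0, 0.95, by = 0.05), initiation_size, numeric(1),
              sizes = c(1.1, 3.2, 2.5, 4.8, 2.2, 3.9))
  expect_true(all(diff(s) >= 0))
  expect_error(initiation_size(0.5, numeric(0)), class = "replicycle_domain_error")
})

test_that("initiation delay is the difference in absolute time from birth", {
  expect_equal(initiation_delay(0.3, 25, 0.3, 25), 0)
  # small-size mutants initiate ~8 and ~5.5 minutes later than wild type
  expect_equal(initiation_delay(0.47, 26.2, 0.17, 25.4), 7.996, tolerance = 1e-3)
  expect_equal(initiation_delay(0.38, 25.7, 0.17, 25.4), 5.448, tolerance = 1e-3)
})

test_that("tidy, glance and autoplot summarize a mixture fit", {
  cfg <- sim_config(seed = 5, n_cells = 8000)
  fit <- fit_ploidy_mixture(simulate_runout_histogram(cfg),
                            unit_fluorescence = 100)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("chromosomes", "fraction", "mean_fluorescence"))
  gl <- glance(fit)
  expect_equal(gl$n_classes, nrow(td))
  expect_equal(gl$mean_chromosomes, sum(td$chromosomes * td$fraction))
  expect_s3_class(autoplot(fit), "ggplot")
})
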