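# Independent oracles used across test files.

# Lineage-simulation oracle for the initiation age: a round of
# replication fires C+D minutes before the division it serves, so its
# position in the cycle is the backwards wrap of C+D around tau.
lineage_initiation_age <- function(tau, c_period, d_period) {
  ((-(c_period + d_period)) %% tau) / tau
}

# Random valid parameter sets away from degeneracy, for property loops.
random_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tau <- stats::runif(1, 15, 60)
      cell_cycle_params(
        tau = tau,
        c_period = stats::runif(1, 0.2, 3) * tau,
        d_period = stats::runif(1, 0.05, 1.5) * tau
      )
    })
  })
}

# Bare mixture object for unit tests of downstream accessors.
make_mixture <- function(chromosomes, fractions, unit = 100, cv = 0.05) {
  structure(
    list(
      classes = tibble::tibble(
        chromosomes = as.integer(chromosomes),
        fraction = fractions,
        mean_fluorescence = chromosomes * unit
      ),
      unit_fluorescence = unit,
      cv = cv,
      rss = 0,
      histogram = NULL
    ),
    class = "ploidy_mixture"
  )
}
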