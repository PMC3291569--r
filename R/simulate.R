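#' Configuration for the steady-state population simulator
#'
#' Fixes the ground truth from which all synthetic data are generated.
#' Defaults describe a fast-growing wild-type culture in rich medium with
#' overlapping replication rounds: tau = 24 min, C = 43.8 min,
#' D = 23.7 min (so (C+D)/tau ~ 2.81 and run-out peaks at 4 and 8
#' chromosomes), 6% flow-cytometer measurement CV, mean birth area
#' 4 square micrometers with 15% log-normal cell-to-cell variation,
#' 0.05-cycle Cq noise, and a DnaA concentration of 250 molecules per
#' square micrometer of cross-section (about 1400 molecules in an
#' average cell). The seed is explicit: no generator touches the global
#' RNG state implicitly.
#'
#' @param seed Integer seed; required, drives every draw.
#' @param tau,c_period,d_period Cell-cycle periods in minutes.
#' @param n_cells Number of cells to simulate.
#' @param fluorescence_cv Multiplicative Gaussian measurement noise of
#'   the flow cytometer (coefficient of variation).
#' @param size_birth_mean Mean cross-sectional area at birth,
#'   micrometers squared.
#' @param size_birth_cv Log-normal coefficient of variation of birth size.
#' @param cq_sd Per-well qPCR quantification-cycle noise SD, cycles.
#' @param dnaa_concentration DnaA molecules per square micrometer of
#'   cross-sectional area (held constant across cell sizes).
#' @return A `sim_config` object (contains a [cell_cycle_params()] as
#'   `$params`).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$params
#' @export
sim_config <- function(seed,
                       tau = 24, c_period = 43.8, d_period = 23.7,
                       n_cells = 20000,
                       fluorescence_cv = 0.06,
                       size_birth_mean = 4.0, size_birth_cv = 0.15,
                       cq_sd = 0.05,
                       dnaa_concentration = 250) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be supplied explicitly as a single integer.",
                 class = "replicycle_domain_error")
  }
  if (n_cells < 1) {
    rlang::abort("`n_cells` must be >= 1.", class = "replicycle_domain_error")
  }
  if (fluorescence_cv < 0 || size_birth_cv < 0 || cq_sd < 0) {
    rlang::abort("Noise levels (`fluorescence_cv`, `size_birth_cv`, `cq_sd`) must be >= 0.",
                 class = "replicycle_domain_error")
  }
  if (size_birth_mean <= 0 || dnaa_concentration <= 0) {
    rlang::abort("`size_birth_mean` and `dnaa_concentration` must be positive.",
                 class = "replicycle_domain_error")
  }
  structure(
    list(
      params = cell_cycle_params(tau, c_period, d_period),
      n_cells = as.integer(n_cells),
      fluorescence_cv = fluorescence_cv,
      size_birth_mean = size_birth_mean,
      size_birth_cv = size_birth_cv,
      cq_sd = cq_sd,
      dnaa_concentration = dnaa_concentration,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

assert_config <- function(config) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be a `sim_config` object (see `sim_config()`).",
                 class = "replicycle_domain_error")
  }
  invisible(config)
}

#' Sample cell ages from the steady-state age distribution
#'
#' Inverse-CDF sampling: `a = -log2(1 - u/2)` with `u` uniform on
#' `[0, 1)`. Bit-reproducible for a given seed.
#'
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of ages in `[0, 1)`.
#' @export
sample_ages <- function(n, seed) {
  if (!is.numeric(n) || n < 1) {
    rlang::abort("`n` must be >= 1.", class = "replicycle_domain_error")
  }
  withr::with_seed(as.integer(seed), {
    u <- stats::runif(n)
    -log2(1 - u / 2)
  })
}

#' Simulate a steady-state exponentially growing population
#'
#' Draws cell ages from the steady-state age distribution, gives each
#' cell a log-normally distributed birth size grown exponentially within
#' the cycle (`size = birth_size * 2^age`), computes its replication
#' state (origins, fork pairs, genome equivalents) from the
#' Cooper-Helmstetter forward model, and assigns DnaA in proportion to
#' size at fixed concentration.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per cell: `age`, `size`, `origins`,
#'   `fork_pairs`, `genome_equivalents`, `dnaa_molecules`.
#' @examples
#' pop <- simulate_population(sim_config(seed = 1, n_cells = 1000))
#' mean(pop$origins)
#' @export
simulate_population <- function(config) {
  assert_config(config)
  withr::with_seed(config$seed, {
    u <- stats::runif(config$n_cells)
    age <- -log2(1 - u / 2)
    if (config$size_birth_cv > 0) {
      sdlog <- sqrt(log(1 + config$size_birth_cv^2))
      birth <- stats::rlnorm(config$n_cells,
                             meanlog = log(config$size_birth_mean) - sdlog^2 / 2,
                             sdlog = sdlog)
    } else {
      birth <- rep(config$size_birth_mean, config$n_cells)
    }
    size <- birth * 2^age
    state <- state_at_age(age, config$params)
    tibble::tibble(
      age = age,
      size = size,
      origins = state$origins,
      fork_pairs = state$fork_pairs,
      genome_equivalents = state$genome_equivalents,
      dnaa_molecules = config$dnaa_concentration * size
    )
  })
}

#' Simulate a replication run-out DNA-content histogram
#'
#' After a complete run-out each cell's DNA equals its origin count in
#' genome equivalents (no new initiations, all forks finish). Measured
#' fluorescence is `unit * origins * (1 + e)` with
#' `e ~ Normal(0, fluorescence_cv)`, binned on `n_bins` equal-width bins
#' over the observed range.
#'
#' @param config A [sim_config()].
#' @param n_bins Number of histogram bins.
#' @param unit_fluorescence Fluorescence per chromosome equivalent
#'   (arbitrary instrument scale).
#' @return A tibble with columns `fluorescence` (bin centers) and `count`.
#' @examples
#' h <- simulate_runout_histogram(sim_config(seed = 1, n_cells = 5000))
#' @export
simulate_runout_histogram <- function(config, n_bins = 256,
                                      unit_fluorescence = 100) {
  assert_config(config)
  if (n_bins < 8) {
    rlang::abort("`n_bins` must be >= 8.", class = "replicycle_domain_error")
  }
  withr::with_seed(config$seed + 1L, {
    age <- sample_ages_local(config$n_cells)
    state <- state_at_age(age, config$params)
    eps <- if (config$fluorescence_cv > 0) {
      stats::rnorm(config$n_cells, 0, config$fluorescence_cv)
    } else {
      rep(0, config$n_cells)
    }
    fluor <- unit_fluorescence * state$origins * (1 + eps)
    breaks <- seq(min(fluor), max(fluor), length.out = n_bins + 1)
    if (breaks[1] == breaks[n_bins + 1]) {
      breaks <- seq(breaks[1] - 1, breaks[1] + 1, length.out = n_bins + 1)
    }
    counts <- graphics::hist(fluor, breaks = breaks, plot = FALSE)$counts
    tibble::tibble(
      fluorescence = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
      count = as.numeric(counts)
    )
  })
}

# Inverse-CDF age draws using the ambient RNG stream (callers manage seeding).
sample_ages_local <- function(n) {
  u <- stats::runif(n)
  -log2(1 - u / 2)
}

#' Simulate a tidy qPCR quantification table
#'
#' Generates Cq values for ori and ter amplicons in a growing sample and
#' in a 1:1 calibrator, consistent with the declared amplification
#' efficiencies and the true marker-frequency ratio
#' `ori/ter = 2^(C/tau)` of the configured cell cycle, plus
#' `Normal(0, cq_sd)` noise per well. Layout: `n_biological` replicate
#' cultures x `n_technical` wells per (target, role).
#'
#' @param config A [sim_config()].
#' @param n_biological,n_technical Replicate structure.
#' @param eff_ori,eff_ter Amplification efficiencies in `(1, 2]`.
#' @param base_cq Quantification cycle of the ter amplicon (and of the
#'   calibrator wells) before noise.
#' @param sample_id Label for the sample rows.
#' @return A tibble with columns `sample_id`, `target`, `role`,
#'   `replicate`, `cq`, `efficiency`, ready for [pfaffl_ratios()].
#' @examples
#' q <- simulate_qpcr(sim_config(seed = 1))
#' pfaffl_ratios(q)
#' @export
simulate_qpcr <- function(config, n_biological = 3, n_technical = 3,
                          eff_ori = 2, eff_ter = 2, base_cq = 15,
                          sample_id = "sample") {
  assert_config(config)
  rho <- ori_ter_ratio(config$params)
  n_wells <- n_biological * n_technical
  layout <- tidyr::expand_grid(
    role = c("sample", "calibrator"),
    target = c("ori", "ter"),
    replicate = seq_len(n_wells)
  )
  eff <- ifelse(layout$target == "ori", eff_ori, eff_ter)
  # template quantity ratio rho shifts the ori Cq earlier by log(rho)/log(E)
  cq0 <- ifelse(layout$role == "sample" & layout$target == "ori",
                base_cq - log(rho) / log(eff_ori),
                base_cq)
  withr::with_seed(config$seed + 2L, {
    noise <- if (config$cq_sd > 0) {
      stats::rnorm(nrow(layout), 0, config$cq_sd)
    } else {
      rep(0, nrow(layout))
    }
    tibble::tibble(
      sample_id = ifelse(layout$role == "sample", sample_id, "calibrator"),
      target = layout$target,
      role = layout$role,
      replicate = layout$replicate,
      cq = cq0 + noise,
      efficiency = eff
    )
  })
}

#' Simulate immunoblot and hemocytometer tables for a strain pair
#'
#' Derives blot intensities and cell counts from two simulated
#' populations. Lane loading is modeled as exact, with an ideal loading
#' control (constant intensity per lane): on the optical-density basis
#' the DnaA band reports concentration (total DnaA per biomass), on the
#' cell-count basis it reports mean DnaA per cell. Hemocytometer counts
#' at matched OD scale inversely with mean cell size.
#'
#' @param config_test,config_reference [sim_config()]s for the two strains.
#' @param reference_cells_per_ml Hemocytometer count of the reference
#'   culture at `od`.
#' @param od Optical density at which both cultures are sampled.
#' @return A list with `blots` (tibble: strain, basis, band, control) and
#'   `counts` (tibble: strain, cells_per_ml, od).
#' @export
simulate_abundance_tables <- function(config_test, config_reference,
                                      reference_cells_per_ml = 6.4e8,
                                      od = 0.3) {
  assert_config(config_test)
  assert_config(config_reference)
  pop_t <- simulate_population(config_test)
  pop_r <- simulate_population(config_reference)
  conc_t <- mean(pop_t$dnaa_molecules) / mean(pop_t$size)
  conc_r <- mean(pop_r$dnaa_molecules) / mean(pop_r$size)
  blots <- tibble::tibble(
    strain = rep(c("test", "reference"), each = 2),
    basis = rep(c("optical_density", "cell_count"), 2),
    band = c(conc_t, mean(pop_t$dnaa_molecules),
             conc_r, mean(pop_r$dnaa_molecules)),
    control = 100
  )
  counts <- tibble::tibble(
    strain = c("reference", "test"),
    cells_per_ml = reference_cells_per_ml *
      c(1, mean(pop_r$size) / mean(pop_t$size)),
    od = od
  )
  list(blots = blots, counts = counts)
}
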