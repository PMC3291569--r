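#' Cell-cycle parameter set
#'
#' Bundles the three durations that drive all Cooper-Helmstetter
#' steady-state mathematics: the mass doubling time tau, the C period
#' (time to replicate the chromosome once) and the D period (time between
#' replication termination and cell division). All in minutes.
#'
#' When `C + D > tau` replication rounds overlap (multifork replication)
#' and cells carry 2^n origin classes; the closed-form relations in this
#' module (see [ori_ter_ratio()], [origins_per_cell()],
#' [model_initiation_age()]) all follow from steady-state exponential
#' growth with synchronous initiation at every origin.
#'
#' @param tau Mass doubling time in minutes. Must be positive.
#' @param c_period Replication elongation time C in minutes. Must be
#'   non-negative; `C = 0` (instantaneous replication) is permitted for
#'   degenerate test scenarios and raises a warning.
#' @param d_period Termination-to-division time D in minutes, >= 0.
#'
#' @return An object of class `cell_cycle_params`.
#' @examples
#' wt <- cell_cycle_params(tau = 24, c_period = 43.8, d_period = 23.7)
#' origins_per_cell(wt)
#' @export
cell_cycle_params <- function(tau, c_period, d_period) {
  for (v in list(tau = tau, c_period = c_period, d_period = d_period)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort("`tau`, `c_period` and `d_period` must be finite numeric scalars.",
                   class = "replicycle_domain_error")
    }
  }
  if (tau <= 0) {
    rlang::abort("`tau` must be positive.", class = "replicycle_domain_error")
  }
  if (c_period < 0 || d_period < 0) {
    rlang::abort("`c_period` and `d_period` must be non-negative.",
                 class = "replicycle_domain_error")
  }
  if (c_period == 0) {
    rlang::warn("`c_period` = 0 is degenerate (instantaneous replication); intended for testing only.")
  }
  structure(
    list(tau = tau, c_period = c_period, d_period = d_period),
    class = "cell_cycle_params"
  )
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  cat("<cell_cycle_params>\n")
  cat(sprintf("  tau = %.2f min, C = %.2f min, D = %.2f min\n",
              x$tau, x$c_period, x$d_period))
  cat(sprintf("  (C+D)/tau = %.3f; origins/cell = %.2f; ori/ter = %.2f\n",
              (x$c_period + x$d_period) / x$tau,
              origins_per_cell(x), ori_ter_ratio(x)))
  invisible(x)
}

assert_params <- function(params) {
  if (!inherits(params, "cell_cycle_params")) {
    rlang::abort("`params` must be a `cell_cycle_params` object (see `cell_cycle_params()`).",
                 class = "replicycle_domain_error")
  }
  invisible(params)
}

assert_age <- function(age, upper_closed = FALSE, arg = "age") {
  if (!is.numeric(age) || anyNA(age) || any(!is.finite(age))) {
    rlang::abort(sprintf("`%s` must be finite numeric.", arg),
                 class = "replicycle_domain_error")
  }
  hi_ok <- if (upper_closed) age <= 1 else age < 1
  if (any(age < 0) || any(!hi_ok)) {
    rlang::abort(
      sprintf("`%s` must lie in [0, 1%s (0 = birth, 1 = division).",
              arg, if (upper_closed) "]" else ")"),
      class = "replicycle_domain_error"
    )
  }
  invisible(age)
}

#' Steady-state cell-age distribution
#'
#' In a steady-state exponentially growing population with symmetric
#' division, the density of cell ages a (0 = birth, 1 = division) is
#' `phi(a) = 2 ln2 * 2^(-a)`: newborn cells are twice as frequent as
#' dividing cells. `age_cdf()` is its exact integral,
#' `F(a) = 2 (1 - 2^(-a))`.
#'
#' @param age Cell age(s), dimensionless in `[0, 1)` for `age_pdf()` and
#'   `[0, 1]` for `age_cdf()`.
#' @return Density values (`age_pdf`) or cumulative fractions (`age_cdf`).
#' @examples
#' age_pdf(0)      # 2 ln 2
#' age_cdf(0.5)
#' @export
age_pdf <- function(age) {
  assert_age(age)
  2 * log(2) * 2^(-age)
}

#' @rdname age_pdf
#' @export
age_cdf <- function(age) {
  assert_age(age, upper_closed = TRUE)
  2 * (1 - 2^(-age))
}

#' Marker-frequency relations between cell-cycle periods and copy-number ratios
#'
#' At steady state the relative abundance of origin- vs terminus-proximal
#' DNA in a replicating population is `ori/ter = 2^(C/tau)`, and the mean
#' number of replication origins per cell is `2^((C+D)/tau)`.
#' `c_period_from_ratio()`, `tau_from_ratio()` and `d_period_from_origins()`
#' are the exact inverses used to turn measured ratios into periods.
#'
#' @param params A [cell_cycle_params()] object.
#' @param ratio Measured ori:ter marker-frequency ratio, >= 1.
#' @param tau Mass doubling time in minutes.
#' @param c_period C period in minutes.
#' @param origins Mean origins per cell, >= 1.
#' @return A dimensionless ratio, or a period in minutes.
#' @examples
#' p <- cell_cycle_params(24.02, 43.8, 23.7)
#' ori_ter_ratio(p)                      # ~3.54
#' c_period_from_ratio(3.54, 24.02)      # ~43.8 min
#' d_period_from_origins(7.0, 24.02, 43.8)
#' @export
ori_ter_ratio <- function(params) {
  assert_params(params)
  2^(params$c_period / params$tau)
}

#' @rdname ori_ter_ratio
#' @export
c_period_from_ratio <- function(ratio, tau) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio < 1)) {
    rlang::abort("ori:ter `ratio` must be >= 1: at steady state origins can only be over-represented.",
                 class = "replicycle_measurement_error")
  }
  if (!is.numeric(tau) || any(tau <= 0)) {
    rlang::abort("`tau` must be positive.", class = "replicycle_domain_error")
  }
  tau * log2(ratio)
}

#' @rdname ori_ter_ratio
#' @export
tau_from_ratio <- function(ratio, c_period) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 1)) {
    rlang::abort("ori:ter `ratio` must be > 1 to solve for tau.",
                 class = "replicycle_measurement_error")
  }
  c_period / log2(ratio)
}

#' @rdname ori_ter_ratio
#' @export
origins_per_cell <- function(params) {
  assert_params(params)
  2^((params$c_period + params$d_period) / params$tau)
}

#' @rdname ori_ter_ratio
#' @export
d_period_from_origins <- function(origins, tau, c_period) {
  if (!is.numeric(origins) || any(!is.finite(origins)) || any(origins < 1)) {
    rlang::abort("`origins` per cell must be >= 1.",
                 class = "replicycle_measurement_error")
  }
  d <- tau * log2(origins) - c_period
  if (any(d < 0)) {
    rlang::warn("Inferred D period is negative; the ori:ter ratio and origins-per-cell measurements are mutually inconsistent. Returning the negative value unclipped.")
  }
  d
}

#' Model-predicted initiation age
#'
#' Under the Cooper-Helmstetter model a round of replication initiates
#' `C + D` minutes before the division it serves. With `r = (C+D)/tau`,
#' initiation for the division `ceiling(r)` generations ahead falls at age
#' `a_i = ceiling(r) - r` in the current cycle; when `r` is an exact
#' integer initiation coincides with birth (`a_i = 0`).
#'
#' Because `a_i` lives on the unit circle (an initiation just before
#' division and one just after birth are physiologically adjacent),
#' compare predicted and measured ages with [age_distance()].
#'
#' @param params A [cell_cycle_params()] object.
#' @return Initiation age in `[0, 1)`.
#' @examples
#' model_initiation_age(cell_cycle_params(24.02, 43.8, 23.7))  # ~0.19
#' @export
model_initiation_age <- function(params) {
  assert_params(params)
  r <- (params$c_period + params$d_period) / params$tau
  ai <- ceiling(r) - r
  if (ai >= 1) ai <- 0  # r == 0 edge
  ai
}

#' Circular distance between cell ages
#'
#' Ages are positions on the unit circle: 0.98 and 0.02 are 0.04 apart,
#' not 0.96. Used to compare model-predicted and measured initiation ages
#' when `(C+D)/tau` sits near an integer and initiation wraps across
#' division.
#'
#' @param a,b Ages in `[0, 1]`.
#' @return `min(|a - b|, 1 - |a - b|)`, elementwise.
#' @export
age_distance <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 1 - d)
}

#' Per-age replication state of a cell
#'
#' Enumerates the replication rounds active in a cell of given age and
#' returns its origin count, active fork-pair count, and DNA content in
#' chromosome (genome) equivalents. Initiation is assumed synchronous
#' across all origins, division symmetric.
#'
#' A round serving the division `k` generations ahead initiates `C + D`
#' minutes before that division; its replication progress at the current
#' age is `f_k = ((C+D) - (1 - age + k) tau) / C`, clamped to `[0, 1]`.
#' The round replicates `2^k` chromosome units within the current cell, so
#' `genome_equivalents = 1 + sum_k 2^k * clamp(f_k)` - continuous and
#' piecewise-linear in age, doubling exactly across division.
#'
#' @param age Cell age(s) in `[0, 1)`; vectorized.
#' @param params A [cell_cycle_params()] object.
#' @return A tibble with columns `age`, `origins`, `fork_pairs`,
#'   `genome_equivalents`.
#' @examples
#' state_at_age(c(0, 0.25, 0.5, 0.75), cell_cycle_params(24.02, 43.8, 23.7))
#' @export
state_at_age <- function(age, params) {
  assert_age(age)
  assert_params(params)
  tau <- params$tau; C <- params$c_period; D <- params$d_period
  r <- (C + D) / tau
  n <- ceiling(r)
  ai <- model_initiation_age(params)
  origins <- ifelse(age < ai, 2^(max(n - 1, 0)), 2^n)
  geq <- rep(1, length(age))
  fp <- rep(0, length(age))
  if (n >= 1) {
    for (k in 0:(n - 1)) {
      if (C > 0) {
        f <- ((C + D) - (1 - age + k) * tau) / C
      } else {
        f <- ifelse((C + D) - (1 - age + k) * tau > 0, 1, -1)
      }
      geq <- geq + 2^k * pmin(pmax(f, 0), 1)
      fp <- fp + 2^k * (f > 0 & f < 1)
    }
  }
  tibble::tibble(
    age = age,
    origins = as.integer(round(origins)),
    fork_pairs = as.integer(fp),
    genome_equivalents = geq
  )
}

#' Population-mean DNA content
#'
#' Closed-form mean genome equivalents per cell over the steady-state age
#' distribution: `G = (tau / (C ln 2)) * (2^((C+D)/tau) - 2^(D/tau))`,
#' with the `C -> 0` limit `2^(D/tau)`.
#'
#' @param params A [cell_cycle_params()] object.
#' @return Mean chromosome equivalents of DNA per cell.
#' @export
mean_genome_equivalents <- function(params) {
  assert_params(params)
  tau <- params$tau; C <- params$c_period; D <- params$d_period
  if (C == 0) return(2^(D / tau))
  (tau / (C * log(2))) * (2^((C + D) / tau) - 2^(D / tau))
}

#' Cell-cycle period from the frequency of a marker structure
#'
#' A structure present from age `a1` until division (e.g. the FtsZ
#' cytokinetic ring, defining the Z period) is seen in a fraction
#' `2^(1 - a1) - 1` of a steady-state population. This inverts that
#' relation: `a1 = 1 - log2(1 + frequency)`.
#'
#' @param frequency Fraction of cells displaying the structure, in `[0, 1]`.
#' @return The age at which the period begins, in `[0, 1]`.
#' @examples
#' period_from_frequency(0.8)  # ~0.152: rings assemble early in the cycle
#' @export
period_from_frequency <- function(frequency) {
  if (!is.numeric(frequency) || any(!is.finite(frequency)) ||
      any(frequency < 0) || any(frequency > 1)) {
    rlang::abort("`frequency` must lie in [0, 1].", class = "replicycle_domain_error")
  }
  1 - log2(1 + frequency)
}

#' Plot the steady-state age distribution
#'
#' @param params A [cell_cycle_params()] object; its model-predicted
#'   initiation age is marked with a dashed line.
#' @return A ggplot object.
#' @export
plot_age_distribution <- function(params) {
  assert_params(params)
  grid <- tibble::tibble(age = seq(0, 0.999, length.out = 400))
  grid$density <- age_pdf(grid$age)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$age, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = model_initiation_age(params), linetype = "dashed") +
    ggplot2::labs(
      x = "cell age (0 = birth, 1 = division)",
      y = "population density",
      title = "Steady-state age distribution",
      subtitle = sprintf("dashed: model initiation age a_i = %.2f",
                         model_initiation_age(params))
    )
}
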