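#' Decompose a replication run-out DNA histogram into integer-chromosome classes
#'
#' After a replication run-out (initiation and division blocked while
#' ongoing forks finish), every cell holds a number of fully replicated
#' chromosomes equal to its origin count at drug addition - a power of 2
#' under synchronous initiation. The DNA-content histogram is therefore a
#' mixture of Gaussian peaks whose means are pinned to integer multiples
#' `n * u` of one shared unit fluorescence `u` (one chromosome
#' equivalent), with a shared coefficient of variation.
#'
#' The fit minimizes the sum of squared differences between the
#' bin-integrated mixture density and the count-normalized histogram
#' (integrating each component over the bin keeps the mass of classes
#' narrower than one bin). Weights are solved by
#' non-negative least squares at each candidate `(u, cv)` (variable
#' projection); `(u, cv)` are refined by Nelder-Mead from starts anchored
#' at the tallest histogram peak assigned to each allowed chromosome
#' number. Classes ending below 1% of fitted mass are pruned and the
#' remaining fractions renormalized, so shoulder artifacts do not count
#' as peaks.
#'
#' A histogram alone fixes peak positions only up to a common scale:
#' peaks at u and 2u fit equally well as classes (2,4) at unit u or
#' (4,8) at unit u/2. When `unit_fluorescence` is not supplied, the
#' first-found assignment is kept deterministically; class fractions,
#' the uninitiated fraction and the initiation age are invariant to this
#' choice, but absolute chromosome numbers (hence origins per cell and
#' the D period) are not. Supply `unit_fluorescence` from an instrument
#' calibration (e.g. reference standards of known genome content) when
#' absolute ploidy matters.
#'
#' @param hist A data frame with numeric columns `fluorescence`
#'   (ascending bin centers, arbitrary units) and `count` (non-negative).
#'   At least 8 bins with positive total count.
#' @param allowed_chromosomes Candidate chromosome numbers for the
#'   classes; defaults to powers of two `c(2, 4, 8, 16)`.
#' @param unit_fluorescence Optional known fluorescence per chromosome
#'   equivalent (from instrument calibration). When given, only the CV
#'   and class weights are fitted.
#' @return A `ploidy_mixture` object with elements `classes` (tibble:
#'   `chromosomes`, `fraction`, `mean_fluorescence`), `unit_fluorescence`,
#'   `cv`, `rss` and the input histogram. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @examples
#' cfg <- sim_config(seed = 1, n_cells = 5000)
#' h <- simulate_runout_histogram(cfg)
#' fit <- fit_ploidy_mixture(h)
#' tidy(fit)
#' @export
fit_ploidy_mixture <- function(hist, allowed_chromosomes = c(2, 4, 8, 16),
                               unit_fluorescence = NULL) {
  h <- as_runout_histogram(hist)
  x <- h$fluorescence
  cnt <- h$count
  if (length(allowed_chromosomes) == 0 ||
      any(allowed_chromosomes < 1) ||
      any(allowed_chromosomes != round(allowed_chromosomes))) {
    rlang::abort("`allowed_chromosomes` must be positive integers.",
                 class = "replicycle_domain_error")
  }
  chroms <- sort(unique(as.integer(allowed_chromosomes)))
  bw <- mean(diff(x))
  dens <- cnt / (sum(cnt) * bw)

  # anchor candidate unit fluorescences at the tallest (smoothed) peak
  sm <- dens
  if (length(dens) >= 7) {
    k <- stats::filter(dens, rep(1 / 5, 5), sides = 2)
    sm <- ifelse(is.na(k), dens, as.numeric(k))
  }
  p1 <- x[which.max(sm)]
  if (p1 <= 0) p1 <- x[which.max(dens)]

  # model the expected density in each bin as the bin-integrated component
  # probability / bin width, so classes narrower than one bin keep their mass
  lo <- x - bw / 2
  hi <- x + bw / 2
  design <- function(u, cv) {
    vapply(chroms, function(n) {
      s <- cv * n * u
      (stats::pnorm(hi, n * u, s) - stats::pnorm(lo, n * u, s)) / bw
    }, numeric(length(x)))
  }
  objective <- function(par) {
    u <- exp(par[1]); cv <- exp(par[2])
    if (!is.finite(u) || !is.finite(cv) || cv < 5e-4 || cv > 0.6) return(1e12)
    A <- design(u, cv)
    if (any(!is.finite(A))) return(1e12)
    w <- tryCatch(pracma::lsqnonneg(A, dens)$x, error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w))) return(1e12)
    sum((A %*% w - dens)^2)
  }

  best <- NULL
  if (!is.null(unit_fluorescence)) {
    if (!is.numeric(unit_fluorescence) || unit_fluorescence <= 0) {
      rlang::abort("`unit_fluorescence` must be a positive scale.",
                   class = "replicycle_domain_error")
    }
    lu <- log(unit_fluorescence)
    opt <- stats::optimize(function(lcv) objective(c(lu, lcv)),
                           interval = log(c(5e-4, 0.6)), tol = 1e-10)
    best <- list(par = c(lu, opt$minimum), value = opt$objective)
  } else {
    for (n0 in chroms) {
      u0 <- p1 / n0
      if (n0 * u0 > max(x) * 1.5 || max(chroms) * u0 < min(x) / 4) next
      for (cv0 in c(0.03, 0.06, 0.12)) {
        opt <- stats::optim(c(log(u0), log(cv0)), objective,
                            method = "Nelder-Mead",
                            control = list(maxit = 400, reltol = 1e-10))
        if (is.null(best) || opt$value < best$value * (1 - 1e-9)) {
          best <- opt
        }
      }
    }
  }
  if (is.null(best) || best$value >= 1e12) {
    rlang::abort("Ploidy mixture fit failed: no candidate unit fluorescence produced a finite fit.",
                 class = "replicycle_estimation_error")
  }

  u <- exp(best$par[1]); cv <- exp(best$par[2])
  A <- design(u, cv)
  w <- pracma::lsqnonneg(A, dens)$x
  if (sum(w) <= 0) {
    rlang::abort("Ploidy mixture fit failed: all class weights are zero.",
                 class = "replicycle_estimation_error")
  }
  frac <- w / sum(w)
  keep <- frac >= 0.01
  if (!any(keep)) {
    rlang::abort("Ploidy mixture fit failed: no class retained >= 1% of fitted mass.",
                 class = "replicycle_estimation_error")
  }
  frac <- frac[keep] / sum(frac[keep])
  classes <- tibble::tibble(
    chromosomes = chroms[keep],
    fraction = frac,
    mean_fluorescence = chroms[keep] * u
  )
  structure(
    list(
      classes = classes,
      unit_fluorescence = u,
      cv = cv,
      rss = best$value,
      histogram = h
    ),
    class = "ploidy_mixture"
  )
}

# Coerce a two-column histogram data frame and enforce its invariants.
as_runout_histogram <- function(hist) {
  if (!is.data.frame(hist)) {
    rlang::abort("`hist` must be a data frame (fluorescence bin centers + counts).",
                 class = "replicycle_domain_error")
  }
  if (all(c("fluorescence", "count") %in% names(hist))) {
    h <- tibble::tibble(fluorescence = as.numeric(hist$fluorescence),
                        count = as.numeric(hist$count))
  } else {
    num <- which(vapply(hist, is.numeric, logical(1)))
    if (length(num) < 2) {
      rlang::abort("`hist` needs numeric columns `fluorescence` and `count`.",
                   class = "replicycle_parse_error")
    }
    h <- tibble::tibble(fluorescence = as.numeric(hist[[num[1]]]),
                        count = as.numeric(hist[[num[2]]]))
  }
  if (nrow(h) < 8) {
    rlang::abort("Run-out histogram needs at least 8 bins.",
                 class = "replicycle_domain_error")
  }
  if (any(!is.finite(h$fluorescence)) || any(diff(h$fluorescence) <= 0)) {
    rlang::abort("Histogram bin centers must be finite and strictly increasing.",
                 class = "replicycle_domain_error")
  }
  if (any(!is.finite(h$count)) || any(h$count < 0) || sum(h$count) <= 0) {
    rlang::abort("Histogram counts must be non-negative with positive total.",
                 class = "replicycle_domain_error")
  }
  h
}

#' @export
print.ploidy_mixture <- function(x, ...) {
  cat("<ploidy_mixture>\n")
  cat(sprintf("  unit fluorescence = %.4g, cv = %.3f, rss = %.3g\n",
              x$unit_fluorescence, x$cv, x$rss))
  print(x$classes)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted ploidy mixture
#'
#' `tidy()` returns one row per chromosome class; `glance()` returns the
#' one-row fit summary.
#'
#' @param x A `ploidy_mixture` from [fit_ploidy_mixture()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ploidy_mixture <- function(x, ...) {
  x$classes
}

#' @rdname tidy.ploidy_mixture
#' @export
glance.ploidy_mixture <- function(x, ...) {
  tibble::tibble(
    unit_fluorescence = x$unit_fluorescence,
    cv = x$cv,
    n_classes = nrow(x$classes),
    mean_chromosomes = mean_chromosomes(x),
    rss = x$rss
  )
}

#' @rdname tidy.ploidy_mixture
#' @param object A `ploidy_mixture`.
#' @export
autoplot.ploidy_mixture <- function(object, ...) {
  h <- object$histogram
  bw <- mean(diff(h$fluorescence))
  dens <- h$count / (sum(h$count) * bw)
  obs <- tibble::tibble(fluorescence = h$fluorescence, density = dens)
  grid <- seq(min(h$fluorescence), max(h$fluorescence), length.out = 400)
  comp <- purrr::pmap_dfr(
    object$classes,
    function(chromosomes, fraction, mean_fluorescence) {
      tibble::tibble(
        fluorescence = grid,
        density = fraction * stats::dnorm(grid, mean_fluorescence,
                                          object$cv * mean_fluorescence),
        class = factor(chromosomes)
      )
    }
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$fluorescence, y = .data$density)) +
    ggplot2::geom_col(width = bw, fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(colour = .data$class), linewidth = 0.8) +
    ggplot2::labs(x = "DNA content (fluorescence, a.u.)", y = "density",
                  colour = "chromosomes",
                  title = "Replication run-out histogram decomposition")
}

#' Fraction of uninitiated cells in a run-out mixture
#'
#' In a two-peak run-out profile the lower-ploidy peak holds the cells
#' that had not yet initiated replication at drug addition; its fraction
#' is the uninitiated fraction F used to place the initiation age in the
#' cycle. Profiles with more than two classes (three run-out peaks) are
#' rejected: F is not defined when initiation spans more than one
#' doubling class.
#'
#' @param mix A `ploidy_mixture` with exactly two classes whose
#'   chromosome numbers differ by a factor of 2.
#' @return The fraction F in `[0, 1]`.
#' @export
fraction_uninitiated <- function(mix) {
  if (!inherits(mix, "ploidy_mixture")) {
    rlang::abort("`mix` must be a `ploidy_mixture`.", class = "replicycle_domain_error")
  }
  cl <- mix$classes
  if (nrow(cl) != 2) {
    rlang::abort(
      sprintf("Uninitiated fraction requires a two-peak profile; this mixture has %d class(es). Profiles with more than two peaks cannot be reduced to a single uninitiated fraction.",
              nrow(cl)),
      class = "replicycle_profile_error"
    )
  }
  if (cl$chromosomes[2] != 2 * cl$chromosomes[1]) {
    rlang::abort("The two classes must differ by one doubling (chromosome numbers in ratio 2).",
                 class = "replicycle_profile_error")
  }
  cl$fraction[1]
}

#' Initiation age from the uninitiated fraction
#'
#' Cells younger than the initiation age at drug addition end the run-out
#' in the lower-ploidy peak, so F equals the steady-state age CDF at the
#' initiation age: `F = 2 (1 - 2^(-a_i))`. Inverting,
#' `a_i = -log2(1 - F/2)`.
#'
#' @param F Uninitiated fraction in `[0, 1)`.
#' @return Initiation age in `[0, 1)`.
#' @examples
#' initiation_age_from_fraction(0.2223)  # ~0.17
#' @export
initiation_age_from_fraction <- function(F) {
  if (!is.numeric(F) || any(!is.finite(F)) || any(F < 0) || any(F >= 1)) {
    rlang::abort("`F` must lie in [0, 1).", class = "replicycle_domain_error")
  }
  -log2(1 - F / 2)
}

#' Mean chromosome number of a run-out mixture
#'
#' The fraction-weighted mean of the integer chromosome classes; after a
#' complete run-out this estimates the mean origins per cell of the
#' growing population.
#'
#' @param mix A `ploidy_mixture`.
#' @return Mean chromosome equivalents.
#' @export
mean_chromosomes <- function(mix) {
  if (!inherits(mix, "ploidy_mixture")) {
    rlang::abort("`mix` must be a `ploidy_mixture`.", class = "replicycle_domain_error")
  }
  sum(mix$classes$fraction * mix$classes$chromosomes)
}

#' Cell size at initiation by rank-order mapping
#'
#' Maps the initiation age onto an empirical size distribution: under
#' steady-state growth, cells ranked by size stand in for cells ranked by
#' age, so the size at initiation is the empirical quantile of the size
#' sample at probability `age_cdf(a_i)` (linear interpolation between
#' order statistics, quantile type 7).
#'
#' @param a_i Initiation age in `[0, 1)`.
#' @param sizes Numeric vector of cell cross-sectional areas (micrometers
#'   squared), or a data frame with an `area` column.
#' @return Size at initiation, same units as `sizes`.
#' @export
initiation_size <- function(a_i, sizes) {
  assert_age(a_i, arg = "a_i")
  if (is.data.frame(sizes)) {
    if (!"area" %in% names(sizes)) {
      rlang::abort("`sizes` data frame must have an `area` column.",
                   class = "replicycle_parse_error")
    }
    sizes <- sizes$area
  }
  if (!is.numeric(sizes) || length(sizes) == 0 ||
      any(!is.finite(sizes)) || any(sizes <= 0)) {
    rlang::abort("`sizes` must be a non-empty vector of finite positive areas.",
                 class = "replicycle_domain_error")
  }
  unname(stats::quantile(sizes, probs = age_cdf(a_i), type = 7))
}

#' Initiation delay between two strains in absolute time
#'
#' Converts each strain's initiation age to minutes from birth
#' (`age * tau`) and differences them, giving the delay of the test
#' strain relative to the reference (positive = later initiation).
#'
#' @param age_mut,tau_mut Initiation age and doubling time (minutes) of
#'   the test strain.
#' @param age_wt,tau_wt Initiation age and doubling time (minutes) of the
#'   reference strain.
#' @return Delay in minutes.
#' @examples
#' initiation_delay(0.47, 26.2, 0.17, 25.4)  # ~8 min
#' @export
initiation_delay <- function(age_mut, tau_mut, age_wt, tau_wt) {
  assert_age(age_mut, arg = "age_mut")
  assert_age(age_wt, arg = "age_wt")
  age_mut * tau_mut - age_wt * tau_wt
}
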