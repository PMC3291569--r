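#' Full cell-cycle report for one or more strains
#'
#' Orchestrates the whole inference chain per strain: Pfaffl
#' quantification of the qPCR table to an ori:ter ratio; C period from
#' the ratio; ploidy-mixture decomposition of the run-out histogram to
#' origins per cell and the uninitiated fraction; D period from origins;
#' initiation age from the uninitiated fraction; initiation size from
#' the size sample; and, when the optional inputs are present,
#' DnaA per origin and relative cell mass.
#'
#' @param strains A list of per-strain input lists. Each must contain
#'   `strain_id`, `tau` (minutes), `qpcr` (tidy qPCR data frame or file
#'   path) and `runout` (histogram data frame or file path); optional:
#'   `unit_fluorescence` (instrument calibration: fluorescence per
#'   chromosome equivalent, required for absolute ploidy and hence D),
#'   `sizes` (numeric vector, data frame with `area`, or path),
#'   `cells_per_ml` + `od` (hemocytometer count), and `dnaa_per_cell`
#'   (molecules per cell, from immunoblots scaled by a user-supplied
#'   literature baseline). Relative mass is computed against the first
#'   strain.
#' @param allowed_chromosomes Passed to [fit_ploidy_mixture()].
#' @return A tibble with one row per strain: `strain_id`, `tau`,
#'   `ori_ter`, `c_period`, `origins_per_cell`, `d_period`,
#'   `initiation_age`, `initiation_size`, `dnaa_per_ori`,
#'   `relative_mass`, `initiation_delay_min` (vs the first strain).
#' @examples
#' cfg <- sim_config(seed = 1, n_cells = 5000)
#' run_report(list(list(
#'   strain_id = "wt", tau = cfg$params$tau,
#'   qpcr = simulate_qpcr(cfg),
#'   runout = simulate_runout_histogram(cfg)
#' )))
#' @export
run_report <- function(strains, allowed_chromosomes = c(2, 4, 8, 16)) {
  if (!is.list(strains) || length(strains) == 0) {
    rlang::abort("`strains` must be a non-empty list of per-strain input lists.",
                 class = "replicycle_parse_error")
  }
  if (!is.null(strains$strain_id)) strains <- list(strains)  # single strain given bare
  rows <- purrr::map(strains, function(s) {
    for (f in c("strain_id", "tau", "qpcr", "runout")) {
      if (is.null(s[[f]])) {
        rlang::abort(sprintf("Strain input is missing required field `%s`.", f),
                     class = "replicycle_parse_error")
      }
    }
    if (!is.numeric(s$tau) || s$tau <= 0) {
      rlang::abort(sprintf("Strain '%s': `tau` must be a positive number of minutes.",
                           s$strain_id),
                   class = "replicycle_validation_error")
    }
    qpcr <- if (is.character(s$qpcr)) read_qpcr_table(s$qpcr) else s$qpcr
    runout <- if (is.character(s$runout)) read_runout_histogram(s$runout) else s$runout

    ratio <- pfaffl_ratios(qpcr)$ori_ter[1]
    mix <- fit_ploidy_mixture(runout, allowed_chromosomes = allowed_chromosomes,
                              unit_fluorescence = s$unit_fluorescence)
    origins <- mean_chromosomes(mix)
    periods <- infer_c_and_d(ratio, origins, s$tau)
    ai <- initiation_age_from_fraction(fraction_uninitiated(mix))

    size_i <- NA_real_
    if (!is.null(s$sizes)) {
      sizes <- if (is.character(s$sizes)) read_size_sample(s$sizes) else s$sizes
      size_i <- initiation_size(ai, sizes)
    }
    tibble::tibble(
      strain_id = s$strain_id,
      tau = s$tau,
      ori_ter = ratio,
      c_period = periods$c_period,
      origins_per_cell = origins,
      d_period = periods$d_period,
      initiation_age = ai,
      initiation_size = size_i,
      dnaa_per_ori = if (!is.null(s$dnaa_per_cell)) {
        dnaa_per_ori(s$dnaa_per_cell, origins)
      } else NA_real_,
      cells_per_ml = if (!is.null(s$cells_per_ml)) s$cells_per_ml else NA_real_,
      od = if (!is.null(s$od)) s$od else NA_real_
    )
  })
  report <- dplyr::bind_rows(rows)
  ref <- report[1, ]
  report |>
    dplyr::mutate(
      relative_mass = ifelse(
        !is.na(.data$cells_per_ml) & !is.na(ref$cells_per_ml),
        ref$cells_per_ml / .data$cells_per_ml,
        NA_real_
      ),
      initiation_delay_min = initiation_delay(.data$initiation_age, .data$tau,
                                              ref$initiation_age, ref$tau)
    ) |>
    dplyr::select(-"cells_per_ml", -"od")
}

#' Round a cell-cycle report to conventional reporting precision
#'
#' Periods to 0.1 min, ages to 0.01, ratios and relative masses to 0.01.
#' Use [write_report()] for full-precision serialization.
#'
#' @param report A tibble from [run_report()].
#' @return The rounded tibble.
#' @export
format_report <- function(report) {
  report |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c("tau", "c_period", "d_period",
                                    "initiation_delay_min")),
                    ~ round(.x, 1)),
      dplyr::across(dplyr::any_of(c("ori_ter", "origins_per_cell",
                                    "initiation_age", "initiation_size",
                                    "relative_mass")),
                    ~ round(.x, 2)),
      dplyr::across(dplyr::any_of("dnaa_per_ori"), ~ round(.x, 0))
    )
}

#' Serialize a cell-cycle report
#'
#' Writes the full-precision report as JSON (one record per strain) or
#' CSV.
#'
#' @param report A tibble from [run_report()].
#' @param path Output file path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(report, path)
  }
  rlang::inform(sprintf("Wrote %d strain record(s) to '%s' (%s).",
                        nrow(report), path, format))
  invisible(path)
}

#' Scatter plot of cell size against origins per cell
#'
#' Displays the proportionality between cell size and replication-origin
#' number across a (simulated or measured) population: at constant
#' initiator concentration, bigger cells carry proportionally more
#' origins.
#'
#' @param population A tibble with `size` and `origins` columns (e.g.
#'   from [simulate_population()]).
#' @return A ggplot object.
#' @export
plot_size_origins <- function(population) {
  if (!all(c("size", "origins") %in% names(population))) {
    rlang::abort("`population` needs `size` and `origins` columns.",
                 class = "replicycle_parse_error")
  }
  summ <- population |>
    dplyr::group_by(.data$origins) |>
    dplyr::summarise(median_size = stats::median(.data$size),
                     n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$median_size, y = .data$origins)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::labs(x = expression("median cross-sectional area (" * mu * m^2 * ")"),
                  y = "origins per cell", size = "cells",
                  title = "Origins scale with cell size")
}
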