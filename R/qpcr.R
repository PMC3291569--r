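#' Pfaffl relative quantification of the ori:ter marker-frequency ratio
#'
#' Efficiency-corrected relative quantification of origin- vs
#' terminus-proximal amplicons against a calibrator whose true ori:ter
#' ratio is 1 (replication run-out cells or spore DNA):
#' `ratio = E_ori^(Cq_ori,cal - Cq_ori,sample) /
#'          E_ter^(Cq_ter,cal - Cq_ter,sample)`.
#' Amplification efficiencies are per-cycle fold changes in `(1, 2]`
#' (2 = perfect doubling).
#'
#' @param cq_ori_sample,cq_ter_sample Quantification cycles of the ori
#'   and ter amplicons in the growing sample.
#' @param cq_ori_calibrator,cq_ter_calibrator Quantification cycles in
#'   the 1:1 calibrator.
#' @param eff_ori,eff_ter Amplification efficiencies in `(1, 2]`;
#'   default 2 (perfect doubling).
#' @return The ori:ter ratio (dimensionless).
#' @examples
#' pfaffl_ori_ter_ratio(14, 15, 15, 15)  # one cycle earlier ori: ratio 2
#' @export
pfaffl_ori_ter_ratio <- function(cq_ori_sample, cq_ter_sample,
                                 cq_ori_calibrator, cq_ter_calibrator,
                                 eff_ori = 2, eff_ter = 2) {
  cqs <- c(cq_ori_sample, cq_ter_sample, cq_ori_calibrator, cq_ter_calibrator)
  if (!is.numeric(cqs) || any(!is.finite(cqs))) {
    rlang::abort("All Cq values must be finite numerics.",
                 class = "replicycle_domain_error")
  }
  for (e in c(eff_ori, eff_ter)) {
    if (!is.numeric(e) || !is.finite(e) || e <= 1 || e > 2) {
      rlang::abort("Amplification efficiencies must lie in (1, 2] (per-cycle fold change).",
                   class = "replicycle_measurement_error")
    }
  }
  (eff_ori^(cq_ori_calibrator - cq_ori_sample)) /
    (eff_ter^(cq_ter_calibrator - cq_ter_sample))
}

#' Pfaffl ori:ter ratios from a tidy qPCR table
#'
#' Takes a long-format quantification table with one row per well and
#' returns one ori:ter ratio per sample, normalized against the
#' calibrator rows. Technical/biological replicates are averaged on the
#' Cq (log) scale before the Pfaffl computation.
#'
#' @param data A data frame with columns `sample_id`, `target`
#'   (`"ori"`/`"ter"`), `role` (`"sample"`/`"calibrator"`), `cq`, and
#'   `efficiency`.
#' @return A tibble with columns `sample_id` and `ori_ter`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' pfaffl_ratios(simulate_qpcr(cfg))
#' @export
pfaffl_ratios <- function(data) {
  required <- c("sample_id", "target", "role", "cq", "efficiency")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("qPCR table is missing column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "replicycle_parse_error")
  }
  if (!all(data$target %in% c("ori", "ter"))) {
    rlang::abort("`target` must be 'ori' or 'ter'.", class = "replicycle_parse_error")
  }
  if (!all(data$role %in% c("sample", "calibrator"))) {
    rlang::abort("`role` must be 'sample' or 'calibrator'.", class = "replicycle_parse_error")
  }
  means <- data |>
    dplyr::group_by(.data$role, .data$sample_id, .data$target) |>
    dplyr::summarise(cq = mean(.data$cq),
                     efficiency = mean(.data$efficiency),
                     .groups = "drop")
  cal <- means |>
    dplyr::filter(.data$role == "calibrator") |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(cq_cal = mean(.data$cq), .groups = "drop")
  if (!setequal(cal$target, c("ori", "ter"))) {
    rlang::abort("Calibrator rows for both 'ori' and 'ter' targets are required.",
                 class = "replicycle_parse_error")
  }
  means |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::left_join(cal, by = "target") |>
    tidyr::pivot_wider(id_cols = "sample_id",
                       names_from = "target",
                       values_from = c("cq", "efficiency", "cq_cal")) |>
    dplyr::mutate(ori_ter = pfaffl_ori_ter_ratio(
      cq_ori_sample = .data$cq_ori,
      cq_ter_sample = .data$cq_ter,
      cq_ori_calibrator = .data$cq_cal_ori,
      cq_ter_calibrator = .data$cq_cal_ter,
      eff_ori = .data$efficiency_ori[1],
      eff_ter = .data$efficiency_ter[1]
    )) |>
    dplyr::select("sample_id", "ori_ter")
}

#' Infer C and D periods from an ori:ter ratio and origins per cell
#'
#' Combines the two marker-frequency inversions: the C period from the
#' qPCR ori:ter ratio (`C = tau log2(ratio)`) and the D period from
#' flow-cytometry origins per cell (`D = tau log2(origins) - C`).
#'
#' @param ratio ori:ter marker-frequency ratio, >= 1.
#' @param origins Mean origins per cell, >= 1.
#' @param tau Mass doubling time in minutes.
#' @return A tibble with columns `c_period`, `d_period` and `status`
#'   (`"ok"`, `"degenerate"` when both periods collapse to 0, or
#'   `"negative_d"` when the two measurements are inconsistent; a
#'   negative D is returned unclipped).
#' @examples
#' infer_c_and_d(ratio = 3.54, origins = 7.0, tau = 24.02)
#' @export
infer_c_and_d <- function(ratio, origins, tau) {
  C <- c_period_from_ratio(ratio, tau)
  D <- withCallingHandlers(
    d_period_from_origins(origins, tau, C),
    warning = function(w) invokeRestart("muffleWarning")
  )
  status <- dplyr::case_when(
    D < 0 ~ "negative_d",
    C == 0 & D == 0 ~ "degenerate",
    .default = "ok"
  )
  if (any(status == "negative_d")) {
    rlang::warn("Inferred D period is negative: ori:ter ratio and origins per cell are inconsistent.")
  }
  if (any(status == "degenerate")) {
    rlang::warn("Degenerate cell cycle inferred (C = D = 0).")
  }
  tibble::tibble(c_period = C, d_period = D, status = status)
}
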