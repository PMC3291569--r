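#' Immunoblot and cell-count measurement records
#'
#' `blot_measurement()` records one quantitative-immunoblot lane: the
#' band intensity of the protein of interest (DnaA), the loading-control
#' intensity (FtsZ), and the basis the lane loading was normalized to
#' (culture optical density for concentration, or cell number for
#' per-cell amounts). `count_measurement()` records a hemocytometer
#' count at a given optical density.
#'
#' @param band_intensity,loading_control_intensity Densitometry
#'   intensities, arbitrary units, >= 0.
#' @param basis `"optical_density"` or `"cell_count"`.
#' @param basis_value The OD600 or cells/mL the lane was normalized to.
#' @return A `blot_measurement` / `count_measurement` object.
#' @export
blot_measurement <- function(band_intensity, loading_control_intensity,
                             basis = c("optical_density", "cell_count"),
                             basis_value = 1) {
  basis <- match.arg(basis)
  if (!is.numeric(band_intensity) || band_intensity < 0 ||
      !is.numeric(loading_control_intensity) || loading_control_intensity < 0) {
    rlang::abort("Intensities must be non-negative.", class = "replicycle_domain_error")
  }
  if (!is.numeric(basis_value) || basis_value <= 0) {
    rlang::abort("`basis_value` must be positive.", class = "replicycle_domain_error")
  }
  structure(list(band = band_intensity, control = loading_control_intensity,
                 basis = basis, basis_value = basis_value),
            class = "blot_measurement")
}

#' @rdname blot_measurement
#' @param cells_per_ml Hemocytometer count, cells/mL.
#' @param od Optical density (600 nm) of the counted culture.
#' @export
count_measurement <- function(cells_per_ml, od) {
  if (!is.numeric(cells_per_ml) || cells_per_ml <= 0 ||
      !is.numeric(od) || od <= 0) {
    rlang::abort("`cells_per_ml` and `od` must be positive.",
                 class = "replicycle_domain_error")
  }
  structure(list(cells_per_ml = cells_per_ml, od = od),
            class = "count_measurement")
}

#' Relative protein level between two immunoblot lanes
#'
#' Control-normalized ratio of a test lane to a reference lane:
#' `(band_test / control_test) / (band_ref / control_ref)`. Both lanes
#' must share the same normalization basis - a concentration comparison
#' (OD-normalized) and a per-cell comparison (count-normalized) answer
#' different questions and cannot be mixed. Invariant to any common gain
#' applied to all four intensities.
#'
#' @param test,reference [blot_measurement()] objects on the same basis.
#' @return The level of the test sample as a fraction of the reference.
#' @export
relative_dnaa_level <- function(test, reference) {
  for (m in list(test, reference)) {
    if (!inherits(m, "blot_measurement")) {
      rlang::abort("`test` and `reference` must be `blot_measurement` objects.",
                   class = "replicycle_domain_error")
    }
  }
  if (test$basis != reference$basis) {
    rlang::abort("Blot lanes were normalized to different bases; ratios are only meaningful on a shared basis.",
                 class = "replicycle_basis_error")
  }
  if (reference$band <= 0 || reference$control <= 0 || test$control <= 0) {
    rlang::abort("Reference band and both loading controls must be positive to form a ratio.",
                 class = "replicycle_measurement_error")
  }
  (test$band / test$control) / (reference$band / reference$control)
}

#' DnaA molecules per replication origin
#'
#' Divides an absolute per-cell DnaA amount (from immunoblots scaled by
#' an external literature baseline, supplied by the user) by the mean
#' origins per cell measured by replication run-out.
#'
#' @param dnaa_per_cell DnaA molecules per cell.
#' @param origins Mean origins per cell, >= 1.
#' @return Molecules per origin.
#' @examples
#' dnaa_per_ori(1400, 7)  # 200
#' @export
dnaa_per_ori <- function(dnaa_per_cell, origins) {
  if (!is.numeric(origins) || any(origins < 1)) {
    rlang::abort("`origins` must be >= 1.", class = "replicycle_domain_error")
  }
  dnaa_per_cell / origins
}

#' Relative cell mass from hemocytometer counts at equal optical density
#'
#' At matched OD two cultures hold the same total biomass, so more cells
#' per mL means smaller cells: relative mass (test vs reference) is
#' `reference_count / test_count`. The two counts must come from
#' cultures at the same OD (within `od_tolerance`).
#'
#' @param reference,test [count_measurement()] objects.
#' @param od_tolerance Maximum relative OD mismatch, default 5%.
#' @return Relative mass per cell of the test strain (reference = 1).
#' @examples
#' wt <- count_measurement(6.4e8, od = 0.3)
#' mut <- count_measurement(7.8e8, od = 0.3)
#' relative_mass_per_cell(wt, mut)  # 0.82
#' @export
relative_mass_per_cell <- function(reference, test, od_tolerance = 0.05) {
  for (m in list(reference, test)) {
    if (!inherits(m, "count_measurement")) {
      rlang::abort("`reference` and `test` must be `count_measurement` objects.",
                   class = "replicycle_domain_error")
    }
  }
  if (abs(reference$od - test$od) / reference$od > od_tolerance) {
    rlang::abort("Counts were taken at different optical densities; relative mass requires matched OD.",
                 class = "replicycle_basis_error")
  }
  reference$cells_per_ml / test$cells_per_ml
}
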