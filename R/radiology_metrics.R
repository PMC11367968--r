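#' Radiological percent reduction
#'
#' Percentage of lumen diameter or cross-sectional area lost at a
#' measurement site: `100 * reduction / reference`, rounded half-up to the
#' nearest integer (the convention that reproduces clinical reporting,
#' e.g. 4 mm lost of a 17 mm reference -> 23.53 -> 24%).
#'
#' @param reduction lumen lost (mm or mm^2)
#' @param reference undeformed lumen (same units)
#' @return integer percent
#' @export
percent_reduction <- function(reduction, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  if (any(reduction < 0) || any(reduction > reference)) {
    stop("reduction must lie in [0, reference]")
  }
  round_half_up(100 * reduction / reference)
}

#' Classify extrinsic outflow-graft obstruction significance
#'
#' The literature definition of significant extrinsic outflow-graft
#' obstruction is a cross-sectional-area decrease strictly greater
#' than 25%.
#'
#' @param csa_reduction_pct percent CSA reduction in `[0, 100]`
#' @return `"significant"` or `"not significant"`
#' @export
classify_eogo <- function(csa_reduction_pct) {
  stopifnot(all(csa_reduction_pct >= 0), all(csa_reduction_pct <= 100))
  ifelse(csa_reduction_pct > 25, "significant", "not significant")
}

#' One radiological measurement site
#'
#' @param case case label
#' @param site_mm distance from the graft inlet, mm
#' @param diameter_reduction_mm lumen diameter lost, mm
#' @param reference_diameter_mm undeformed diameter, mm
#' @param area_reduction_mm2 CSA lost, mm^2
#' @param reference_area_mm2 undeformed CSA, mm^2
#' @return a one-row tibble of class `radiological_measurement`
#' @export
radiological_measurement <- function(case, site_mm,
                                     diameter_reduction_mm,
                                     reference_diameter_mm,
                                     area_reduction_mm2,
                                     reference_area_mm2) {
  stopifnot(diameter_reduction_mm >= 0,
            diameter_reduction_mm <= reference_diameter_mm,
            area_reduction_mm2 >= 0,
            area_reduction_mm2 <= reference_area_mm2)
  structure(
    tibble::tibble(case = case, site_mm = site_mm,
                   diameter_reduction_mm = diameter_reduction_mm,
                   reference_diameter_mm = reference_diameter_mm,
                   area_reduction_mm2 = area_reduction_mm2,
                   reference_area_mm2 = reference_area_mm2),
    class = c("radiological_measurement", class(tibble::tibble())))
}

#' Radiological severity report
#'
#' One row per measurement site: integer percent diameter and CSA
#' reductions and the obstruction classification (significant if the CSA
#' reduction exceeds 25%). Input row order is preserved.
#'
#' @param measurements a tibble of measurement sites (rows as produced by
#'   [radiological_measurement()] or [make_radiology_fixture()])
#' @return tibble: case, site_mm, diameter_pct, csa_pct, classification
#' @export
radiology_report <- function(measurements) {
  stopifnot(nrow(measurements) > 0)
  d_pct <- percent_reduction(measurements$diameter_reduction_mm,
                             measurements$reference_diameter_mm)
  a_pct <- percent_reduction(measurements$area_reduction_mm2,
                             measurements$reference_area_mm2)
  tibble::tibble(case = measurements$case,
                 site_mm = measurements$site_mm,
                 diameter_pct = as.integer(d_pct),
                 csa_pct = as.integer(a_pct),
                 classification = classify_eogo(a_pct))
}
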