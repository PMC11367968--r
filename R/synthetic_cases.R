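# Parametric stand-ins for the two patients' stenosed outflow grafts and
# analytic/stochastic field fixtures, so every downstream stage is
# testable without any imaging data.

# Narrowest CSA (mm^2) and reported integer percent reductions per severity.
CASE_TABLE <- list(
  `1` = list(csa = c(OS = 173, AS1 = 136, AS2 = 116),
             pct = c(OS = 28, AS1 = 43, AS2 = 52)),
  `2` = list(csa = c(OS = 165, AS1 = 130, AS2 = 93),
             pct = c(OS = 31, AS1 = 46, AS2 = 61))
)

#' Synthetic case fixture for one patient-like graft
#'
#' Parametric stand-in for a segmented stenosed outflow graft. The
#' unstenosed baseline area is never reported clinically, so it is
#' back-computed as the mean of `narrowest_CSA / (1 - pct/100)` over the
#' three severities (about 240 mm^2 for both cases, consistent with a
#' 17.5 mm lumen). The stenosis spans 45 mm (the window the ten
#' 5 mm-apart measurement planes cover), centred 30 mm from the inlet,
#' between the 20 mm and 40 mm radiological sites; the compression is
#' one-sided (eccentricity 1), as extrinsic material under the bend relief
#' compresses one wall.
#'
#' @param case_id 1 or 2
#' @param length graft segment length, m
#' @param stenosis_center m from the inlet
#' @param stenosis_extent m
#' @param eccentricity one-sided fraction of the compression
#' @return object of class `case_fixture`
#' @export
make_case <- function(case_id, length = 0.090,
                      stenosis_center = 0.030, stenosis_extent = 0.045,
                      eccentricity = 1) {
  key <- as.character(case_id)
  if (!key %in% names(CASE_TABLE)) stop("unknown case id: ", case_id)
  tab <- CASE_TABLE[[key]]
  baseline_mm2 <- mean(tab$csa / (1 - tab$pct / 100))
  structure(
    list(case_id = as.integer(case_id),
         baseline_area_mm2 = baseline_mm2,
         baseline_diameter = 2 * sqrt(baseline_mm2 * 1e-6 / pi),
         target_csa_mm2 = tab$csa,
         reported_pct = tab$pct,
         stenosis_center = stenosis_center,
         stenosis_extent = stenosis_extent,
         eccentricity = eccentricity,
         curvature_radius = Inf,
         length = length,
         flows_lpm = c(3.5, 4.5, 5.5)),
    class = "case_fixture")
}

#' Build the graft geometry of a case fixture at a given severity
#'
#' The original stenosis (OS) is built directly; the augmented severities
#' (AS1, AS2) are produced from OS by stepwise linear augmentation of the
#' compression displacement, scaled to hit the severity's narrowest CSA.
#'
#' @param fixture a [make_case()] fixture
#' @param severity `"OS"`, `"AS1"` or `"AS2"`
#' @return a `graft_geometry`
#' @export
case_graft <- function(fixture, severity = c("OS", "AS1", "AS2")) {
  severity <- match.arg(severity)
  spec <- stenosis_spec(
    center_position = fixture$stenosis_center,
    axial_extent = fixture$stenosis_extent,
    target_narrowest_csa = fixture$target_csa_mm2[["OS"]] * 1e-6,
    eccentricity = fixture$eccentricity)
  os <- build_graft(spec, fixture$baseline_diameter, fixture$length,
                    curvature_radius = fixture$curvature_radius)
  if (severity == "OS") return(os)
  f <- severity_factor_for_csa(os, fixture$target_csa_mm2[[severity]] * 1e-6)
  augment_stenosis(os, f)
}

#' @export
print.case_fixture <- function(x, ...) {
  cat(sprintf("case_fixture %d: baseline %.1f mm^2, targets %s mm^2\n",
              x$case_id, x$baseline_area_mm2,
              paste(x$target_csa_mm2, collapse = "/")))
  invisible(x)
}

with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Analytic and stochastic field fixtures
#'
#' Builds a synthetic `flow_field_series` on a raster grid with known
#' statistics, used as oracle input to the metrics stage:
#' \describe{
#'   \item{constant}{uniform axial velocity `value` and uniform pressure
#'     `pressure_pa`; fluctuations are identically zero.}
#'   \item{poiseuille}{steady developed profile `2 v_mean (1 - (r/R)^2)`
#'     for the flow rate `flow_rate_m3s`, with the matching linear axial
#'     pressure fall `8 mu Q / (pi R^4)` from `inlet_pressure_pa`.}
#'   \item{sinusoidal}{single-component signal `A sin(2 pi f t)` sampled
#'     uniformly over `n_periods` whole periods (non-integer period counts
#'     are rejected: they would bias the RMS), so the fluctuation RMS is
#'     exactly `A / sqrt(2)`.}
#'   \item{gaussian}{mean axial field `mean` plus independent zero-mean
#'     Gaussian noise of standard deviation `sigma` in all three
#'     components, per cell and instant, seeded and reproducible; TKE
#'     density converges to `1.5 rho sigma^2`.}
#' }
#'
#' @param kind fixture kind
#' @param raster a `graft_raster` providing the grid
#' @param fluid a [fluid_properties()]
#' @param params named list of parameters (see Details above)
#' @param n_samples number of sampled instants
#' @param seed RNG seed for stochastic fixtures (default 1); the global
#'   RNG state is preserved
#' @return a `flow_field_series` carrying cell-centred components
#'   (`uz`, `ur`, `w`)
#' @export
make_field_fixture <- function(kind = c("constant", "poiseuille",
                                        "sinusoidal", "gaussian"),
                               raster, fluid = fluid_properties(),
                               params = list(), n_samples = 16L, seed = 1L) {
  kind <- match.arg(kind)
  nz <- raster$nz; nr <- raster$nr
  fluid_mask <- outer(raster$np, seq_len(nr), ">=")  # nz x nr
  zero <- array(0, dim = c(nz, nr, n_samples))
  times <- seq(0, 1, length.out = n_samples)
  uz <- zero; ur <- zero; w <- zero
  p <- array(0, dim = c(nz, nr, n_samples))

  if (kind == "constant") {
    val <- params$value %||% 1
    p0 <- params$pressure_pa %||% mmhg_to_pa(100)
    uz <- array(val * fluid_mask, dim = dim(zero))
    p <- array(p0, dim = dim(p))
  } else if (kind == "poiseuille") {
    q <- params$flow_rate_m3s %||% lpm_to_m3s(4.5)
    p_in <- params$inlet_pressure_pa %||% mmhg_to_pa(100)
    a <- raster$baseline_radius
    vmean <- q / (pi * a^2)
    prof <- 2 * vmean * (1 - (raster$r_centers / a)^2)
    slope <- -8 * fluid$dynamic_viscosity * q / (pi * a^4)
    uz1 <- t(array(prof, dim = c(nr, nz))) * fluid_mask
    p1 <- array(p_in + slope * raster$z_centers, dim = c(nz, nr))
    uz <- array(uz1, dim = dim(zero))
    p <- array(p1, dim = dim(p))
    times <- seq(0, 1, length.out = n_samples)
  } else if (kind == "sinusoidal") {
    A <- params$amplitude %||% 0.5
    f <- params$frequency %||% 10
    n_periods <- params$n_periods %||% 5
    if (abs(n_periods - round(n_periods)) > 1e-12) {
      stop("sinusoidal fixture requires a whole number of periods")
    }
    times <- (seq_len(n_samples) - 1) / n_samples * n_periods / f
    sig <- A * sin(2 * pi * f * times)
    uz <- outer(array(1, dim = c(nz, nr)) * fluid_mask, sig)
    p <- array(mmhg_to_pa(100), dim = dim(p))
  } else if (kind == "gaussian") {
    mu0 <- params$mean %||% 1
    sigma <- params$sigma %||% 0.1
    ncell <- nz * nr * n_samples
    noise <- with_preserved_seed(seed, {
      list(u = stats::rnorm(ncell, 0, sigma),
           v = stats::rnorm(ncell, 0, sigma),
           w = stats::rnorm(ncell, 0, sigma))
    })
    mask3 <- array(fluid_mask, dim = dim(zero))
    uz <- (mu0 + array(noise$u, dim = dim(zero))) * mask3
    ur <- array(noise$v, dim = dim(zero)) * mask3
    w <- array(noise$w, dim = dim(zero)) * mask3
    p <- array(mmhg_to_pa(100), dim = dim(p))
  }

  structure(
    list(raster = raster, fluid = fluid,
         config = list(kind = kind, params = params, seed = seed),
         uz = uz, ur = ur, w = w, p = p, times = times,
         flux_in = rep(1, n_samples), flux_out = rep(1, n_samples),
         div_max = rep(0, n_samples),
         diagnostics = list(fixture = kind)),
    class = "flow_field_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The four reported radiological measurement sites
#'
#' Diameter and CSA reductions (with their references) measured at 20 and
#' 40 mm from the graft inlet in the two cases.
#'
#' @return tibble with one row per site, ordered Case 1 at 20 mm, Case 1
#'   at 40 mm, Case 2 at 20 mm, Case 2 at 40 mm
#' @export
make_radiology_fixture <- function() {
  dplyr::bind_rows(
    radiological_measurement(1L, 20, 4, 17, 54, 244),
    radiological_measurement(1L, 40, 6, 17, 76, 259),
    radiological_measurement(2L, 20, 9, 17, 85, 236),
    radiological_measurement(2L, 40, 6, 17, 44, 246))
}
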