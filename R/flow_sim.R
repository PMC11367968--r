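#' Blood fluid properties
#'
#' Newtonian model: at the shear levels reached in a stenosed outflow graft
#' shear-thinning is negligible, so a constant viscosity is used.
#'
#' @param density kg/m^3 (default 1060, whole blood)
#' @param dynamic_viscosity Pa.s (default 3.5e-3)
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 3.5e-3) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Solver configuration
#'
#' Desk-scale defaults: 32 cells per diameter, adaptive time step at
#' advective CFL 0.4 (also bounded by the explicit-diffusion limit),
#' washout of three domain pass-through times before sampling, then a 1 s
#' sampling window at 200 evenly spaced instants. The pressure Poisson
#' equation is solved to a relative residual of 1e-6. An optional
#' steady-state detector freezes the run when the velocity field stops
#' changing (sup-norm change below `steady_tol * u_inlet` over 25 steps)
#' and replicates the steady field across the remaining samples.
#'
#' @param flow_rate_lpm inlet (device) flow, L/min
#' @param outlet_pressure_mmhg aortic reference static pressure at the
#'   outlet, mmHg
#' @param resolution grid cells per baseline diameter
#' @param cfl advective Courant number for the adaptive time step
#' @param washout_time s of flow time discarded before sampling
#'   (`NULL` = 3 domain pass-through times at the bulk velocity)
#' @param sampling_time s of flow time sampled for statistics
#' @param n_samples number of sampled instants across `sampling_time`
#' @param mode `"axisymmetric"` or `"planar"`
#' @param beta_upwind fraction of first-order upwinding blended into the
#'   second-order central advection scheme (deferred-correction style
#'   stabilization; 0 = pure central)
#' @param poisson_tol relative residual for the pressure solve
#' @param steady_tol steady-state detection threshold (0 disables)
#' @param max_steps hard cap on time steps
#' @return object of class `sim_config`
#' @export
sim_config <- function(flow_rate_lpm = 4.5,
                       outlet_pressure_mmhg = 100,
                       resolution = 32L,
                       cfl = 0.4,
                       washout_time = NULL,
                       sampling_time = 1.0,
                       n_samples = 200L,
                       mode = c("axisymmetric", "planar"),
                       beta_upwind = 0.15,
                       poisson_tol = 1e-6,
                       steady_tol = 1e-6,
                       max_steps = 2e6) {
  mode <- match.arg(mode)
  stopifnot(flow_rate_lpm >= 0, resolution >= 8, cfl > 0, cfl <= 1,
            sampling_time > 0, n_samples >= 1,
            beta_upwind >= 0, beta_upwind <= 1, poisson_tol > 0)
  structure(
    list(flow_rate_lpm = flow_rate_lpm,
         inlet_flow_m3s = lpm_to_m3s(flow_rate_lpm),
         outlet_pressure_pa = mmhg_to_pa(outlet_pressure_mmhg),
         outlet_pressure_mmhg = outlet_pressure_mmhg,
         resolution = as.integer(resolution), cfl = cfl,
         washout_time = washout_time, sampling_time = sampling_time,
         n_samples = as.integer(n_samples), mode = mode,
         beta_upwind = beta_upwind, poisson_tol = poisson_tol,
         steady_tol = steady_tol, max_steps = as.integer(max_steps)),
    class = "sim_config")
}

#' Simulate unsteady incompressible flow through a rasterized graft
#'
#' Fractional-step (projection) advance of the incompressible
#' Navier-Stokes equations on the staggered grid of a [rasterize()]d
#' geometry: flat (plug) inlet velocity matching the device flow rate,
#' fixed static reference pressure with zero-gradient velocity at the
#' outlet, rigid no-slip walls. Fields are sampled at a fixed cadence after
#' the washout period.
#'
#' @param raster a `graft_raster`
#' @param fluid a [fluid_properties()]
#' @param config a [sim_config()] (its `resolution`/`mode` must match the
#'   raster's)
#' @return object of class `flow_field_series`: sampled staggered velocity
#'   fields (m/s), absolute pressure fields (Pa), sample times, per-sample
#'   inlet/outlet fluxes and divergence maxima, and solver diagnostics
#' @export
simulate_flow <- function(raster, fluid, config) {
  stopifnot(inherits(raster, "graft_raster"),
            inherits(fluid, "fluid_properties"),
            inherits(config, "sim_config"))
  if (config$mode != raster$mode) {
    stop("config mode (", config$mode, ") does not match raster mode (",
         raster$mode, ")")
  }
  axisym <- raster$mode == "axisymmetric"
  dr <- raster$dr
  n_in <- raster$nu[1]
  a_in <- if (axisym) pi * (n_in * dr)^2 else n_in * dr  # open inlet area
  u_in <- if (config$inlet_flow_m3s > 0) config$inlet_flow_m3s / a_in else 0
  u_bulk <- if (axisym) config$inlet_flow_m3s / (pi * raster$baseline_radius^2) else u_in
  washout <- config$washout_time
  if (is.null(washout)) {
    washout <- if (u_bulk > 0) 3 * raster$length / u_bulk else 0
  }
  # advective stability bound for the time-step cap
  max_dt <- 0.125 * min(raster$dz, dr)^2 * fluid$density / fluid$dynamic_viscosity
  res <- .simulate_core(
    raster$nz, raster$nr, raster$dz, dr, axisym,
    as.integer(raster$np), as.integer(raster$nu), as.numeric(raster$hu),
    fluid$density, fluid$dynamic_viscosity, u_in, config$outlet_pressure_pa,
    config$cfl, washout, config$sampling_time, config$n_samples,
    config$beta_upwind, config$poisson_tol, config$steady_tol,
    max_dt, config$max_steps)
  ns <- config$n_samples
  structure(
    list(
      raster = raster, fluid = fluid, config = config,
      u = array(res$u, dim = c(raster$nz + 1L, raster$nr, ns)),
      v = array(res$v, dim = c(raster$nz, raster$nr + 1L, ns)),
      p = array(res$p, dim = c(raster$nz, raster$nr, ns)),
      times = res$times,
      flux_in = res$flux_in, flux_out = res$flux_out,
      div_max = res$div_max,
      diagnostics = list(n_steps = res$n_steps,
                         cg_iterations = res$cg_iterations,
                         steady = res$steady, steady_step = res$steady_step,
                         dt_final = res$dt_final,
                         washout_time = washout, u_inlet = u_in)
    ),
    class = "flow_field_series")
}

#' @export
print.flow_field_series <- function(x, ...) {
  cat(sprintf("flow_field_series: %d samples over %.3g s (%s, %d x %d cells)\n",
              length(x$times), diff(range(x$times)) + 0,
              x$raster$mode, x$raster$nz, x$raster$nr))
  cat(sprintf("  Q = %.2f L/min, %d steps, steady: %s\n",
              x$config$flow_rate_lpm, x$diagnostics$n_steps,
              x$diagnostics$steady))
  invisible(x)
}

#' Cell-centred velocity components of a sampled series
#'
#' Interpolates the staggered components to pressure-cell centres. Solid
#' cells carry zeros.
#'
#' @param series a `flow_field_series`
#' @return list with arrays `uz`, `ur` of dim (nz, nr, n_samples)
#' @export
cell_velocity <- function(series) {
  if (!is.null(series$uz)) return(list(uz = series$uz, ur = series$ur))
  nz <- series$raster$nz; nr <- series$raster$nr
  uz <- 0.5 * (series$u[1:nz, , , drop = FALSE] +
               series$u[2:(nz + 1L), , , drop = FALSE])
  ur <- 0.5 * (series$v[, 1:nr, , drop = FALSE] +
               series$v[, 2:(nr + 1L), , drop = FALSE])
  mask <- outer(seq_len(nr), series$raster$np, function(j, np) j > np)  # nr x nz
  mask <- aperm(array(mask, dim = c(nr, nz, dim(uz)[3])), c(2, 1, 3))
  uz[mask] <- 0; ur[mask] <- 0
  list(uz = uz, ur = ur)
}

#' Cell volumes of a raster grid
#'
#' Axisymmetric: full annular volumes `2 pi r dr dz`; planar: `dr dz` per
#' unit depth. Solid cells get volume 0.
#'
#' @param raster a `graft_raster`
#' @return matrix (nz x nr) of volumes, m^3
#' @export
cell_volumes <- function(raster) {
  w <- if (raster$mode == "axisymmetric") {
    2 * pi * raster$r_centers * raster$dr * raster$dz
  } else {
    rep(raster$dr * raster$dz, raster$nr)
  }
  vol <- matrix(w, nrow = raster$nz, ncol = raster$nr, byrow = TRUE)
  fluid <- outer(raster$np, seq_len(raster$nr), ">=")
  vol * fluid
}

#' Discrete mass-conservation check
#'
#' @param series a `flow_field_series`
#' @return list: `flux_mismatch` = max over samples of
#'   `|outlet flux - inlet flux| / max(|inlet flux|, eps)`;
#'   `max_divergence` = max discrete divergence over cells and samples (1/s)
#' @export
check_mass_conservation <- function(series) {
  stopifnot(inherits(series, "flow_field_series"), length(series$times) > 0)
  denom <- pmax(abs(series$flux_in), 1e-15)
  list(flux_mismatch = max(abs(series$flux_out - series$flux_in) / denom),
       max_divergence = max(series$div_max))
}

#' Reynolds number of graft flow
#'
#' `rho * v_mean * d / mu` with the bulk velocity `v_mean = Q / (pi d^2/4)`.
#'
#' @param fluid a [fluid_properties()]
#' @param flow_rate m^3/s
#' @param diameter m
#' @export
reynolds_number <- function(fluid, flow_rate, diameter) {
  stopifnot(flow_rate >= 0, diameter > 0)
  v <- flow_rate / (pi * diameter^2 / 4)
  fluid$density * v * diameter / fluid$dynamic_viscosity
}

#' Analytic bracket for the stenotic pressure drop
#'
#' Lower bound: inviscid Bernoulli acceleration into the throat with no
#' pressure recovery, `0.5 rho (v_throat^2 - v_inlet^2)`. Upper bound: the
#' same plus the fully developed Poiseuille drop of the unstenosed tube
#' over the graft length. The simulated inlet-to-outlet drop of a stenosed
#' graft should fall between these within a solver tolerance factor.
#'
#' @param geom a `graft_geometry`
#' @param fluid a [fluid_properties()]
#' @param flow_rate m^3/s
#' @return list with `lower_pa`, `upper_pa`, `lower_mmhg`, `upper_mmhg`
#' @export
pressure_drop_bracket <- function(geom, fluid, flow_rate) {
  a <- geom$baseline_radius
  a_throat <- sqrt(narrowest_csa(geom) / pi)
  v_in <- flow_rate / (pi * a^2)
  v_th <- flow_rate / (pi * a_throat^2)
  bern <- 0.5 * fluid$density * (v_th^2 - v_in^2)
  pois <- 8 * fluid$dynamic_viscosity * geom$length * flow_rate / (pi * a^4)
  list(lower_pa = bern, upper_pa = bern + pois,
       lower_mmhg = pa_to_mmhg(bern), upper_mmhg = pa_to_mmhg(bern + pois))
}

#' Grid-refinement (mesh-independence) study
#'
#' Reruns the same physical problem at increasing grid resolutions and
#' reports the time-averaged pressure gradient at each, with pairwise
#' differences between consecutive resolutions. Mirrors the usual CFD
#' protocol: the difference between the two finest grids quantifies the
#' residual discretization error of the reported pressure level.
#'
#' @param geom a `graft_geometry`
#' @param fluid a [fluid_properties()]
#' @param config a [sim_config()]; its `resolution` is overridden
#' @param resolutions strictly increasing integer vector, length >= 3
#' @return tibble: resolution, pressure_gradient_mmHg, diff_prev_mmHg
#' @export
mesh_independence_study <- function(geom, fluid, config,
                                    resolutions = c(16L, 32L, 48L)) {
  stopifnot(length(resolutions) >= 3L, all(diff(resolutions) > 0))
  grads <- vapply(resolutions, function(res) {
    cfg <- config
    cfg$resolution <- as.integer(res)
    raster <- rasterize(geom, res)
    series <- simulate_flow(raster, fluid, cfg)
    planes <- place_planes(csa_profile(geom, 201L))
    pp <- plane_mean_pressure(series, planes)
    pressure_gradient(pp$mean_pressure_mmhg, config$outlet_pressure_mmhg)
  }, numeric(1))
  tibble::tibble(
    resolution = as.integer(resolutions),
    pressure_gradient_mmHg = grads,
    diff_prev_mmHg = c(NA_real_, abs(diff(grads))))
}
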