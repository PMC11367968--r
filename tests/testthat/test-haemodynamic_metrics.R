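# Plane placement, plane-averaged pressures, pressure gradient, peak
# velocity, Reynolds decomposition and integrated TKE.

test_that("planes centre on the throat and fall back to the midpoint", {
  g <- case_graft(make_case(1), "OS")      # throat at 30 mm in a 90 mm tube
  planes <- place_planes(csa_profile(g, 301L))
  expect_equal(nrow(planes), 10L)
  expect_equal(diff(planes$station_m), rep(5e-3, 9L), tolerance = 1e-9)
  expect_lt(abs(mean(planes$station_m) - 0.030), 2e-4)
  expect_equal(max(planes$station_m) - min(planes$station_m), 0.045)
  # plane 5 or 6 is nearest the narrowest station
  nearest <- which.min(abs(planes$station_m - 0.030))
  expect_true(nearest %in% c(5L, 6L))

  tube <- straight_tube(length = 0.09)     # no stenosis: centre on midpoint
  pl2 <- place_planes(csa_profile(tube, 101L))
  expect_lt(abs(mean(pl2$station_m) - 0.045), 1e-3)

  short <- csa_profile(straight_tube(length = 0.03), 31L)
  expect_error(place_planes(short), "exceeds the domain")
})

test_that("plane set shifts inward when the stenosis abuts the inlet", {
  g <- build_graft(stenosis_spec(0.012, 0.02, 150e-6, 0), 0.0175, 0.09)
  planes <- place_planes(csa_profile(g, 301L))
  expect_true(min(planes$station_m) >= 0)
  expect_equal(diff(planes$station_m), rep(5e-3, 9L), tolerance = 1e-9)
})

test_that("plane mean pressure recovers constructed fields exactly", {
  raster <- rasterize(straight_tube(length = 0.09), 16L)
  fluid <- fluid_properties()
  fix <- make_field_fixture("constant", raster, fluid,
                            params = list(value = 1, pressure_pa = mmhg_to_pa(104)))
  planes <- place_planes(raster_csa(raster))
  pp <- plane_mean_pressure(fix, planes)
  expect_equal(pp$mean_pressure_mmhg, rep(104, 10L), tolerance = 1e-12)

  # per-plane target values painted onto the pressure field
  fix2 <- fix
  targets <- seq(101, 110, length.out = 10L)
  for (k in seq_len(10L)) {
    i <- which.min(abs(raster$z_centers - planes$station_m[k]))
    fix2$p[i, , ] <- mmhg_to_pa(targets[k])
  }
  expect_equal(plane_mean_pressure(fix2, planes)$mean_pressure_mmhg, targets,
               tolerance = 1e-12)
})

test_that("poiseuille fixture yields the analytic pressure slope and peak", {
  raster <- rasterize(straight_tube(length = 0.09), 32L)
  fluid <- fluid_properties()
  q <- lpm_to_m3s(4.5)
  fix <- make_field_fixture("poiseuille", raster, fluid,
                            params = list(flow_rate_m3s = q))
  planes <- place_planes(raster_csa(raster))
  pp <- plane_mean_pressure(fix, planes)
  slope <- stats::coef(stats::lm(mean_pressure_mmhg ~ station_m, pp))[[2]]
  a <- raster$baseline_radius
  # planes snap to the nearest cell layer, so the slope carries a
  # half-cell jitter
  expect_equal(slope, pa_to_mmhg(-8 * fluid$dynamic_viscosity * q / (pi * a^4)),
               tolerance = 5e-3)
  expect_true(all(diff(pp$mean_pressure_mmhg) < 0))  # monotone downstream
  vmean <- q / (pi * a^2)
  expect_equal(peak_velocity(fix), 2 * vmean, tolerance = 0.01)
})

test_that("pressure_gradient is a shifted maximum", {
  expect_equal(pressure_gradient(rep(100, 10)), 0)
  expect_equal(pressure_gradient(c(108.44, 104, 101), 100), 8.44)
  x <- c(103.2, 101.7, 100.4, 105.9, 100.1)
  expect_equal(pressure_gradient(sample(x), 100), pressure_gradient(x, 100))
  # invariant to shifting field and reference together
  expect_equal(pressure_gradient(x + 7, 107), pressure_gradient(x, 100))
  expect_error(pressure_gradient(numeric(0)))
})

test_that("peak_velocity is homogeneous and zero for zero flow", {
  raster <- rasterize(straight_tube(length = 0.05), 16L)
  fluid <- fluid_properties()
  fix <- make_field_fixture("poiseuille", raster, fluid,
                            params = list(flow_rate_m3s = lpm_to_m3s(3.5)))
  v1 <- peak_velocity(fix)
  fix$uz <- 2.5 * fix$uz; fix$ur <- 2.5 * fix$ur
  expect_equal(peak_velocity(fix), 2.5 * v1, tolerance = 1e-12)
  fix$uz[] <- 0; fix$ur[] <- 0
  expect_equal(peak_velocity(fix), 0)
  expect_gte(peak_velocity(fix, mode = "instant"), peak_velocity(fix))
})

test_that("reynolds_stats obeys the TKE identity and needs >= 2 samples", {
  raster <- rasterize(straight_tube(length = 0.035), 8L)
  fluid <- fluid_properties()
  fix <- make_field_fixture("gaussian", raster, fluid,
                            params = list(mean = 0.5, sigma = 0.05),
                            n_samples = 200L, seed = 11L)
  rs <- reynolds_stats(fix, fluid)
  expect_true(all(rs$up >= 0 & rs$vp >= 0 & rs$wp >= 0))
  expect_equal(rs$tke_density,
               0.5 * fluid$density * (rs$up^2 + rs$vp^2 + rs$wp^2),
               tolerance = 1e-15)
  one <- fix
  one$uz <- fix$uz[, , 1, drop = FALSE]
  one$ur <- fix$ur[, , 1, drop = FALSE]
  one$w <- fix$w[, , 1, drop = FALSE]
  one$times <- fix$times[1]
  expect_error(reynolds_stats(one, fluid), "at least 2 samples")
})

test_that("integrate_tke is exact for uniform density and converges", {
  raster <- rasterize(straight_tube(length = 0.05), 16L)
  vol <- cell_volumes(raster)
  k0 <- 37.5
  tke <- matrix(k0, raster$nz, raster$nr) * (vol > 0)
  expect_equal(integrate_tke(tke, vol), 1000 * k0 * sum(vol), tolerance = 1e-12)
  # aligned mask: raster volume matches the analytic cylinder volume
  a <- raster$baseline_radius
  expect_equal(sum(vol), pi * a^2 * raster$length, tolerance = 1e-6)

  # quadrature convergence for a smooth analytic density
  int_at <- function(res) {
    r <- rasterize(straight_tube(length = 0.05), res)
    dens <- outer(r$z_centers, r$r_centers,
                  function(z, rr) 50 * sin(pi * z / 0.05) * (1 - (rr / a)^2))
    integrate_tke(dens * (cell_volumes(r) > 0), cell_volumes(r))
  }
  expect_lt(abs(int_at(32L) - int_at(16L)) / abs(int_at(32L)), 0.01)
})

test_that("summary bundles gradient, peak velocity and integrated TKE", {
  raster <- rasterize(straight_tube(length = 0.09), 16L)
  fluid <- fluid_properties()
  fix <- make_field_fixture("poiseuille", raster, fluid,
                            params = list(flow_rate_m3s = lpm_to_m3s(4.5),
                                          inlet_pressure_pa = mmhg_to_pa(101)))
  s <- summarize_haemodynamics(fix)
  expect_s3_class(s, "haemodynamic_summary")
  expect_equal(nrow(s$plane_pressures), 10L)
  expect_equal(s$integrated_tke_mj, 0)           # steady flow: no fluctuations
  expect_gt(s$pressure_gradient_mmhg, 0)
})
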