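# Projection solver: analytic limits, conservation, scaling behaviour and
# boundary-condition invariances. Runs use small grids and short windows;
# the steady-state detector shortcuts the laminar cases.

test_that("reynolds_number follows rho v d / mu", {
  fluid <- fluid_properties()
  re <- reynolds_number(fluid, lpm_to_m3s(5.5), 0.0175)
  expect_equal(re, 1060 * (lpm_to_m3s(5.5) / (pi * 0.0175^2 / 4)) * 0.0175 / 3.5e-3)
  expect_equal(re, 2017, tolerance = 0.01)
  expect_equal(reynolds_number(fluid, 0, 0.0175), 0)
  expect_equal(reynolds_number(fluid, 2 * lpm_to_m3s(3.5), 0.0175),
               2 * reynolds_number(fluid, lpm_to_m3s(3.5), 0.0175))
})

test_that("zero inflow stays quiescent at the reference pressure", {
  raster <- rasterize(straight_tube(length = 0.05), 16L)
  cfg <- sim_config(flow_rate_lpm = 0, resolution = 16L, washout_time = 0.01,
                    sampling_time = 0.01, n_samples = 3L)
  s <- simulate_flow(raster, fluid_properties(), cfg)
  expect_equal(max(abs(s$u)), 0)
  expect_equal(max(abs(s$v)), 0)
  expect_equal(max(abs(s$p - mmhg_to_pa(100))), 0, tolerance = 1e-9)
  mc <- check_mass_conservation(s)
  expect_equal(mc$flux_mismatch, 0)
})

test_that("low-Re tube flow converges to Hagen-Poiseuille", {
  fluid <- fluid_properties()
  tube <- straight_tube(length = 8 * 0.0175)
  raster <- rasterize(tube, 16L)
  q <- flow_for_re(50)
  cfg <- sim_config(flow_rate_lpm = m3s_to_lpm(q), resolution = 16L,
                    sampling_time = 0.2, n_samples = 10L)
  s <- simulate_flow(raster, fluid, cfg)
  expect_true(s$diagnostics$steady)
  a <- raster$baseline_radius
  vmean <- q / (pi * a^2)
  # centreline velocity 2 x mean (coarse grid: 5% band; the acceptance
  # suite checks 2% at 32 cells/diameter)
  expect_equal(peak_velocity(s), 2 * vmean, tolerance = 0.05)
  # developed-region pressure slope
  planes <- place_planes(csa_profile(tube, 101L), count = 6L, spacing = 0.012)
  pp <- plane_mean_pressure(s, planes)
  dev <- pp[pp$station_m > 0.5 * raster$length, ]
  slope <- stats::coef(stats::lm(mean_pressure_mmhg ~ station_m, dev))[[2]]
  expect_equal(slope, pa_to_mmhg(-8 * fluid$dynamic_viscosity * q / (pi * a^4)),
               tolerance = 0.05)
  expect_true(all(diff(pp$mean_pressure_mmhg) < 0))
  mc <- check_mass_conservation(s)
  expect_lt(mc$flux_mismatch, 1e-3)
})

test_that("stenosed-tube drop sits in the Bernoulli-Poiseuille bracket", {
  # study-shaped geometry (61% CSA reduction over 45 mm) at 5.5 L/min; 24
  # cells/diameter is the coarsest grid inside the solver's asymptotic range
  # for this quantity
  fluid <- fluid_properties()
  g <- case_graft(make_case(2), "AS2")
  raster <- rasterize(g, 24L)
  q <- lpm_to_m3s(5.5)
  cfg <- sim_config(flow_rate_lpm = 5.5, resolution = 24L,
                    sampling_time = 0.3, n_samples = 30L)
  s <- simulate_flow(raster, fluid, cfg)
  # time-averaged inlet-column pressure versus the outlet reference
  p_tavg <- apply(s$p, c(1, 2), mean)
  w <- raster$r_centers[seq_len(raster$np[1])]
  drop <- sum(p_tavg[1, seq_len(raster$np[1])] * w) / sum(w) - mmhg_to_pa(100)
  br <- pressure_drop_bracket(g, fluid, q)
  expect_gt(drop, br$lower_pa / 2)
  expect_lt(drop, br$upper_pa * 2)
  expect_lt(check_mass_conservation(s)$flux_mismatch, 1e-3)
})

test_that("pressure-drop components scale as alpha (viscous) and ~alpha^2 (convective)", {
  fluid <- fluid_properties()
  inlet_drop <- function(geom, q, res = 12L) {
    raster <- rasterize(geom, res)
    cfg <- sim_config(flow_rate_lpm = m3s_to_lpm(q), resolution = res,
                      sampling_time = 0.05, n_samples = 5L)
    s <- simulate_flow(raster, fluid, cfg)
    p_tavg <- apply(s$p, c(1, 2), mean)
    w <- raster$r_centers[seq_len(raster$np[1])]
    sum(p_tavg[1, seq_len(raster$np[1])] * w) / sum(w) - mmhg_to_pa(100)
  }
  # viscous limit (Re 10 -> 20): drop doubles
  tube <- straight_tube(length = 6 * 0.0175)
  d1 <- inlet_drop(tube, flow_for_re(10))
  d2 <- inlet_drop(tube, flow_for_re(20))
  expect_equal(d2 / d1, 2, tolerance = 0.15)
  # convective limit (Re 500 -> 1000) through a strong stenosis: ~quadruples
  g <- quick_stenosis(length = 0.05, reduction = 0.6)
  c1 <- inlet_drop(g, flow_for_re(500))
  c2 <- inlet_drop(g, flow_for_re(1000))
  expect_gt(c2 / c1, 2.7)
  expect_lt(c2 / c1, 4.8)
})

test_that("shifting the outlet reference leaves the velocity field unchanged", {
  fluid <- fluid_properties()
  g <- quick_stenosis(length = 0.05, reduction = 0.4)
  raster <- rasterize(g, 12L)
  base <- list(flow_rate_lpm = 3.5, resolution = 12L, washout_time = 0.1,
               sampling_time = 0.05, n_samples = 5L)
  s1 <- simulate_flow(raster, fluid, do.call(sim_config, c(base, outlet_pressure_mmhg = 100)))
  s2 <- simulate_flow(raster, fluid, do.call(sim_config, c(base, outlet_pressure_mmhg = 0)))
  expect_equal(s1$u, s2$u, tolerance = 1e-12)
  expect_equal(s1$v, s2$v, tolerance = 1e-12)
  expect_equal(s1$p - mmhg_to_pa(100), s2$p - mmhg_to_pa(0), tolerance = 1e-9)
})

test_that("planar mode reproduces plane-Poiseuille flow", {
  fluid <- fluid_properties()
  d <- 0.0175
  ch <- build_graft(stenosis_spec(0.05, 0.03, pi * (d / 2)^2 * (1 - 1e-9), 0),
                    d, 0.1, mode_hint = "planar")
  raster <- rasterize(ch, 16L)
  # Re ~ 40 channel flow; inlet_flow interpreted per metre depth
  q2 <- 40 * fluid$dynamic_viscosity / fluid$density   # m^2/s
  cfg <- sim_config(flow_rate_lpm = m3s_to_lpm(q2), resolution = 16L,
                    mode = "planar", sampling_time = 0.2, n_samples = 5L)
  s <- simulate_flow(raster, fluid, cfg)
  h <- raster$baseline_radius                # half-width
  umean <- q2 / h
  expect_equal(peak_velocity(s), 1.5 * umean, tolerance = 0.05)
  expect_lt(check_mass_conservation(s)$flux_mismatch, 1e-3)
})

test_that("mesh independence study reports shrinking differences", {
  fluid <- fluid_properties()
  tube <- straight_tube(length = 6 * 0.0175)
  cfg <- sim_config(flow_rate_lpm = m3s_to_lpm(flow_for_re(100)),
                    sampling_time = 0.05, n_samples = 5L)
  tab <- mesh_independence_study(tube, fluid, cfg, resolutions = c(8L, 12L, 16L))
  expect_equal(nrow(tab), 3L)
  expect_true(is.na(tab$diff_prev_mmHg[1]))
  expect_true(all(tab$diff_prev_mmHg[-1] >= 0))
  expect_lt(tab$diff_prev_mmHg[3], tab$diff_prev_mmHg[2])
  expect_error(mesh_independence_study(tube, fluid, cfg, resolutions = c(16L, 16L)),
               "increasing|length")
})

test_that("solver rejects mismatched modes and reports failures cleanly", {
  raster <- rasterize(straight_tube(), 16L)
  cfg <- sim_config(mode = "planar", resolution = 16L)
  expect_error(simulate_flow(raster, fluid_properties(), cfg), "mode")
})
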