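# Parametric stenosed-graft geometry: narrowest-CSA targeting, stepwise
# augmentation, area profiles, and rasterization.

test_that("build_graft reaches reported narrowest-CSA targets", {
  # severity pairs: (narrowest mm^2, % reduction) imply the baseline area
  d175 <- 0.0175
  base <- pi * (d175 / 2)^2                      # ~240.5 mm^2
  g <- build_graft(stenosis_spec(0.03, 0.045, 173e-6, 1), d175, 0.09)
  amin <- narrowest_csa(g)
  expect_lt(abs(amin - 173e-6) / 173e-6, 0.005)
  expect_equal(percent_csa_reduction(amin * 1e6, base * 1e6), 28)

  g2 <- build_graft(stenosis_spec(0.03, 0.045, 93e-6, 1), d175, 0.09)
  expect_equal(percent_csa_reduction(narrowest_csa(g2) * 1e6, 240.5), 61)

  # zero-extent compression limit: an unstenosed tube has a flat profile
  tube <- straight_tube()
  prof <- csa_profile(tube, 101L)
  expect_lt(diff(range(prof$area_m2)) / max(prof$area_m2), 1e-8)
})

test_that("build_graft rejects impossible targets", {
  d <- 0.0175
  base <- pi * (d / 2)^2
  expect_error(build_graft(stenosis_spec(0.03, 0.045, base * 1.1, 1), d, 0.09),
               "smaller than the baseline")
  expect_error(build_graft(stenosis_spec(0.03, 0.1, 100e-6, 1), d, 0.09),
               "axial extent")
})

test_that("compression profile is smooth, localized and non-negative", {
  g <- build_graft(stenosis_spec(0.03, 0.045, 120e-6, 1), 0.0175, 0.09)
  s <- seq(0, 0.09, by = 1e-4)
  delta <- graft_compression(g, s)
  expect_true(all(delta >= 0))
  expect_true(all(delta[s < 0.0075 | s > 0.0525] == 0))
  # continuity: no jump larger than expected for a C1 bump
  expect_lt(max(abs(diff(delta))), g$stenosis$delta_max * pi * 1e-4 / 0.045 * 1.01)
  # area never exceeds baseline
  expect_true(all(graft_area(g, s) <= pi * g$baseline_radius^2 + 1e-15))
})

test_that("augment_stenosis scales displacement and preserves surroundings", {
  g <- build_graft(stenosis_spec(0.03, 0.045, 165e-6, 1), 0.0175, 0.09)
  expect_identical(augment_stenosis(g, 1), g)    # exact identity

  g2 <- augment_stenosis(g, 1.4)
  s <- seq(0, 0.09, by = 5e-4)
  expect_equal(graft_compression(g2, s), 1.4 * graft_compression(g, s))
  outside <- s[s < 0.0075 | s > 0.0525]
  expect_equal(graft_area(g2, outside), graft_area(g, outside))
  # narrowest point stays at the bump centre
  prof <- csa_profile(g2, 901L)
  expect_lt(abs(prof$station_m[which.min(prof$area_m2)] - 0.03), 2e-4)

  expect_error(augment_stenosis(g, 50), "occlude")
  expect_error(augment_stenosis(g, 0.5), "severity_factor")
})

test_that("augmentation to a target CSA verifies by fine-sampled area scan", {
  fx <- make_case(2)
  os <- case_graft(fx, "OS")
  f <- severity_factor_for_csa(os, 93e-6)
  as2 <- augment_stenosis(os, f)
  # independent oracle: brute-force scan at 10x the usual station density
  s_fine <- seq(1e-6, fx$length - 1e-6, length.out = 4010L)
  amin_scan <- min(graft_area(as2, s_fine))
  expect_lt(abs(amin_scan - 93e-6) / 93e-6, 0.005)
})

test_that("augmentation severity is monotone in the factor", {
  g <- build_graft(stenosis_spec(0.03, 0.045, 170e-6, 1), 0.0175, 0.09)
  factors <- c(1, 1.2, 1.5, 1.9, 2.4)
  mins <- vapply(factors, function(f) narrowest_csa(augment_stenosis(g, f)),
                 numeric(1))
  expect_true(all(diff(mins) < 0))
})

test_that("csa_profile converges with station refinement", {
  g <- build_graft(stenosis_spec(0.03, 0.045, 130e-6, 1), 0.0175, 0.09)
  m1 <- min(csa_profile(g, 200L)$area_m2)
  m2 <- min(csa_profile(g, 400L)$area_m2)
  expect_lt(abs(m2 - m1) / m1, 0.001)
  tube <- straight_tube()
  expect_equal(csa_profile(tube, 50L)$area_m2,
               rep(pi * 0.00875^2 * (1 - 1e-9), 50L), tolerance = 1e-9)
})

test_that("percent_csa_reduction matches reported pairs and guards input", {
  expect_equal(percent_csa_reduction(173, 240.3), 28)
  expect_equal(percent_csa_reduction(93, 238.5), 61)
  expect_equal(percent_csa_reduction(42, 42), 0)
  expect_error(percent_csa_reduction(10, 0), "positive")
  expect_error(percent_csa_reduction(-1, 10))
  expect_error(percent_csa_reduction(11, 10))
})

test_that("eccentric sections: quadrature agrees with the closed form", {
  a <- 0.00875
  for (e in c(0.3, 0.7, 1)) {
    for (delta in c(0.1, 0.5, 1, 1.4) * a) {
      expect_equal(section_area(a, delta, e, method = "quadrature"),
                   section_area(a, delta, e, method = "closed"),
                   tolerance = 1e-7)
    }
  }
  # eccentric and concentric geometries targeted at the same narrowest CSA
  # have the same minimum area (CSA, not shape, is the severity variable)
  g_ecc <- build_graft(stenosis_spec(0.03, 0.045, 130e-6, 1), 0.0175, 0.09)
  g_con <- build_graft(stenosis_spec(0.03, 0.045, 130e-6, 0), 0.0175, 0.09)
  expect_equal(narrowest_csa(g_ecc), narrowest_csa(g_con), tolerance = 1e-6)
})

test_that("rasterize produces a wall mask within one cell of the lumen", {
  tube <- straight_tube()
  r16 <- rasterize(tube, 16L)
  expect_true(all(r16$np == r16$np[1]))          # constant width mask
  expect_identical(r16$nr, r16$np[1])

  g <- case_graft(make_case(1), "OS")
  r32 <- rasterize(g, 32L)
  r_analytic <- equivalent_radius(g, r32$z_centers)
  expect_true(all(abs(r32$np * r32$dr - r_analytic) <= r32$dr))
  # sub-cell ghost wall representation recovers the analytic area closely
  rc <- raster_csa(r32)
  expect_lt(max(abs(rc$area_m2 - graft_area(g, rc$station_m)) /
                  graft_area(g, rc$station_m)), 0.02)

  # refinement does not grow the mask wall-position error
  err <- vapply(c(16L, 32L, 64L), function(res) {
    r <- rasterize(g, res)
    max(abs(r$np * r$dr - equivalent_radius(g, r$z_centers)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_error(rasterize(g, 6L), "at least 8")
  # throat narrower than 4 cells across is rejected
  tiny <- build_graft(stenosis_spec(0.03, 0.045, 8e-6, 0), 0.0175, 0.09)
  expect_error(rasterize(tiny, 8L), "coarse")
})

test_that("geometry exports are well-formed", {
  g <- case_graft(make_case(1), "AS1")
  tf <- tempfile(fileext = ".csv")
  write_csa_csv(csa_profile(g, 40L), tf)
  df <- read.csv(tf)
  expect_named(df, c("station_m", "area_mm2"))
  expect_equal(nrow(df), 40L)
  expect_true(all(diff(df$station_m) > 0))

  stl_a <- tempfile(fileext = ".stl")
  write_stl(g, stl_a, n_axial = 20L, n_theta = 12L)
  lines <- readLines(stl_a)
  expect_match(lines[1], "^solid")
  expect_equal(sum(grepl("facet normal", lines)), 2L * 19L * 12L)

  stl_b <- tempfile(fileext = ".stl")
  write_stl(g, stl_b, n_axial = 20L, n_theta = 12L, ascii = FALSE)
  expect_equal(file.size(stl_b), 84 + 50 * 2 * 19 * 12)
})
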