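# Configuration, report assembly and field/surface export.

run_config_defaults <- function() {
  list(
    case = 1L,
    geometry = list(
      baseline_diameter_mm = NULL,   # NULL = back-computed from the case table
      length_mm = 90,
      stenosis_center_mm = 30,
      stenosis_extent_mm = 45,
      eccentricity = 1),
    solver = list(
      resolution = 32L,
      cfl = 0.4,
      washout_time = NULL,
      sampling_time = 1.0,
      n_samples = 200L,
      mode = "axisymmetric",
      beta_upwind = 0.15,
      poisson_tol = 1e-6,
      steady_tol = 1e-6),
    metrics = list(
      plane_count = 10L,
      plane_spacing_mm = 5,
      peak_velocity_mode = "mean"),
    flows_lpm = c(3.5, 4.5, 5.5),
    reference_pressure_mmhg = 100,
    output_dir = "results",
    seed = 1L,
    log_level = "info")
}

#' Load a run configuration from YAML
#'
#' Fills defaults for missing keys and rejects unknown keys by name;
#' schema violations are collected and reported together, not one at a
#' time. Flows are converted to SI on load.
#'
#' @param path YAML file; top-level keys `case`, `geometry`, `solver`,
#'   `metrics`, `flows_lpm`, `reference_pressure_mmhg`, `output_dir`,
#'   `seed`, `log_level`
#' @return object of class `run_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- run_config_defaults()
  problems <- character()

  unknown <- setdiff(names(user), names(defaults))
  for (k in unknown) problems <- c(problems, paste0("unknown key: ", k))
  for (section in c("geometry", "solver", "metrics")) {
    if (!is.null(user[[section]])) {
      bad <- setdiff(names(user[[section]]), names(defaults[[section]]))
      for (k in bad) problems <- c(problems, paste0("unknown key: ", section, ".", k))
    }
  }

  cfg <- utils::modifyList(defaults, user[intersect(names(user), names(defaults))])

  if (!cfg$case %in% c(1L, 2L)) problems <- c(problems, "case must be 1 or 2")
  if (!all(cfg$flows_lpm > 0)) problems <- c(problems, "flows_lpm must be positive")
  if (cfg$solver$resolution < 8) problems <- c(problems, "solver.resolution must be >= 8")
  if (cfg$solver$sampling_time <= 0) problems <- c(problems, "solver.sampling_time must be > 0")
  if (!cfg$solver$mode %in% c("axisymmetric", "planar")) {
    problems <- c(problems, "solver.mode must be axisymmetric or planar")
  }
  if (cfg$metrics$plane_count < 1) problems <- c(problems, "metrics.plane_count must be >= 1")
  if (length(problems) > 0) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }

  cfg$flows_m3s <- lpm_to_m3s(cfg$flows_lpm)
  cfg$reference_pressure_pa <- mmhg_to_pa(cfg$reference_pressure_mmhg)
  structure(cfg, class = "run_config")
}

#' Content hash of a configuration (or any R object)
#'
#' MD5 of the serialized object; stamped into every report file so a run
#' can be tied back to its archived configuration.
#'
#' @param x any serializable object
#' @return 32-character hex string
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  writeBin(serialize(x, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  df <- as.data.frame(df)   # plain columns: tibble format() pretty-prints
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the sweep report
#'
#' Writes the tidy per-cell results CSV, the correlation CSV, the
#' per-plane pressure-profile CSV, and summary plots (plane-pressure
#' profile along the graft, gradient versus narrowest CSA and flow, and
#' the gradient-versus-peak-velocity / gradient-versus-TKE scatter
#' panels). Every CSV carries the configuration hash in a leading comment
#' line; reruns on identical inputs produce byte-identical CSVs.
#'
#' @param sweep a [run_sweep()] result
#' @param correlations a [correlation_panel()] table (or `NULL` to compute
#'   it from the sweep, if complete)
#' @param out_dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report <- function(sweep, correlations = NULL, out_dir = "results") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(fixture = sweep$fixture, config = sweep$config))
  if (is.null(correlations) && !any(sweep$table$failed) && nrow(sweep$table) >= 3) {
    correlations <- correlation_panel(sweep)
  }

  paths <- character()
  p1 <- file.path(out_dir, sprintf("case%d_sweep.csv", sweep$case_id))
  write_stamped_csv(sweep$table[, setdiff(names(sweep$table), "error")], p1, hash)
  paths <- c(paths, p1)

  prof <- dplyr::bind_rows(lapply(names(sweep$summaries), function(lbl) {
    s <- sweep$summaries[[lbl]]
    if (is.null(s)) return(NULL)
    cbind(cell = lbl, s$plane_pressures)
  }))
  p2 <- file.path(out_dir, sprintf("case%d_plane_pressures.csv", sweep$case_id))
  write_stamped_csv(prof, p2, hash)
  paths <- c(paths, p2)

  if (!is.null(correlations)) {
    p3 <- file.path(out_dir, sprintf("case%d_correlations.csv", sweep$case_id))
    write_stamped_csv(correlations, p3, hash)
    paths <- c(paths, p3)
  }

  # plots (layout, not data of record; exempt from byte-identity)
  tab <- sweep$table
  cap <- paste0("config ", substr(hash, 1, 8))
  pp <- file.path(out_dir, sprintf("case%d_report.pdf", sweep$case_id))
  grDevices::pdf(pp, width = 7, height = 5, onefile = TRUE)
  tryCatch({
    if (nrow(prof) > 0) {
      prof$flow <- sub(".*_", "", prof$cell)
      prof$severity <- sub("_.*", "", prof$cell)
      print(ggplot2::ggplot(prof,
              ggplot2::aes(x = 1e3 * station_m, y = mean_pressure_mmhg,
                           colour = severity, linetype = flow)) +
            ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
            ggplot2::labs(x = "axial position (mm)", y = "plane mean pressure (mmHg)",
                          title = sprintf("Case %d plane-pressure profiles", sweep$case_id),
                          caption = cap))
    }
    print(ggplot2::ggplot(tab, ggplot2::aes(x = csa_mm2, y = gradient_mmHg,
                                            colour = factor(flow_lpm))) +
          ggplot2::geom_line() + ggplot2::geom_point() +
          ggplot2::labs(x = "narrowest CSA (mm^2)", y = "pressure gradient (mmHg)",
                        colour = "flow (L/min)", caption = cap))
    print(ggplot2::ggplot(tab, ggplot2::aes(x = peak_velocity_ms, y = gradient_mmHg,
                                            shape = severity, colour = factor(flow_lpm))) +
          ggplot2::geom_point(size = 2) +
          ggplot2::labs(x = "peak velocity (m/s)", y = "pressure gradient (mmHg)",
                        colour = "flow (L/min)", caption = cap))
    print(ggplot2::ggplot(tab, ggplot2::aes(x = tke_mJ, y = gradient_mmHg,
                                            shape = severity, colour = factor(flow_lpm))) +
          ggplot2::geom_point(size = 2) +
          ggplot2::labs(x = "TKE (mJ)", y = "pressure gradient (mmHg)",
                        colour = "flow (L/min)", caption = cap))
  }, finally = grDevices::dev.off())
  paths <- c(paths, pp)
  invisible(paths)
}

#' Export a sampled flow field as a legacy-ASCII VTK rectilinear grid
#'
#' Writes cell data (pressure in mmHg, cell-centred velocity components,
#' fluid mask) for one sampled instant so standard viewers can render the
#' fields. Axisymmetric fields are written on the r-z half-plane.
#'
#' @param series a `flow_field_series`
#' @param path output `.vtk` file
#' @param sample index of the sampled instant (default last)
#' @export
write_vtk <- function(series, path, sample = length(series$times)) {
  raster <- series$raster
  nz <- raster$nz; nr <- raster$nr
  cc <- cell_velocity(series)
  p <- series$p[, , sample]
  uz <- cc$uz[, , sample]; ur <- cc$ur[, , sample]
  fluid <- outer(raster$np, seq_len(nr), ">=")
  con <- file(path, open = "wt")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 9)
  writeLines(c("# vtk DataFile Version 3.0",
               "stenoflow field export", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", nz + 1L, nr + 1L),
               sprintf("X_COORDINATES %d float", nz + 1L),
               paste(num((0:nz) * raster$dz), collapse = " "),
               sprintf("Y_COORDINATES %d float", nr + 1L),
               paste(num((0:nr) * raster$dr), collapse = " "),
               "Z_COORDINATES 1 float", "0",
               sprintf("CELL_DATA %d", nz * nr)), con)
  scalar <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s float 1", name), "LOOKUP_TABLE default",
                 paste(num(as.vector(m)), collapse = " ")), con)
  }
  scalar("pressure_mmHg", pa_to_mmhg(p))
  scalar("velocity_z", uz)
  scalar("velocity_r", ur)
  scalar("fluid_mask", fluid + 0)
  invisible(path)
}

#' Export a graft surface as STL
#'
#' Revolves the axisymmetric-equivalent radius profile into a triangulated
#' tube surface (open ends). A finite `curvature_radius` bends the
#' centreline in the x-z plane. Both ASCII and binary STL are supported.
#'
#' @param geom a `graft_geometry`
#' @param path output `.stl` file
#' @param n_axial axial sampling stations
#' @param n_theta circumferential facets
#' @param ascii write ASCII STL (default); `FALSE` writes binary
#' @export
write_stl <- function(geom, path, n_axial = 120L, n_theta = 48L, ascii = TRUE) {
  s <- seq(0, geom$length, length.out = n_axial)
  rad <- equivalent_radius(geom, pmin(pmax(s, 1e-9), geom$length - 1e-9))
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  ring <- function(k) {
    z <- s[k]; r <- rad[k]
    if (is.finite(geom$curvature_radius)) {
      rc <- geom$curvature_radius
      phi <- z / rc
      cx <- rc * (1 - cos(phi)); cz <- rc * sin(phi)
      # local frame: tangent in x-z plane, normal toward the bend centre
      nx <- cos(phi); nz <- -sin(phi)
      cbind(cx + r * cos(th) * nx, r * sin(th), cz + r * cos(th) * nz)
    } else {
      cbind(r * cos(th), r * sin(th), z)
    }
  }
  verts <- lapply(seq_len(n_axial), ring)
  tri <- list()
  for (k in seq_len(n_axial - 1L)) {
    a <- verts[[k]]; b <- verts[[k + 1L]]
    for (t in seq_len(n_theta)) {
      t2 <- if (t == n_theta) 1L else t + 1L
      tri[[length(tri) + 1L]] <- rbind(a[t, ], b[t, ], b[t2, ])
      tri[[length(tri) + 1L]] <- rbind(a[t, ], b[t2, ], a[t2, ])
    }
  }
  normal <- function(v) {
    n <- c(
      (v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) - (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
      (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) - (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
      (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) - (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1]))
    l <- sqrt(sum(n^2))
    if (l > 0) n / l else c(0, 0, 1)
  }
  if (ascii) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("solid graft", con)
    for (v in tri) {
      n <- normal(v)
      writeLines(c(sprintf("  facet normal %e %e %e", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %e %e %e", v[, 1], v[, 2], v[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid graft", con)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(length(tri)), con, size = 4, endian = "little")
    for (v in tri) {
      writeBin(as.numeric(c(normal(v), t(v))), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Run the analytic oracle validation suite
#'
#' Exercises the solver and metrics against closed-form references:
#' steady Poiseuille flow (centreline velocity and pressure slope),
#' discrete mass conservation, the TKE identity on a constant field, the
#' sinusoidal-fluctuation RMS, and the Pearson product-moment formula.
#'
#' @param resolution grid resolution for the Poiseuille check
#' @param quick use a shorter, coarser Poiseuille run
#' @return tibble: check, value, reference, rel_error, pass
#' @export
validate_solver <- function(resolution = 32L, quick = FALSE) {
  checks <- list()
  fluid <- fluid_properties()

  # Poiseuille: low-Re straight tube
  d <- 0.0175; len <- if (quick) 6 * d else 10 * d
  q_lam <- 50 * pi * d * fluid$dynamic_viscosity / (4 * fluid$density)  # Re = 50
  tube <- build_graft(stenosis_spec(len / 2, len / 4, pi * (d / 2)^2 * (1 - 1e-9), 0),
                      d, len)
  raster <- rasterize(tube, resolution)
  # washout defaults to 3 pass-through times; at Re 50 the run reaches the
  # steady-state detector long before that and skips ahead
  cfg <- sim_config(flow_rate_lpm = m3s_to_lpm(q_lam), resolution = resolution,
                    sampling_time = 0.5, n_samples = 20L)
  series <- simulate_flow(raster, fluid, cfg)
  vmean <- q_lam / (pi * (d / 2)^2)
  vpeak <- peak_velocity(series)
  checks$poiseuille_centreline <- c(vpeak, 2 * vmean)
  planes <- place_planes(csa_profile(tube, 101L), count = 6L, spacing = len / 12)
  pp <- plane_mean_pressure(series, planes)
  dev <- pp[pp$station_m > 0.5 * len, ]
  slope <- stats::coef(stats::lm(mean_pressure_mmhg ~ station_m, dev))[2]
  slope_ref <- pa_to_mmhg(-8 * fluid$dynamic_viscosity * q_lam / (pi * (d / 2)^4))
  checks$poiseuille_dp <- c(unname(slope), slope_ref)
  mc <- check_mass_conservation(series)
  checks$mass_flux_mismatch <- c(mc$flux_mismatch, 0)

  # TKE identity + sinusoidal RMS on fixtures
  sin_fix <- make_field_fixture("sinusoidal", raster, fluid,
                                params = list(amplitude = 0.5), n_samples = 1000L)
  rs <- reynolds_stats(sin_fix, fluid)
  checks$sinusoid_rms <- c(max(rs$up), 0.5 / sqrt(2))
  tke_err <- max(abs(rs$tke_density -
                       0.5 * fluid$density * (rs$up^2 + rs$vp^2 + rs$wp^2)))
  checks$tke_identity <- c(tke_err, 0)

  # Pearson against the hand formula
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  pt <- pearson_test(x, y)
  checks$pearson_R <- c(pt$R, 0.6)

  ref0 <- function(v, r) if (r == 0) abs(v) else abs(v - r) / abs(r)
  tibble::tibble(
    check = names(checks),
    value = vapply(checks, `[`, numeric(1), 1),
    reference = vapply(checks, `[`, numeric(1), 2),
    rel_error = mapply(function(c) ref0(c[1], c[2]), checks),
    pass = mapply(function(nm, c) {
      tol <- switch(nm, poiseuille_centreline = 0.02, poiseuille_dp = 0.02,
                    mass_flux_mismatch = 1e-3, sinusoid_rms = 1e-3,
                    tke_identity = 1e-9, pearson_R = 1e-12)
      ref0(c[1], c[2]) <= tol || (c[2] == 0 && abs(c[1]) <= tol)
    }, names(checks), checks))
}
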