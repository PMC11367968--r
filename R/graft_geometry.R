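#' Specify a localized extrinsic stenosis
#'
#' Describes the compression applied to an otherwise uniform outflow graft:
#' where it sits, how long it is, how narrow the lumen becomes at its
#' narrowest point, and how one-sided the compression is. Extrinsic
#' obstruction (material between graft and bend relief) pushes the wall in
#' from outside, typically from one side; `eccentricity` interpolates
#' between a concentric radial squeeze (0) and a fully one-sided flattening
#' of the section (1).
#'
#' @param center_position axial position of the narrowest point, m from the
#'   graft inlet
#' @param axial_extent length of the compressed segment, m
#' @param target_narrowest_csa lumen cross-sectional area at the narrowest
#'   point, m^2
#' @param eccentricity fraction in `[0, 1]` of the compression applied from
#'   one side; 0 = concentric
#' @return an object of class `stenosis_spec`
#' @export
stenosis_spec <- function(center_position, axial_extent, target_narrowest_csa,
                          eccentricity = 1) {
  stopifnot(
    is.numeric(center_position), length(center_position) == 1L, center_position > 0,
    is.numeric(axial_extent), length(axial_extent) == 1L, axial_extent > 0,
    is.numeric(target_narrowest_csa), length(target_narrowest_csa) == 1L,
    target_narrowest_csa > 0,
    is.numeric(eccentricity), length(eccentricity) == 1L,
    eccentricity >= 0, eccentricity <= 1
  )
  structure(
    list(
      center_position = center_position,
      axial_extent = axial_extent,
      target_narrowest_csa = target_narrowest_csa,
      eccentricity = eccentricity
    ),
    class = "stenosis_spec"
  )
}

#' Cross-sectional area of a compressed circular section
#'
#' The deformed lumen section is modelled as a disc of baseline radius `a`
#' shrunk concentrically by the concentric share of the wall displacement
#' and clipped by a chord for the one-sided share: with total inward
#' displacement `delta` and eccentricity `e`, the disc radius becomes
#' `a - (1 - e) * delta` and a chord removes everything beyond distance
#' `a - (1 - e) * delta - e * delta` from the centre on one side.
#'
#' @param baseline_radius undeformed lumen radius, m
#' @param delta total inward wall displacement, m (scalar or vector)
#' @param eccentricity one-sided fraction in `[0, 1]`
#' @param method `"closed"` for the closed-form circular-segment area,
#'   `"quadrature"` for numerical integration of the section width (the
#'   independent route used for eccentric sections in [csa_profile()])
#' @return area(s) in m^2; 0 indicates a fully occluded section
#' @export
section_area <- function(baseline_radius, delta, eccentricity = 1,
                         method = c("closed", "quadrature")) {
  method <- match.arg(method)
  a <- baseline_radius
  stopifnot(a > 0, all(delta >= 0))
  e <- eccentricity
  a2 <- a - (1 - e) * delta       # concentrically shrunk radius
  d0 <- a2 - e * delta            # chord offset from centre
  one <- function(a2i, d0i) {
    if (a2i <= 0 || d0i <= -a2i) return(0)
    if (d0i >= a2i) return(pi * a2i^2)
    if (method == "closed") {
      seg <- a2i^2 * acos(d0i / a2i) - d0i * sqrt(a2i^2 - d0i^2)
      pi * a2i^2 - seg
    } else {
      # integrate the chord width across the retained part of the section
      stats::integrate(function(x) 2 * sqrt(pmax(a2i^2 - x^2, 0)),
                       lower = -a2i, upper = d0i,
                       rel.tol = 1e-10, subdivisions = 500L)$value
    }
  }
  vapply(seq_along(a2), function(k) one(a2[k], d0[k]), numeric(1))
}

# Inward displacement needed so the deformed section area equals `target`.
solve_displacement <- function(baseline_radius, target_area, eccentricity) {
  a <- baseline_radius
  if (eccentricity == 0) return(a - sqrt(target_area / pi))
  # occlusion at delta_max: concentric part closes at a/(1-e), chord part at
  # the delta where d0 reaches -a2
  upper <- if (eccentricity < 1) a / (1 - eccentricity) else 2 * a
  f <- function(d) section_area(a, d, eccentricity) - target_area
  stats::uniroot(f, lower = 0, upper = upper * (1 - 1e-9), tol = 1e-14)$root
}

#' Build a parametric stenosed-graft geometry
#'
#' Constructs a straight (or gently curved) tube of uniform baseline radius
#' carrying one localized extrinsic compression. The compression profile is
#' a smooth cosine-squared bump over the stenotic extent: it is continuously
#' differentiable, vanishes outside the segment, and peaks at the centre,
#' where the lumen area equals the requested narrowest cross-sectional area.
#'
#' @param spec a [stenosis_spec()]
#' @param baseline_diameter undeformed lumen diameter, m
#' @param length axial extent of the modelled graft segment, m
#' @param curvature_radius centreline radius of curvature, m (`Inf` =
#'   straight; used for surface export only — the flow solver treats the
#'   tube as straight)
#' @param mode_hint `"axisymmetric"` or `"planar"`, the solver mode the
#'   geometry is intended for
#' @return an object of class `graft_geometry`
#' @export
build_graft <- function(spec, baseline_diameter, length,
                        curvature_radius = Inf,
                        mode_hint = c("axisymmetric", "planar")) {
  mode_hint <- match.arg(mode_hint)
  stopifnot(inherits(spec, "stenosis_spec"),
            baseline_diameter > 0, length > 0)
  a <- baseline_diameter / 2
  base_area <- pi * a^2
  if (spec$target_narrowest_csa >= base_area) {
    stop("target narrowest CSA (", spec$target_narrowest_csa,
         " m^2) must be smaller than the baseline area (", base_area, " m^2)")
  }
  if (spec$axial_extent >= length) {
    stop("stenosis axial extent must be smaller than the graft length")
  }
  delta_max <- solve_displacement(a, spec$target_narrowest_csa, spec$eccentricity)
  geom <- structure(
    list(
      length = length,
      baseline_radius = a,
      stenosis = list(
        center = spec$center_position,
        extent = spec$axial_extent,
        delta_max = delta_max,
        eccentricity = spec$eccentricity
      ),
      curvature_radius = curvature_radius,
      mode_hint = mode_hint
    ),
    class = "graft_geometry"
  )
  validate_graft(geom)
  geom
}

validate_graft <- function(geom) {
  st <- geom$stenosis
  a2 <- geom$baseline_radius - (1 - st$eccentricity) * st$delta_max
  d0 <- a2 - st$eccentricity * st$delta_max
  if (a2 <= 0 || d0 <= -a2) {
    stop("compression would occlude the lumen (displacement ",
         signif(st$delta_max, 4), " m on radius ",
         signif(geom$baseline_radius, 4), " m)")
  }
  invisible(geom)
}

#' Baseline lumen radius at axial stations
#' @param geom a `graft_geometry`
#' @param s axial positions, m from the inlet
#' @return radii in m
#' @export
graft_radius <- function(geom, s) {
  rep_len(geom$baseline_radius, length(s))
}

#' Inward wall displacement of the extrinsic compression at axial stations
#'
#' Cosine-squared bump: `delta_max * cos(pi * (s - center) / extent)^2`
#' inside `|s - center| <= extent / 2`, zero outside.
#'
#' @inheritParams graft_radius
#' @return displacements in m (`>= 0`, 0 outside the stenotic segment)
#' @export
graft_compression <- function(geom, s) {
  st <- geom$stenosis
  x <- (s - st$center) / st$extent
  delta <- st$delta_max * cos(pi * x)^2
  delta[abs(x) > 0.5] <- 0
  delta
}

#' Lumen cross-sectional area at axial stations
#'
#' Concentric sections use the closed-form `pi * r^2`; eccentric sections
#' are integrated numerically across the deformed section.
#'
#' @inheritParams graft_radius
#' @export
graft_area <- function(geom, s) {
  delta <- graft_compression(geom, s)
  e <- geom$stenosis$eccentricity
  method <- if (e == 0) "closed" else "quadrature"
  section_area(geom$baseline_radius, delta, e, method = method)
}

#' Axisymmetric-equivalent lumen radius at axial stations
#'
#' Radius of the concentric section with the same area as the (possibly
#' eccentric) deformed section; severity is carried by CSA, not section
#' shape, so this is the profile the axisymmetric solver runs on.
#'
#' @inheritParams graft_radius
#' @export
equivalent_radius <- function(geom, s) {
  sqrt(graft_area(geom, s) / pi)
}

#' Cross-sectional-area profile along the graft
#'
#' Areas are evaluated at `n_stations` cell centres spanning the graft; the
#' minimum over stations converges to the narrowest CSA as `n_stations`
#' grows (the bump peaks mid-segment, so convergence is quadratic).
#'
#' @param geom a `graft_geometry`
#' @param n_stations number of evenly spaced stations (cell centres), >= 2
#' @return a `tibble` of class `csa_profile` with columns `station_m`,
#'   `area_m2`
#' @export
csa_profile <- function(geom, n_stations = 201L) {
  stopifnot(n_stations >= 2L)
  s <- (seq_len(n_stations) - 0.5) * geom$length / n_stations
  areas <- graft_area(geom, s)
  if (any(areas <= 0)) stop("geometry is occluded at some station")
  structure(
    tibble::tibble(station_m = s, area_m2 = areas),
    class = c("csa_profile", class(tibble::tibble()))
  )
}

#' Narrowest cross-sectional area of a geometry
#'
#' Scans the area profile and polishes the minimum with golden-section
#' refinement around the narrowest sampled station.
#'
#' @inheritParams csa_profile
#' @return narrowest area, m^2
#' @export
narrowest_csa <- function(geom, n_stations = 401L) {
  prof <- csa_profile(geom, n_stations)
  k <- which.min(prof$area_m2)
  lo <- prof$station_m[max(1L, k - 1L)]
  hi <- prof$station_m[min(nrow(prof), k + 1L)]
  if (lo == hi) return(prof$area_m2[k])
  stats::optimize(function(s) graft_area(geom, s),
                  interval = c(lo, hi), tol = 1e-12)$objective
}

#' Percent cross-sectional-area reduction
#'
#' `100 * (1 - narrowest / baseline)`, rounded half-up to the nearest
#' integer for reporting.
#'
#' @param narrowest narrowest CSA (any area unit)
#' @param baseline unstenosed CSA, same unit
#' @return integer percent reduction
#' @export
percent_csa_reduction <- function(narrowest, baseline) {
  if (any(baseline <= 0)) stop("baseline area must be positive")
  if (any(narrowest <= 0) || any(narrowest > baseline * (1 + 1e-12))) {
    stop("narrowest area must lie in (0, baseline]")
  }
  round_half_up(100 * (1 - narrowest / baseline))
}

#' Stepwise linear stenosis augmentation
#'
#' Scales the compression displacement pointwise by `severity_factor`,
#' emulating virtual stepwise linear deformation of the stenosed surface.
#' Stations outside the stenotic segment are untouched and the narrowest
#' point stays where it was.
#'
#' @param geom a `graft_geometry`
#' @param severity_factor dimensionless scale `>= 1`
#' @return a new `graft_geometry`
#' @export
augment_stenosis <- function(geom, severity_factor) {
  stopifnot(inherits(geom, "graft_geometry"),
            is.numeric(severity_factor), length(severity_factor) == 1L,
            severity_factor >= 1)
  if (severity_factor == 1) return(geom)
  out <- geom
  out$stenosis$delta_max <- geom$stenosis$delta_max * severity_factor
  validate_graft(out)
  if (min(graft_area(out, out$stenosis$center)) <= 0) {
    stop("augmentation would occlude the lumen")
  }
  out
}

#' Severity factor that reaches a target narrowest CSA
#'
#' Inverts [augment_stenosis()]: finds the displacement scale that makes
#' the narrowest cross-sectional area equal `target_csa`.
#'
#' @param geom a `graft_geometry` (the original stenosis)
#' @param target_csa desired narrowest CSA, m^2 (must be <= current)
#' @return severity factor `>= 1`
#' @export
severity_factor_for_csa <- function(geom, target_csa) {
  cur <- graft_area(geom, geom$stenosis$center)
  if (target_csa > cur + 1e-15) {
    stop("target CSA exceeds the current narrowest CSA; augmentation only narrows")
  }
  st <- geom$stenosis
  a <- geom$baseline_radius
  d_target <- solve_displacement(a, target_csa, st$eccentricity)
  d_target / st$delta_max
}

#' Rasterize a graft geometry onto the solver grid
#'
#' Produces the structured axisymmetric (r-z) or planar-symmetric (y-z)
#' grid the flow solver runs on: uniform spacing `baseline_diameter /
#' resolution` in both directions, a per-column fluid-cell count (the wall
#' mask, within one cell of the analytic lumen radius), and the sub-cell
#' wall gap used by the solver's ghost-cell no-slip condition, which places
#' the wall at the analytic radius rather than the nearest cell face.
#' Eccentric geometries are mapped to the concentric section of equal area.
#'
#' @param geom a `graft_geometry`
#' @param resolution cells per baseline diameter, >= 8
#' @return an object of class `graft_raster`
#' @export
rasterize <- function(geom, resolution = 32L) {
  stopifnot(inherits(geom, "graft_geometry"))
  if (resolution < 8) stop("resolution must be at least 8 cells per diameter")
  a <- geom$baseline_radius
  dr <- 2 * a / resolution
  nr <- as.integer(round(a / dr))        # wall of the unstenosed tube on a face
  nz <- max(4L, as.integer(round(geom$length / dr)))
  dz <- geom$length / nz
  zc <- (seq_len(nz) - 0.5) * dz         # pressure-cell centres
  zf <- (0:nz) * dz                      # axial-velocity faces
  # axisymmetric: concentric section of equal area; planar: the half-channel
  # width with the compression applied to the mirrored wall
  wall_at <- function(s) {
    if (geom$mode_hint == "axisymmetric") equivalent_radius(geom, s)
    else graft_radius(geom, s) - graft_compression(geom, s)
  }
  r_wall_c <- wall_at(zc)
  r_wall_f <- wall_at(pmin(pmax(zf, zc[1]), zc[nz]))
  np <- pmin(as.integer(floor(r_wall_c / dr + 1e-6)), nr)
  if (any(np < 2L)) {
    stop("resolution too coarse: fewer than 4 cells across the narrowest lumen")
  }
  nu <- pmin(as.integer(floor(r_wall_f / dr + 1e-6)), nr)
  nu <- pmin(nu, c(np[1], pmin(np[-nz], np[-1]), np[nz]))
  # sub-cell gap between the top fluid node and the wall, clamped to
  # [0.5, 1.5] dr so the ghost-cell coefficient stays bounded
  hu <- pmin(pmax(r_wall_f - (nu - 0.5) * dr, 0.5 * dr), 1.5 * dr)
  hp <- pmin(pmax(r_wall_c - (np - 0.5) * dr, 0.5 * dr), 1.5 * dr)
  structure(
    list(
      nz = nz, nr = nr, dz = dz, dr = dr,
      z_centers = zc, r_centers = (seq_len(nr) - 0.5) * dr,
      np = np, nu = nu, hu = hu, hp = hp,
      r_wall = r_wall_c,
      resolution = resolution,
      mode = geom$mode_hint,
      baseline_radius = a,
      length = geom$length,
      geom = geom
    ),
    class = "graft_raster"
  )
}

#' Cross-sectional areas represented by a raster
#'
#' Area per pressure column as enforced by the discrete no-slip condition:
#' the wall sits at the sub-cell position `(np - 0.5) * dr + hp` the
#' ghost-cell scheme uses, not at the nearest cell face. In planar mode the
#' value is the half-channel open width (area per unit depth).
#'
#' @param raster a `graft_raster`
#' @return a `csa_profile` tibble
#' @export
raster_csa <- function(raster) {
  r_eff <- (raster$np - 0.5) * raster$dr + raster$hp
  area <- if (raster$mode == "axisymmetric") pi * r_eff^2 else r_eff
  structure(
    tibble::tibble(station_m = raster$z_centers, area_m2 = area),
    class = c("csa_profile", class(tibble::tibble()))
  )
}

#' @export
print.graft_geometry <- function(x, ...) {
  st <- x$stenosis
  amin <- narrowest_csa(x)
  cat("graft_geometry:",
      sprintf("L = %.1f mm, baseline d = %.2f mm (%.1f mm^2)",
              1e3 * x$length, 2e3 * x$baseline_radius,
              1e6 * pi * x$baseline_radius^2), "\n")
  cat(sprintf("  stenosis: centre %.1f mm, extent %.1f mm, ecc %.2f, narrowest CSA %.1f mm^2 (%d%% reduction)\n",
              1e3 * st$center, 1e3 * st$extent, st$eccentricity, 1e6 * amin,
              percent_csa_reduction(amin, pi * x$baseline_radius^2)))
  invisible(x)
}

#' @export
print.graft_raster <- function(x, ...) {
  cat(sprintf("graft_raster (%s): %d x %d cells, h = %.3f mm, throat %d cells across\n",
              x$mode, x$nz, x$nr, 1e3 * x$dr, 2L * min(x$np)))
  invisible(x)
}

#' Write a cross-sectional-area profile as CSV
#'
#' Columns `station_m` and `area_mm2`.
#'
#' @param profile a `csa_profile`
#' @param path output file
#' @export
write_csa_csv <- function(profile, path) {
  df <- data.frame(station_m = profile$station_m,
                   area_mm2 = 1e6 * profile$area_m2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
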