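#' Place cross-sectional measurement planes over the stenotic segment
#'
#' Ten planes 5 mm apart (by default) centred on the narrowest station of
#' the cross-sectional-area profile, mirroring how pressure is profiled
#' across a graft stenosis. If no stenotic segment is identifiable (all
#' areas within 1% of the widest), the planes are centred on the domain
#' midpoint. If the symmetric span would leave the domain, the plane set
#' is shifted inward; a span longer than the domain is an error.
#'
#' @param csa a [csa_profile()]
#' @param count number of planes
#' @param spacing plane spacing, m
#' @return object of class `plane_set` (tibble with `plane`, `station_m`)
#' @export
place_planes <- function(csa, count = 10L, spacing = 5e-3) {
  stopifnot(inherits(csa, "csa_profile"), count >= 1, spacing > 0)
  s <- csa$station_m; a <- csa$area_m2
  length_dom <- max(s) + s[1]            # stations are cell centres on (0, L)
  baseline <- max(a)
  center <- if (min(a) < baseline * 0.99) s[which.min(a)] else length_dom / 2
  offsets <- (seq_len(count) - (count + 1) / 2) * spacing
  span <- max(offsets) - min(offsets)
  if (span >= length_dom) {
    stop("plane span (", signif(span, 3), " m) exceeds the domain length (",
         signif(length_dom, 3), " m)")
  }
  pos <- center + offsets
  margin <- min(s)
  if (min(pos) < margin) pos <- pos + (margin - min(pos))
  if (max(pos) > length_dom - margin) pos <- pos - (max(pos) - (length_dom - margin))
  structure(
    tibble::tibble(plane = seq_len(count), station_m = pos),
    spacing = spacing, center = center,
    class = c("plane_set", class(tibble::tibble())))
}

#' Per-plane time-averaged mean pressure
#'
#' For each plane: area-weighted spatial mean of pressure over the lumen
#' cells of the nearest cell layer, then a uniform time average over all
#' sampled instants. Reported in mmHg.
#'
#' @param series a `flow_field_series`
#' @param planes a [place_planes()] result
#' @return tibble: `plane`, `station_m`, `mean_pressure_mmhg`
#' @export
plane_mean_pressure <- function(series, planes) {
  raster <- series$raster
  w <- if (raster$mode == "axisymmetric") raster$r_centers else rep(1, raster$nr)
  p_tavg <- apply(series$p, c(1, 2), mean)       # nz x nr, Pa
  out <- vapply(planes$station_m, function(z) {
    if (z < 0 || z > raster$length) stop("plane at ", z, " m lies outside the domain")
    i <- which.min(abs(raster$z_centers - z))
    jmax <- raster$np[i]
    if (jmax < 1L) stop("plane at ", z, " m has no lumen cells")
    sum(p_tavg[i, 1:jmax] * w[1:jmax]) / sum(w[1:jmax])
  }, numeric(1))
  tibble::tibble(plane = planes$plane, station_m = planes$station_m,
                 mean_pressure_mmhg = pa_to_mmhg(out))
}

#' Pressure gradient over the stenotic segment
#'
#' Difference between the maximum plane-averaged mean pressure and the
#' aortic reference pressure.
#'
#' @param plane_pressures_mmhg per-plane mean pressures, mmHg
#' @param reference_mmhg aortic reference, mmHg (default 100)
#' @return pressure gradient, mmHg
#' @export
pressure_gradient <- function(plane_pressures_mmhg, reference_mmhg = 100) {
  stopifnot(length(plane_pressures_mmhg) > 0)
  max(plane_pressures_mmhg) - reference_mmhg
}

#' Peak velocity in the graft
#'
#' Default (`"mean"`): maximum over lumen cells of the time-averaged
#' velocity magnitude, matching how mean velocity-magnitude fields are
#' displayed and read. `"instant"`: maximum over all cells and sampled
#' instants.
#'
#' @param series a `flow_field_series`
#' @param mode `"mean"` or `"instant"`
#' @return peak velocity, m/s
#' @export
peak_velocity <- function(series, mode = c("mean", "instant")) {
  mode <- match.arg(mode)
  cc <- cell_velocity(series)
  w2 <- if (!is.null(series$w)) series$w^2 else 0
  mag <- sqrt(cc$uz^2 + cc$ur^2 + w2)
  if (mode == "mean") max(apply(mag, c(1, 2), mean)) else max(mag)
}

#' Reynolds-decomposed velocity statistics
#'
#' Splits each sampled velocity component into its time mean and a
#' fluctuating part; the fluctuation strength is the root mean square of
#' the instantaneous minus mean signal (`1/N` normalization), and the
#' turbulent-kinetic-energy density is
#' `0.5 * rho * (u'^2 + v'^2 + w'^2)`. The axisymmetric solver carries no
#' azimuthal component, so `w' = 0` unless the series provides one (as the
#' synthetic field fixtures do).
#'
#' @param series a `flow_field_series` with at least 2 samples
#' @param fluid a [fluid_properties()]
#' @return object of class `reynolds_stats`: per-cell matrices `mean_uz`,
#'   `mean_ur`, `mean_w`, `up`, `vp`, `wp`, `tke_density` (J/m^3), and `n`
#' @export
reynolds_stats <- function(series, fluid) {
  n <- length(series$times)
  if (n < 2) stop("Reynolds decomposition needs at least 2 samples")
  cc <- cell_velocity(series)
  wz <- if (!is.null(series$w)) series$w else array(0, dim = dim(cc$uz))
  stat1 <- function(x) {
    m <- apply(x, c(1, 2), mean)
    rms <- sqrt(apply((x - array(m, dim = dim(x)))^2, c(1, 2), mean))
    list(mean = m, rms = rms)
  }
  su <- stat1(cc$uz); sv <- stat1(cc$ur); sw <- stat1(wz)
  structure(
    list(mean_uz = su$mean, mean_ur = sv$mean, mean_w = sw$mean,
         up = su$rms, vp = sv$rms, wp = sw$rms,
         tke_density = 0.5 * fluid$density *
           (su$rms^2 + sv$rms^2 + sw$rms^2),
         n = n),
    class = "reynolds_stats")
}

#' Volume-integrated turbulent kinetic energy
#'
#' Integrates the TKE density over the lumen and reports millijoules.
#'
#' @param tke_density per-cell TKE density, J/m^3 (nz x nr)
#' @param volumes matching cell volumes, m^3 (solid cells 0; see
#'   [cell_volumes()])
#' @return integrated TKE, mJ
#' @export
integrate_tke <- function(tke_density, volumes) {
  stopifnot(all(dim(tke_density) == dim(volumes)))
  1000 * sum(tke_density * volumes)
}

#' Haemodynamic summary of one simulated condition
#'
#' Bundles the per-plane pressure profile, the pressure gradient, the peak
#' velocity, and the lumen-integrated turbulent kinetic energy for one
#' (severity, flow) condition.
#'
#' @param series a `flow_field_series`
#' @param planes optional [place_planes()] result; default places planes
#'   from the raster's area profile
#' @param reference_mmhg aortic reference pressure, mmHg
#' @param peak_mode passed to [peak_velocity()]
#' @return object of class `haemodynamic_summary`
#' @export
summarize_haemodynamics <- function(series, planes = NULL,
                                    reference_mmhg = 100,
                                    peak_mode = "mean") {
  if (is.null(planes)) planes <- place_planes(raster_csa(series$raster))
  pp <- plane_mean_pressure(series, planes)
  rs <- reynolds_stats(series, series$fluid)
  structure(
    list(plane_pressures = pp,
         pressure_gradient_mmhg = pressure_gradient(pp$mean_pressure_mmhg,
                                                    reference_mmhg),
         peak_velocity_ms = peak_velocity(series, peak_mode),
         integrated_tke_mj = integrate_tke(rs$tke_density,
                                           cell_volumes(series$raster)),
         reynolds = rs,
         reference_mmhg = reference_mmhg),
    class = "haemodynamic_summary")
}

#' @export
print.haemodynamic_summary <- function(x, ...) {
  cat(sprintf("haemodynamic_summary: gradient %.3f mmHg, peak velocity %.3f m/s, TKE %.3g mJ\n",
              x$pressure_gradient_mmhg, x$peak_velocity_ms, x$integrated_tke_mj))
  invisible(x)
}
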