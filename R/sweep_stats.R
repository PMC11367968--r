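#' Enumerate the severity-by-flow simulation grid
#'
#' Lists every (case, severity, flow) condition of a sweep without running
#' anything: two cases at three severities and three device flows
#' enumerate 18 simulation configurations.
#'
#' @param fixtures list of [make_case()] fixtures
#' @param severities character vector of severities
#' @param flows_lpm device flows, L/min
#' @return tibble: case, severity, csa_mm2, flow_lpm
#' @export
enumerate_sweep <- function(fixtures,
                            severities = c("OS", "AS1", "AS2"),
                            flows_lpm = c(3.5, 4.5, 5.5)) {
  rows <- lapply(fixtures, function(fx) {
    grid <- expand.grid(severity = severities, flow_lpm = flows_lpm,
                        stringsAsFactors = FALSE)
    tibble::tibble(case = fx$case_id,
                   severity = grid$severity,
                   csa_mm2 = unname(fx$target_csa_mm2[grid$severity]),
                   flow_lpm = grid$flow_lpm)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$case, out$flow_lpm, match(out$severity, severities)), ]
}

sweep_cache_key <- function(fixture, severity, flow_lpm, config) {
  payload <- list(fixture = fixture, severity = severity,
                  flow = flow_lpm, config = config)
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  writeBin(serialize(payload, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

#' Run a severity-by-flow sweep for one case
#'
#' Simulates every (severity, flow) cell of a case fixture with the
#' desk-scale solver and summarizes each with
#' [summarize_haemodynamics()]. Deterministic given the configuration;
#' completed cells can be cached on disk keyed by a content hash of the
#' inputs. A failing cell is reported in the result (with `failed = TRUE`
#' and the error message), never silently dropped.
#'
#' @param fixture a [make_case()] fixture
#' @param severities subset of `c("OS", "AS1", "AS2")`
#' @param flows_lpm device flows to run, L/min
#' @param config a [sim_config()] template; the flow rate is overridden
#'   per cell
#' @param cache_dir optional directory for content-hash caching of cell
#'   results (`NULL` disables)
#' @param planes optional fixed [place_planes()] set; default derives the
#'   planes from the OS geometry so all severities share one plane set
#' @return object of class `sweep_result`: tidy `table` (one row per
#'   cell) and the per-cell `summaries`
#' @export
run_sweep <- function(fixture,
                      severities = c("OS", "AS1", "AS2"),
                      flows_lpm = c(3.5, 4.5, 5.5),
                      config = sim_config(),
                      cache_dir = NULL,
                      planes = NULL) {
  stopifnot(inherits(fixture, "case_fixture"), all(flows_lpm > 0))
  fluid <- fluid_properties()
  if (is.null(planes)) {
    planes <- place_planes(csa_profile(case_graft(fixture, "OS"), 301L))
  }
  rows <- list(); summaries <- list()
  for (sev in severities) {
    geom <- case_graft(fixture, sev)
    raster <- rasterize(geom, config$resolution)
    for (fl in flows_lpm) {
      cfg <- config
      cfg$flow_rate_lpm <- fl
      cfg$inlet_flow_m3s <- lpm_to_m3s(fl)
      key <- paste0("cell-", sweep_cache_key(fixture, sev, fl, cfg), ".rds")
      cell <- NULL
      if (!is.null(cache_dir) && file.exists(file.path(cache_dir, key))) {
        cell <- readRDS(file.path(cache_dir, key))
      }
      if (is.null(cell)) {
        cell <- tryCatch({
          series <- simulate_flow(raster, fluid, cfg)
          s <- summarize_haemodynamics(series, planes = planes,
                                       reference_mmhg = cfg$outlet_pressure_mmhg)
          s$reynolds <- NULL  # keep cells small; stats live in the summary numbers
          list(summary = s, failed = FALSE, error = NA_character_)
        }, error = function(e) {
          list(summary = NULL, failed = TRUE, error = conditionMessage(e))
        })
        if (!is.null(cache_dir)) {
          dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
          saveRDS(cell, file.path(cache_dir, key))
        }
      }
      lbl <- paste(sev, fl, sep = "_")
      summaries[[lbl]] <- cell$summary
      rows[[lbl]] <- tibble::tibble(
        case = fixture$case_id, severity = sev,
        csa_mm2 = unname(fixture$target_csa_mm2[[sev]]),
        flow_lpm = fl,
        gradient_mmHg = if (cell$failed) NA_real_ else cell$summary$pressure_gradient_mmhg,
        peak_velocity_ms = if (cell$failed) NA_real_ else cell$summary$peak_velocity_ms,
        tke_mJ = if (cell$failed) NA_real_ else cell$summary$integrated_tke_mj,
        failed = cell$failed, error = cell$error)
    }
  }
  structure(list(case_id = fixture$case_id, fixture = fixture,
                 table = dplyr::bind_rows(rows), summaries = summaries,
                 config = config, planes = planes),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result case %d: %d cells (%d failed)\n",
              x$case_id, nrow(x$table), sum(x$table$failed)))
  print(x$table[, c("severity", "csa_mm2", "flow_lpm", "gradient_mmHg",
                    "peak_velocity_ms", "tke_mJ")])
  invisible(x)
}

#' Pearson correlation with small-sample p-value
#'
#' Product-moment correlation with a two-sided p-value from the exact
#' small-sample reference distribution under normality (the t-transform
#' `t = R sqrt(n-2) / sqrt(1-R^2)` with `n - 2` degrees of freedom), as
#' implemented by [stats::cor.test]. Significance at alpha = 0.05.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @param pair optional label for the variable pair
#' @return one-row tibble: pair, R, p, n, significant
#' @export
pearson_test <- function(x, y, pair = "x~y") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in at least one variable")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(pair = pair,
                 R = unname(ct$estimate),
                 p = ct$p.value,
                 n = length(x),
                 significant = ct$p.value < 0.05)
}

#' Correlation panel over a completed sweep
#'
#' Pools the nine (severity, flow) cells of a case and correlates each
#' haemodynamic quantity (pressure gradient, peak velocity, TKE) against
#' stenotic severity — encoded both as narrowest CSA in mm^2 (negative R
#' means the quantity rises as the lumen narrows) and as ordinal severity
#' rank (OS = 1, AS1 = 2, AS2 = 3) — and against device flow. Adds the
#' gradient-versus-peak-velocity and gradient-versus-TKE panels.
#'
#' @param sweep a complete [run_sweep()] result
#' @return tibble of [pearson_test()] rows
#' @export
correlation_panel <- function(sweep) {
  tab <- sweep$table
  if (any(tab$failed)) stop("sweep has failed cells; correlation panel needs a complete sweep")
  if (nrow(tab) < 3) stop("correlation panel needs at least 3 cells")
  rank <- match(tab$severity, c("OS", "AS1", "AS2"))
  pairs <- list(
    gradient_vs_csa = list(tab$gradient_mmHg, tab$csa_mm2),
    gradient_vs_severity_rank = list(tab$gradient_mmHg, rank),
    gradient_vs_flow = list(tab$gradient_mmHg, tab$flow_lpm),
    peak_velocity_vs_csa = list(tab$peak_velocity_ms, tab$csa_mm2),
    peak_velocity_vs_severity_rank = list(tab$peak_velocity_ms, rank),
    peak_velocity_vs_flow = list(tab$peak_velocity_ms, tab$flow_lpm),
    tke_vs_csa = list(tab$tke_mJ, tab$csa_mm2),
    tke_vs_severity_rank = list(tab$tke_mJ, rank),
    tke_vs_flow = list(tab$tke_mJ, tab$flow_lpm),
    gradient_vs_peak_velocity = list(tab$gradient_mmHg, tab$peak_velocity_ms),
    gradient_vs_tke = list(tab$gradient_mmHg, tab$tke_mJ))
  out <- lapply(names(pairs), function(nm) {
    xy <- pairs[[nm]]
    tryCatch(pearson_test(xy[[1]], xy[[2]], pair = nm),
             error = function(e) tibble::tibble(pair = nm, R = NA_real_,
                                                p = NA_real_, n = length(xy[[1]]),
                                                significant = NA))
  })
  dplyr::bind_rows(out)
}
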