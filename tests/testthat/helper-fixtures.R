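# Shared builders for small, fast test problems.

# straight (effectively unstenosed) tube: target area 1 - 1e-9 of baseline
straight_tube <- function(d = 0.0175, length = 10 * d) {
  build_graft(stenosis_spec(length / 2, length / 4, pi * (d / 2)^2 * (1 - 1e-9), 0),
              d, length)
}

# short mildly stenosed tube for quick solver exercises
quick_stenosis <- function(d = 0.0175, length = 0.05, reduction = 0.4,
                           eccentricity = 0) {
  build_graft(stenosis_spec(length / 2, length / 2.5,
                            pi * (d / 2)^2 * (1 - reduction), eccentricity),
              d, length)
}

# flow rate giving a prescribed Reynolds number in a tube of diameter d
flow_for_re <- function(re, d = 0.0175, fluid = fluid_properties()) {
  re * pi * d * fluid$dynamic_viscosity / (4 * fluid$density)
}

# short sampling window, no steadiness shortcut disabled (detector on)
quick_config <- function(flow_lpm, resolution = 16L, ...) {
  sim_config(flow_rate_lpm = flow_lpm, resolution = resolution,
             sampling_time = 0.1, n_samples = 10L, ...)
}
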