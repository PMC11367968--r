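#' Unit conversion constants and helpers
#'
#' Pressures are carried in pascal internally and reported in mmHg;
#' flows are specified in L/min and converted to m^3/s at the boundary.
#' Fixed conversion factors: 1 mmHg = 133.322 Pa, 1 L/min = 1/60000 m^3/s.
#'
#' @name units
NULL

#' @rdname units
#' @export
PA_PER_MMHG <- 133.322

#' @rdname units
#' @param mmhg pressure in millimetres of mercury
#' @export
mmhg_to_pa <- function(mmhg) mmhg * PA_PER_MMHG

#' @rdname units
#' @param pa pressure in pascal
#' @export
pa_to_mmhg <- function(pa) pa / PA_PER_MMHG

#' @rdname units
#' @param lpm volumetric flow in litres per minute
#' @export
lpm_to_m3s <- function(lpm) lpm / 60000

#' @rdname units
#' @param m3s volumetric flow in cubic metres per second
#' @export
m3s_to_lpm <- function(m3s) m3s * 60000

#' Round half away from zero
#'
#' Integer rounding used for all reported percentages. `base::round`
#' rounds half to even; radiological percentages are conventionally
#' rounded half-up (23.53 -> 24, 17.89 -> 18).
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
round_half_up <- function(x) {
  floor(abs(x) + 0.5) * sign(x)
}
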