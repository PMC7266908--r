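#' Nuclide decay constants
#'
#' Physical half-life and the matching decay constant for the radionuclide
#' whose activity the time-activity curves describe. The decay constant is
#' always derived as `log(2) / half-life` so the two fields cannot drift
#' apart.
#'
#' @param physical_half_life_h Physical half-life in hours (> 0).
#'
#' @return A one-row tibble with columns `physical_half_life_h` and
#'   `physical_decay_constant_per_h`.
#' @export
#' @examples
#' nuclide_constants(159.46)
nuclide_constants <- function(physical_half_life_h) {
  if (!is.numeric(physical_half_life_h) || length(physical_half_life_h) != 1L ||
      !is.finite(physical_half_life_h) || physical_half_life_h <= 0) {
    abort("`physical_half_life_h` must be a single positive finite number.")
  }
  tibble(
    physical_half_life_h = physical_half_life_h,
    physical_decay_constant_per_h = log(2) / physical_half_life_h
  )
}

#' Lutetium-177 constants
#'
#' Evaluated-nuclear-data physical half-life of 177Lu, 6.6443 days
#' (159.4632 h). Used as the default tail cap for composite time-activity
#' curves and for trapezoid-plus-physical-decay integration.
#'
#' @return A one-row tibble, see [nuclide_constants()].
#' @export
#' @examples
#' lu177_constants()
lu177_constants <- function() {
  nuclide_constants(6.6443 * 24)
}
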