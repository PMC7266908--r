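#' Biologically effective dose from an initial dose rate
#'
#' Linear-quadratic BED for an exponentially decaying dose-rate curve
#' \eqn{R(t) = R_0 e^{-\lambda_e t}} with sublethal-damage repair at rate
#' \eqn{\mu}:
#' \deqn{BED = \frac{R_0}{\lambda_e}\left[1 +
#'   \frac{R_0}{(\mu + \lambda_e)(\alpha/\beta)}\right]}
#' The first factor is the absorbed dose \eqn{D = R_0/\lambda_e}; the
#' bracket inflates it by the dose-rate-dependent quadratic cell-kill term.
#' Defaults are the kidney literature values \eqn{\mu = 0.248\,h^{-1}},
#' \eqn{\alpha/\beta = 2.6} Gy.
#'
#' @param r0_gy_per_h Initial dose rate (Gy/h, >= 0).
#' @param lambda_e_per_h Target-specific effective decay constant (/h, > 0),
#'   typically the terminal rate of the kidney TAC fit.
#' @param mu_per_h Sublethal damage repair rate (/h).
#' @param alpha_beta_gy Linear-quadratic tissue ratio (Gy).
#' @return One-row tibble: `bed_gy`, `dose_gy`, `r0_gy_per_h`,
#'   `lambda_e_per_h`, `mu_per_h`, `alpha_beta_gy`.
#' @export
#' @examples
#' bed_from_rate(0.1, 0.01)
bed_from_rate <- function(r0_gy_per_h, lambda_e_per_h,
                          mu_per_h = 0.248, alpha_beta_gy = 2.6) {
  if (any(r0_gy_per_h < 0)) abort("`r0_gy_per_h` must be non-negative.")
  if (any(lambda_e_per_h <= 0)) abort("`lambda_e_per_h` must be positive.")
  if (any(mu_per_h <= 0) || any(alpha_beta_gy <= 0)) {
    abort("`mu_per_h` and `alpha_beta_gy` must be positive.")
  }
  d <- r0_gy_per_h / lambda_e_per_h
  bed <- d * (1 + r0_gy_per_h / ((mu_per_h + lambda_e_per_h) * alpha_beta_gy))
  tibble(
    bed_gy = bed, dose_gy = d, r0_gy_per_h = r0_gy_per_h,
    lambda_e_per_h = lambda_e_per_h, mu_per_h = mu_per_h,
    alpha_beta_gy = alpha_beta_gy
  )
}

#' Biologically effective dose from an absorbed dose
#'
#' Dose-first parameterisation of [bed_from_rate()]: the initial dose rate
#' is recovered as \eqn{R_0 = D \lambda_e} and the same closed form
#' applied.
#'
#' @param dose_gy Absorbed dose (Gy, >= 0).
#' @inheritParams bed_from_rate
#' @return As [bed_from_rate()].
#' @export
#' @examples
#' bed_from_dose(6.75, log(2) / 96)
bed_from_dose <- function(dose_gy, lambda_e_per_h,
                          mu_per_h = 0.248, alpha_beta_gy = 2.6) {
  if (any(dose_gy < 0)) abort("`dose_gy` must be non-negative.")
  bed_from_rate(dose_gy * lambda_e_per_h, lambda_e_per_h,
                mu_per_h = mu_per_h, alpha_beta_gy = alpha_beta_gy)
}

#' Kidney cycle planning against a cumulative BED limit
#'
#' Scales the per-cycle kidney BED to the planned number of cycles and
#' tests it against the cumulative limit (default 27 Gy over 4 cycles,
#' i.e. a per-cycle threshold of 6.75 Gy). A cumulative BED exactly at the
#' limit is compliant.
#'
#' @param per_cycle_bed_gy Kidney BED of one therapy cycle (Gy, >= 0).
#' @param limit_gy Cumulative BED limit (Gy), default 27.
#' @param planned_cycles Planned number of cycles, default 4.
#' @return One-row tibble: `per_cycle_bed_gy`, `planned_cycles`,
#'   `cumulative_bed_gy`, `limit_gy`, `per_cycle_threshold_gy`, `exceeds`,
#'   `max_allowed_cycles` (`Inf` when the per-cycle BED is 0).
#' @export
#' @examples
#' plan_cycles(6.75)
#' plan_cycles(6.9)
plan_cycles <- function(per_cycle_bed_gy, limit_gy = 27, planned_cycles = 4L) {
  if (any(per_cycle_bed_gy < 0) || limit_gy < 0 || planned_cycles < 0) {
    abort("Inputs must be non-negative.")
  }
  cumulative <- per_cycle_bed_gy * planned_cycles
  tibble(
    per_cycle_bed_gy = per_cycle_bed_gy,
    planned_cycles = as.integer(planned_cycles),
    cumulative_bed_gy = cumulative,
    limit_gy = limit_gy,
    per_cycle_threshold_gy = limit_gy / planned_cycles,
    exceeds = cumulative > limit_gy,
    max_allowed_cycles = ifelse(per_cycle_bed_gy == 0, Inf,
                                floor(limit_gy / per_cycle_bed_gy))
  )
}
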