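#' Build the vendor-style composite time-activity curve
#'
#' Assembles the four-step piecewise curve used by hybrid dosimetry
#' software: (I) extrapolation of the first sample to `t = 0` according to
#' the start mode, (II) linear (trapezoidal) bridging between samples up to
#' the first fit point, (III) the fitted model between the first fit point
#' and the last sample, and (IV) an exponential tail from the fitted value
#' at the last sample. The tail decays with the fitted effective decay
#' constant unless the effective half-life exceeds the nuclide's physical
#' half-life, in which case the physical decay constant is used (the tail
#' cap).
#'
#' @param fit A [fit_tac()] result.
#' @param first_fit_time Hours; must equal one of the sample times and not
#'   exceed the last. Default: the first sample time, so the trapezoid
#'   segment is empty.
#' @param nuclide A [nuclide_constants()] row; default 177Lu.
#' @param start_mode Override of the fit's stored start mode.
#'
#' @return A `piecewise_curve`: contiguous segments from 0 (tibble with
#'   `t_start`, `t_end`, `form`, `params`), the tail decay constant, and a
#'   `capped` flag.
#' @export
#' @examples
#' tac <- tibble::tibble(time_h = c(0.5, 4, 24, 72),
#'                       activity_mbq = 100 * exp(-0.02 * c(0.5, 4, 24, 72)))
#' pw <- compose_hybrid_curve(fit_tac(tac, "mono"))
#' integrate_tia(pw, horizon_h = Inf)
compose_hybrid_curve <- function(fit, first_fit_time = NULL,
                                 nuclide = lu177_constants(),
                                 start_mode = NULL) {
  stopifnot(inherits(fit, "tac_fit"))
  start_mode <- start_mode %||% fit$start_mode
  t <- fit$data$time_h
  a <- fit$data$activity_mbq
  n <- length(t)
  fft <- first_fit_time %||% t[1]
  if (!any(abs(fft - t) < 1e-12)) abort("`first_fit_time` must equal one of the sample times.")
  if (fft > t[n]) abort("`first_fit_time` must not exceed the last sample time.")

  segs <- list()
  add <- function(t0, t1, form, params) {
    if (t1 > t0) segs[[length(segs) + 1L]] <<- tibble(
      t_start = t0, t_end = t1, form = form, params = list(params)
    )
  }

  # (I) extrapolation to t = 0
  if (t[1] > 0) {
    switch(start_mode,
      line = add(0, t[1], "const", list(value = a[1])),
      origin = add(0, t[1], "linear", list(t0 = 0, t1 = t[1], v0 = 0, v1 = a[1])),
      continue = add(0, t[1], "expsum", c(model_expsum(fit), list(t_ref = 0)))
    )
  }
  # (II) trapezoid bridging up to the first fit point
  k <- which(abs(t - fft) < 1e-12)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      add(t[i], t[i + 1], "linear",
          list(t0 = t[i], t1 = t[i + 1], v0 = a[i], v1 = a[i + 1]))
    }
  }
  # (III) fitted model
  add(fft, t[n], "expsum", c(model_expsum(fit), list(t_ref = 0)))
  # (IV) capped exponential tail
  lam_phys <- nuclide$physical_decay_constant_per_h
  capped <- fit$lambda_e < lam_phys
  lam_tail <- max(fit$lambda_e, lam_phys)
  a_last <- eval_tac_model(fit, t[n])
  segs[[length(segs) + 1L]] <- tibble(
    t_start = t[n], t_end = Inf, form = "expsum",
    params = list(list(A = a_last, lambda = lam_tail, t_ref = t[n]))
  )

  structure(
    list(
      segments = dplyr::bind_rows(segs),
      tail_decay_constant_per_h = lam_tail,
      capped = capped,
      physical_decay_constant_per_h = lam_phys
    ),
    class = "piecewise_curve"
  )
}

#' @export
print.piecewise_curve <- function(x, ...) {
  cat("<piecewise_curve> ", nrow(x$segments), " segments, tail lambda = ",
      signif(x$tail_decay_constant_per_h, 6), " /h",
      if (x$capped) " (capped at physical decay)", "\n", sep = "")
  print(x$segments[c("t_start", "t_end", "form")])
  invisible(x)
}

#' Evaluate a composite curve
#'
#' @param pw A [compose_hybrid_curve()] result.
#' @param times_h Times (hours, >= 0) at which to evaluate.
#' @return Activities (MBq) at `times_h`.
#' @export
eval_curve <- function(pw, times_h) {
  stopifnot(inherits(pw, "piecewise_curve"))
  vapply(times_h, function(tt) {
    i <- which(pw$segments$t_start <= tt & tt <= pw$segments$t_end)[1]
    if (is.na(i)) return(NA_real_)
    seg_value(pw$segments$form[i], pw$segments$params[[i]], tt)
  }, numeric(1))
}

seg_value <- function(form, p, tt) {
  switch(form,
    const = p$value,
    linear = p$v0 + (p$v1 - p$v0) * (tt - p$t0) / (p$t1 - p$t0),
    expsum = sum(p$A * exp(-p$lambda * (tt - p$t_ref)))
  )
}

seg_integral <- function(form, p, a, b) {
  if (b <= a) return(0)
  switch(form,
    const = p$value * (b - a),
    linear = {
      va <- seg_value("linear", p, a)
      vb <- seg_value("linear", p, b)
      (va + vb) / 2 * (b - a)
    },
    expsum = {
      upper <- if (is.infinite(b)) 0 else exp(-p$lambda * (b - p$t_ref))
      sum(p$A / p$lambda * (exp(-p$lambda * (a - p$t_ref)) - upper))
    }
  )
}

#' Time-integrated activity of a composite curve
#'
#' Integrates each segment in closed form (exact trapezoids for linear
#' pieces, \eqn{A/\lambda (e^{-\lambda a} - e^{-\lambda b})} for exponential
#' pieces) up to the requested horizon. The two horizons used by commercial
#' systems — 2400 h and infinity — are both first-class.
#'
#' @param pw A [compose_hybrid_curve()] result (or the curve built
#'   internally by [trapezoid_physical_decay_tia()]).
#' @param horizon_h Upper integration limit in hours, or `Inf`.
#' @param method Tag recorded in the result.
#' @return One-row tibble: `tia_mbq_h`, `horizon_h`, `method`.
#' @export
integrate_tia <- function(pw, horizon_h = Inf, method = "hybrid_piecewise") {
  stopifnot(inherits(pw, "piecewise_curve"))
  if (!is.numeric(horizon_h) || length(horizon_h) != 1L || is.na(horizon_h) || horizon_h < 0) {
    abort("`horizon_h` must be a single non-negative number (or Inf).")
  }
  segs <- pw$segments
  total <- 0
  for (i in seq_len(nrow(segs))) {
    a <- segs$t_start[i]
    b <- min(segs$t_end[i], horizon_h)
    if (b > a) total <- total + seg_integral(segs$form[i], segs$params[[i]], a, b)
  }
  tibble(tia_mbq_h = total, horizon_h = horizon_h, method = method)
}

#' Trapezoidal time-integrated activity with a physical-decay tail
#'
#' The model-free alternative to exponential fitting: trapezoidal
#' integration across the samples (after the configured `t = 0`
#' extrapolation) plus an analytic tail assuming pure physical decay from
#' the last measured value, \eqn{A(t_n)/\lambda_{phys}}.
#'
#' @param data TAC data frame (`time_h`, `activity_mbq`), >= 2 samples.
#' @param nuclide A [nuclide_constants()] row; default 177Lu.
#' @param start_mode `"line"` (constant at the first sample) or `"origin"`
#'   (linear ramp from (0,0)).
#' @param horizon_h Integration horizon, default infinity.
#' @return One-row tibble as [integrate_tia()].
#' @export
#' @examples
#' trapezoid_physical_decay_tia(
#'   tibble::tibble(time_h = c(24, 72), activity_mbq = c(100, 50))
#' )
trapezoid_physical_decay_tia <- function(data, nuclide = lu177_constants(),
                                         start_mode = c("line", "origin"),
                                         horizon_h = Inf) {
  start_mode <- match.arg(start_mode)
  data <- validate_tac(data, min_samples = 2L)
  t <- data$time_h; a <- data$activity_mbq; n <- length(t)
  lam_phys <- nuclide$physical_decay_constant_per_h

  segs <- list()
  if (t[1] > 0) {
    segs[[1]] <- if (start_mode == "line") {
      tibble(t_start = 0, t_end = t[1], form = "const", params = list(list(value = a[1])))
    } else {
      tibble(t_start = 0, t_end = t[1], form = "linear",
             params = list(list(t0 = 0, t1 = t[1], v0 = 0, v1 = a[1])))
    }
  }
  for (i in seq_len(n - 1)) {
    segs[[length(segs) + 1L]] <- tibble(
      t_start = t[i], t_end = t[i + 1], form = "linear",
      params = list(list(t0 = t[i], t1 = t[i + 1], v0 = a[i], v1 = a[i + 1]))
    )
  }
  segs[[length(segs) + 1L]] <- tibble(
    t_start = t[n], t_end = Inf, form = "expsum",
    params = list(list(A = a[n], lambda = lam_phys, t_ref = t[n]))
  )
  pw <- structure(
    list(segments = dplyr::bind_rows(segs),
         tail_decay_constant_per_h = lam_phys, capped = FALSE,
         physical_decay_constant_per_h = lam_phys),
    class = "piecewise_curve"
  )
  integrate_tia(pw, horizon_h, method = "trapezoid_physical_decay")
}

#' Single-time-point time-integrated activity
#'
#' Approximate TIA from one quantitative measurement, assuming
#' mono-exponential decay at a supplied effective decay constant: the curve
#' \eqn{A_0 e^{-\lambda_e t}} is back-extrapolated through the point, so
#' \eqn{\tilde A = A(t_s) e^{\lambda_e t_s} / \lambda_e}. Intended for
#' reduced-schedule protocols with a single late scan; the result is tagged
#' approximate.
#'
#' @param time_h Measurement time (> 0 h).
#' @param activity_mbq Measured activity (MBq, >= 0).
#' @param lambda_e_per_h Assumed effective decay constant (> 0 /h).
#' @return One-row tibble: `tia_mbq_h`, `horizon_h = Inf`,
#'   `method = "single_time_point"`, `approximate = TRUE`.
#' @export
#' @examples
#' single_time_point_tia(96, 10, log(2) / 96)
single_time_point_tia <- function(time_h, activity_mbq, lambda_e_per_h) {
  if (!is.numeric(time_h) || time_h <= 0) abort("`time_h` must be positive.")
  if (!is.numeric(lambda_e_per_h) || lambda_e_per_h <= 0) abort("`lambda_e_per_h` must be positive.")
  if (!is.numeric(activity_mbq) || activity_mbq < 0) abort("`activity_mbq` must be non-negative.")
  tibble(
    tia_mbq_h = activity_mbq * exp(lambda_e_per_h * time_h) / lambda_e_per_h,
    horizon_h = Inf,
    method = "single_time_point",
    approximate = TRUE
  )
}

#' Fit, compose and integrate in one call
#'
#' Convenience wrapper running [fit_tac()], [compose_hybrid_curve()] and
#' [integrate_tia()] and returning the fit diagnostics next to the TIA —
#' the unit of work the dosimetry pipeline performs per target.
#'
#' @inheritParams fit_tac
#' @inheritParams compose_hybrid_curve
#' @inheritParams integrate_tia
#' @return One-row tibble: fit diagnostics ([glance()] columns), `capped`,
#'   `tia_mbq_h`, `horizon_h`.
#' @export
estimate_tia <- function(data, model = "mono", start_mode = "line",
                         horizon_h = Inf, first_fit_time = NULL,
                         nuclide = lu177_constants(),
                         lambda_bounds = c(1e-6, 10)) {
  fit <- fit_tac(data, model = model, start_mode = start_mode,
                 lambda_bounds = lambda_bounds)
  pw <- compose_hybrid_curve(fit, first_fit_time = first_fit_time, nuclide = nuclide)
  res <- integrate_tia(pw, horizon_h)
  dplyr::bind_cols(glance(fit), tibble(capped = pw$capped), res[c("tia_mbq_h", "horizon_h")])
}
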