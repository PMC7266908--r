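test_that("mono fit recovers noiseless in-class parameters on the 4-point design", {
  fit <- fit_tac(mono_tac(100, 0.02), model = "mono")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[["A0"]]), 100, tolerance = 1e-9)
  expect_equal(unname(fit$params[["lambda"]]), 0.02, tolerance = 1e-9)
  expect_identical(fit$lambda_e, unname(fit$params[["lambda"]]))
})

test_that("constant activity degenerates to the lower rate bound with a flag", {
  flat <- tibble::tibble(time_h = design_times, activity_mbq = rep(50, 4))
  fit <- fit_tac(flat, model = "mono")
  expect_true(fit$at_bound)
  expect_lte(fit$params[["lambda"]], 1e-6 * (1 + 1e-6))
  expect_equal(unname(fit$params[["A0"]]), 50, tolerance = 1e-3)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_tac(mono_tac(times = c(1, 5)), "mono"), "At least 3")
  expect_error(fit_tac(mono_tac(times = c(1, 5, 9)), "bi_sum"), "At least 4")
  few_pos <- tibble::tibble(time_h = design_times, activity_mbq = c(0, 0, 0, 5))
  expect_error(fit_tac(few_pos, "mono"), "activity > 0")
  expect_error(fit_tac(mono_tac(), "bi_sum", start_mode = "origin"), "infeasible")
  bad <- tibble::tibble(time_h = c(4, 4, 24, 72), activity_mbq = rep(1, 4))
  expect_error(fit_tac(bad, "mono"), "strictly increasing")
})

test_that("bi_origin recovers noiseless uptake-washout kinetics and honours A(0) = 0", {
  fit <- fit_tac(biorigin_tac(200, 0.01, 0.5), model = "bi_origin")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[["A0"]]), 200, tolerance = 1e-6)
  expect_equal(unname(fit$params[["lambda_w"]]), 0.01, tolerance = 1e-6)
  expect_equal(unname(fit$params[["lambda_u"]]), 0.5, tolerance = 1e-6)
  expect_identical(predict(fit, 0), 0)
  expect_gt(fit$params[["lambda_u"]], fit$params[["lambda_w"]])
  expect_identical(fit$lambda_e, unname(fit$params[["lambda_w"]]))
})

test_that("bi_sum recovers a noiseless two-component decay", {
  times <- design_times
  truth <- 150 * exp(-0.3 * times) + 80 * exp(-0.008 * times)
  fit <- fit_tac(tibble::tibble(time_h = times, activity_mbq = truth), "bi_sum")
  expect_true(fit$converged)
  expect_equal(unname(fit$params[["lambda1"]]), 0.3, tolerance = 1e-5)
  expect_equal(unname(fit$params[["lambda2"]]), 0.008, tolerance = 1e-5)
  expect_identical(fit$lambda_e, unname(fit$params[["lambda2"]]))
})

test_that("monotone-decreasing data under bi_origin is flagged but stays integrable", {
  fit <- fit_tac(mono_tac(100, 0.01), model = "bi_origin", start_mode = "origin")
  expect_true(fit$at_bound || !fit$converged)
  pw <- compose_hybrid_curve(fit)
  tia <- integrate_tia(pw)$tia_mbq_h
  expect_true(is.finite(tia))
  expect_gt(tia, 0)
})

test_that("the composite tail is capped at the physical decay constant when slower", {
  lam_phys <- lu177_constants()$physical_decay_constant_per_h
  slow <- fit_tac(mono_tac(100, 0.002), "mono")   # Teff 346.6 h > physical
  pw_slow <- compose_hybrid_curve(slow)
  expect_true(pw_slow$capped)
  expect_equal(pw_slow$tail_decay_constant_per_h, lam_phys, tolerance = 1e-12)

  fast <- fit_tac(mono_tac(100, 0.00722), "mono") # Teff 96 h < 159.46 h
  pw_fast <- compose_hybrid_curve(fast)
  expect_false(pw_fast$capped)
  expect_equal(pw_fast$tail_decay_constant_per_h, 0.00722, tolerance = 1e-6)
})

test_that("composite curves from in-class fits are continuous and start per mode", {
  fit <- fit_tac(mono_tac(100, 0.01), "mono", start_mode = "line")
  pw <- compose_hybrid_curve(fit)
  ends <- pw$segments$t_end[is.finite(pw$segments$t_end)]
  for (b in ends) {
    expect_equal(eval_curve(pw, b - 1e-9), eval_curve(pw, b + 1e-9), tolerance = 1e-6)
  }
  expect_equal(eval_curve(pw, 0), 100 * exp(-0.01 * 0.5), tolerance = 1e-9)

  pw_o <- compose_hybrid_curve(fit, start_mode = "origin")
  expect_equal(eval_curve(pw_o, 0), 0)
  pw_c <- compose_hybrid_curve(fit, start_mode = "continue")
  expect_equal(eval_curve(pw_c, 0), 100, tolerance = 1e-6)
})

test_that("first_fit_time must be a sample time and adds trapezoid bridging", {
  fit <- fit_tac(mono_tac(100, 0.01), "mono")
  expect_error(compose_hybrid_curve(fit, first_fit_time = 10), "sample times")
  pw <- compose_hybrid_curve(fit, first_fit_time = 24)
  expect_true(any(pw$segments$form == "linear"))
  expect_equal(eval_curve(pw, 4), 100 * exp(-0.01 * 4), tolerance = 1e-9)
})

test_that("closed-form TIA matches the analytic mono-curve value and quadrature", {
  fit <- fit_tac(mono_tac(100, 0.01), "mono", start_mode = "line")
  pw <- compose_hybrid_curve(fit)
  got <- integrate_tia(pw, Inf)$tia_mbq_h
  a1 <- 100 * exp(-0.01 * 0.5)
  analytic <- a1 * 0.5 + (100 / 0.01) * exp(-0.01 * 0.5)  # constant + exp from 0.5 to Inf
  expect_equal(got, analytic, tolerance = 1e-10)
  # independent numeric quadrature over a finite window
  got_fin <- integrate_tia(pw, 500)$tia_mbq_h
  expect_equal(got_fin, quadrature_tia(pw, 500), tolerance = 1e-8)
})

test_that("TIA is zero at horizon 0, monotone in horizon, and nearly converged by 2400 h", {
  fit <- fit_tac(mono_tac(100, log(2) / 96), "mono")
  pw <- compose_hybrid_curve(fit)
  expect_identical(integrate_tia(pw, 0)$tia_mbq_h, 0)
  horizons <- c(24, 96, 500, 2400, Inf)
  tias <- vapply(horizons, function(h) integrate_tia(pw, h)$tia_mbq_h, numeric(1))
  expect_true(all(diff(tias) > 0))
  expect_lt(1 - tias[4] / tias[5], 1e-7)
})

test_that("TIA decreases as the decay constant increases at fixed amplitude", {
  lams <- c(0.004, 0.008, 0.02, 0.05)
  tias <- vapply(lams, function(l) {
    integrate_tia(compose_hybrid_curve(fit_tac(mono_tac(100, l), "mono")))$tia_mbq_h
  }, numeric(1))
  expect_true(all(diff(tias) < 0))
})

test_that("trapezoid + physical-decay tail reproduces the hand-computed integral", {
  lam_phys <- lu177_constants()$physical_decay_constant_per_h
  res <- trapezoid_physical_decay_tia(
    tibble::tibble(time_h = c(24, 72), activity_mbq = c(100, 50))
  )
  hand <- 100 * 24 + (100 + 50) / 2 * 48 + 50 / lam_phys
  expect_equal(res$tia_mbq_h, hand, tolerance = 1e-12)
  expect_identical(res$method, "trapezoid_physical_decay")

  # constant series: the pre-tail part is an exact rectangle
  flat <- tibble::tibble(time_h = c(2, 10, 50), activity_mbq = rep(80, 3))
  tot <- trapezoid_physical_decay_tia(flat)$tia_mbq_h
  expect_equal(tot - 80 / lam_phys, 80 * 50, tolerance = 1e-10)

  expect_error(trapezoid_physical_decay_tia(flat[1, ]), "At least 2")
})

test_that("single-time-point TIA back-extrapolates through the measurement", {
  lam <- log(2) / 96
  res <- single_time_point_tia(96, 10, lam)
  expect_equal(res$tia_mbq_h, 20 / lam, tolerance = 1e-12)
  expect_true(res$approximate)
  expect_identical(single_time_point_tia(96, 0, lam)$tia_mbq_h, 0)
  expect_error(single_time_point_tia(0, 10, lam), "positive")

  # relative error over true mono targets follows the closed form
  for (teff in c(38, 60, 96, 128)) {
    lt <- log(2) / teff
    true_tia <- 100 / lt
    est <- single_time_point_tia(96, 100 * exp(-lt * 96), lam)$tia_mbq_h
    expected_ratio <- (lt / lam) * exp((lam - lt) * 96)
    expect_equal(est / true_tia, expected_ratio, tolerance = 1e-10)
  }
})

test_that("fit-quality rho reflects agreement between measured and fitted ranks", {
  perfect <- fit_tac(mono_tac(100, 0.02), "mono")
  expect_equal(fit_quality_rho(perfect), 1)

  rising <- tibble::tibble(time_h = design_times, activity_mbq = c(10, 20, 30, 40))
  fit_r <- fit_tac(rising, "mono")   # decreasing predictions vs increasing data
  expect_equal(fit_quality_rho(fit_r), -1)

  swapped <- tibble::tibble(time_h = design_times, activity_mbq = c(10, 8, 9, 7))
  fit_s <- fit_tac(swapped, "mono")
  expect_equal(fit_quality_rho(fit_s), 0.8)  # 1 - 6*2/(4*15)
})

test_that("broom-style accessors expose the fit", {
  fit <- fit_tac(mono_tac(100, 0.02), "mono")
  td <- tidy(fit)
  expect_identical(td$term, c("A0", "lambda"))
  gl <- glance(fit)
  expect_equal(gl$effective_half_life_h, log(2) / 0.02, tolerance = 1e-8)
  au <- augment(fit)
  expect_true(all(abs(au$.resid) < 1e-8))
  expect_s3_class(autoplot(fit), "ggplot")
})
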