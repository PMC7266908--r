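test_that("Bland-Altman bias, SD and limits match hand arithmetic", {
  pm <- tibble::tibble(a = c(1, 2, 4), b = c(0, 2, 1))  # d = 1, 0, 3
  ba <- bland_altman(pm, a, b)
  expect_equal(ba$bias, 4 / 3, tolerance = 1e-12)
  expect_equal(ba$sd, sqrt(sum((c(1, 0, 3) - 4 / 3)^2) / 2), tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 3.92 * ba$sd, tolerance = 1e-12)

  ident <- bland_altman(tibble::tibble(a = c(1, 2), b = c(1, 2)), a, b)
  expect_equal(c(ident$bias, ident$sd, ident$loa_low, ident$loa_high), rep(0, 4))
  expect_error(bland_altman(tibble::tibble(a = 1, b = 2), a, b), "At least 2")
})

test_that("adding a constant to one series shifts the bias, not the spread", {
  set.seed(11)
  for (i in 1:5) {
    pm <- tibble::tibble(a = rnorm(8, 5), b = rnorm(8, 5))
    base <- bland_altman(pm, a, b)
    shifted <- bland_altman(dplyr::mutate(pm, a = a + 2.5), a, b)
    expect_equal(shifted$bias, base$bias + 2.5, tolerance = 1e-10)
    expect_equal(shifted$sd, base$sd, tolerance = 1e-10)
  }
})

test_that("relative differences are percentages of the pair average", {
  pm <- tibble::tibble(a = c(3, 2), b = c(1, 2))
  rel <- relative_differences(pm, a, b)
  expect_equal(attr(rel, "pairs")$diff, c(100, 0))
  expect_identical(rel$scale, "relative_percent")

  same <- relative_differences(tibble::tibble(a = c(2, 5), b = c(2, 5)), a, b)
  expect_equal(same$bias, 0)

  withzero <- tibble::tibble(a = c(3, 2, 1), b = c(1, 2, -1))
  expect_warning(out <- relative_differences(withzero, a, b), "zero average")
  expect_equal(out$n, 2)
})

test_that("midrank Spearman equals the classic formula on all small untied pairs", {
  for (n in 4:5) {
    perms <- combinat_perms(n)
    for (i in seq_len(nrow(perms))) {
      y <- perms[i, ]
      pm <- tibble::tibble(a = seq_len(n), b = y)
      classic <- 1 - 6 * sum((seq_len(n) - y)^2) / (n * (n^2 - 1))
      expect_equal(spearman_rho(pm, a, b), classic, tolerance = 1e-12)
    }
  }
})

test_that("Spearman is invariant under monotone transforms and guards edge cases", {
  pm <- tibble::tibble(a = c(2, 9, 4, 7, 5), b = c(1, 8, 2, 9, 3))
  expect_equal(spearman_rho(pm, a, b),
               spearman_rho(dplyr::mutate(pm, a = exp(a), b = b^3), a, b))
  mono <- tibble::tibble(a = 1:5, b = log(1:5))
  expect_equal(spearman_rho(mono, a, b), 1)
  rev <- tibble::tibble(a = 1:4, b = 4:1)
  expect_equal(spearman_rho(rev, a, b), -1)
  expect_error(spearman_rho(tibble::tibble(a = 1:2, b = 2:1), a, b), "At least 3")
  expect_error(spearman_rho(tibble::tibble(a = 1:4, b = rep(2, 4)), a, b), "constant")
})

test_that("ICC(A,1) matches a two-way aov decomposition and its boundary behaviour", {
  set.seed(23)
  x <- rnorm(12, 10, 2)
  y <- x + rnorm(12, 0.5, 0.8)
  got <- icc_agreement_single(tibble::tibble(a = x, b = y), a, b)

  long <- data.frame(val = c(x, y),
                     subj = factor(rep(1:12, 2)),
                     rater = factor(rep(1:2, each = 12)))
  ms <- anova(stats::aov(val ~ subj + rater, data = long))[["Mean Sq"]]
  icc_aov <- (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / 12) * (ms[2] - ms[3]))
  expect_equal(got$icc, icc_aov, tolerance = 1e-10)

  perfect <- icc_agreement_single(tibble::tibble(a = x, b = x), a, b)
  expect_equal(perfect$icc, 1)

  # a growing constant offset degrades absolute agreement monotonically
  iccs <- vapply(c(0, 1, 3, 8), function(off) {
    icc_agreement_single(tibble::tibble(a = x, b = x + off), a, b)$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))

  expect_error(
    icc_agreement_single(tibble::tibble(a = rep(1, 4), b = rep(1, 4)), a, b),
    "Degenerate"
  )
})

test_that("the stratified comparison table carries every statistic per group", {
  pm <- tibble::tibble(
    stratum = rep(c("kidneys", "lesions"), each = 5),
    model = "mono",
    a = c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10),
    b = c(1.1, 2, 2.9, 4.2, 5, 2, 4.1, 6, 8, 9.5)
  )
  out <- build_comparison_table(pm, a, b, stratum, model)
  expect_equal(nrow(out), 2)
  expect_setequal(out$stratum, c("kidneys", "lesions"))
  expect_true(all(c("bias", "sd", "loa_low", "loa_high", "rel_bias",
                    "spearman", "icc") %in% names(out)))
  expect_true(all(out$spearman > 0.9))
})
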