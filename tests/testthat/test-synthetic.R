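test_that("cohort generation is seed-deterministic", {
  a <- generate_cohort(cohort_spec(n_patients = 3, seed = 99))
  b <- generate_cohort(cohort_spec(n_patients = 3, seed = 99))
  expect_identical(a$planar, b$planar)
  expect_identical(a$anchors, b$anchors)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_spec(n_patients = 3, seed = 100))
  expect_false(identical(a$planar, c$planar))
})

test_that("without noise the anchored geometric-mean curve equals the true TAC", {
  sp <- cohort_spec(n_patients = 2, poisson_noise = FALSE, calibration_cv = 0, seed = 3)
  co <- generate_cohort(sp)
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    series <- co$planar[co$planar$patient_id == tr$patient_id &
                        co$planar$target_label == tr$target_label, ]
    anc <- co$anchors[co$anchors$patient_id == tr$patient_id &
                      co$anchors$target_label == tr$target_label, ]
    tac <- anchor_to_spect(geometric_mean_series(series), anc$activity_mbq,
                           anc$anchor_time_h)
    truth_a <- if (tr$model == "mono") {
      tr$a0_mbq * exp(-tr$lambda_e_per_h * sp$times_h)
    } else {
      tr$a0_mbq * (exp(-tr$lambda_w_per_h * sp$times_h) -
                     exp(-tr$lambda_u_per_h * sp$times_h))
    }
    expect_equal(tac$activity_mbq, truth_a, tolerance = 1e-9)
  }
})

test_that("true TIA equals the closed-form integral of the true model", {
  co <- generate_cohort(cohort_spec(n_patients = 2, seed = 17))
  mono <- co$truth[co$truth$model == "mono" & co$truth$target_class == "kidney", ]
  expect_equal(mono$tia_mbq_h, mono$a0_mbq / mono$lambda_e_per_h, tolerance = 1e-12)
  bi <- co$truth[co$truth$model == "bi_origin", ]
  expect_equal(bi$tia_mbq_h,
               bi$a0_mbq * (1 / bi$lambda_w_per_h - 1 / bi$lambda_u_per_h),
               tolerance = 1e-12)
})

test_that("fixture tables carry the printed values, counts and flags", {
  t4 <- load_fixture("table4")
  expect_equal(nrow(t4), 28)
  expect_equal(sum(t4$location == "liver"), 20)
  expect_equal(sum(t4$location == "other"), 8)
  expect_equal(sum(t4$data_flag == "not_reliable"), 1)
  expect_equal(sum(is.na(t4$bi_olinda_gy_per_gbq)), 4)  # patient 2 bi not reported

  t3 <- load_fixture("table3")
  p1 <- t3[t3$patient_id == 1 & t3$target == "kidneys" & t3$model == "mono", ]
  expect_equal(c(p1$olinda_gy_per_gbq, p1$planet_gy_per_gbq), c(0.61, 0.62))
  expect_true(all(t3$data_flag[t3$patient_id == 2 & t3$target == "kidneys"] == "single_kidney"))
  typo <- t3[t3$patient_id == 5 & t3$target == "red_marrow" & t3$model == "bi", ]
  expect_identical(typo$data_flag, "suspected_typo")
  expect_identical(typo$olinda_gy_per_gbq, 0.010)  # kept as printed

  t1 <- load_fixture("table1")
  expect_equal(t1$administered_mbq[t1$patient_id == 1], 7131)
  expect_equal(sum(t1$liver_lesions), 21)  # printed tally, differs from table4 records
})

test_that("fixture value checksums pin the transcription", {
  t3 <- load_fixture("table3")
  expect_equal(sum(t3$olinda_gy_per_gbq), 10.82, tolerance = 1e-10)
  expect_equal(sum(t3$planet_gy_per_gbq), 9.753, tolerance = 1e-10)
  t4 <- load_fixture("table4")
  expect_equal(sum(t4$mono_olinda_gy_per_gbq), 102.57, tolerance = 1e-10)
  expect_equal(sum(t4$mono_planet_gy_per_gbq), 113.28, tolerance = 1e-10)
  expect_equal(sum(t4$bi_olinda_gy_per_gbq, na.rm = TRUE), 90.69, tolerance = 1e-10)
  expect_equal(sum(t4$bi_planet_gy_per_gbq, na.rm = TRUE), 81.37, tolerance = 1e-10)
  expect_equal(sum(load_fixture("table1")$administered_mbq), 73031)
})

test_that("identical processing arms agree perfectly", {
  co <- generate_cohort(cohort_spec(n_patients = 4, seed = 8))
  prof <- shipped_profile("organ_mird")
  pm <- suppressWarnings(suppressMessages(emulate_pipeline_variants(co, prof, prof)))
  kid <- pm[pm$stratum == "kidneys", ]
  ba <- bland_altman(kid, x, y)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 0)
  expect_equal(spearman_rho(kid, x, y), 1)
  expect_equal(icc_agreement_single(kid, x, y)$icc, 1)
})

test_that("arms differing only in horizon are near-identical for Teff ~96 h kinetics", {
  sp <- cohort_spec(n_patients = 4, poisson_noise = FALSE, calibration_cv = 0, seed = 12)
  co <- generate_cohort(sp)
  pa <- analysis_profile("inf", model = "mono", horizon_h = Inf)
  pb <- analysis_profile("2400", model = "mono", horizon_h = 2400)
  pm <- suppressWarnings(suppressMessages(emulate_pipeline_variants(co, pa, pb)))
  kid <- pm[pm$stratum == "kidneys", ]
  rel_bias <- relative_differences(kid, x, y)$bias
  expect_lt(abs(rel_bias), 0.01)  # percent
})

test_that("a mono arm against an origin-anchored bi arm overestimates lesion uptake", {
  co <- generate_cohort(cohort_spec(seed = 42))
  pa <- shipped_profile("organ_mird")             # mono, line, infinity
  pb <- shipped_profile("voxel_like", model = "bi")  # bi_origin, origin, 2400 h
  pm <- suppressWarnings(suppressMessages(emulate_pipeline_variants(co, pa, pb)))
  les <- pm[pm$stratum == "tumour_lesions", ]
  ba <- bland_altman(les, x, y)
  expect_gt(ba$bias, 0)
})
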