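#' Specification of a synthetic hybrid-dosimetry cohort
#'
#' Describes the study design a synthetic cohort should emulate: planar
#' imaging at 0.5, 4, 24 and 72 h post-injection, one quantitative SPECT
#' anchor at 24 h, 7.4 GBq administered per cycle, and per-target kinetic
#' priors — mono-exponential kidneys with an effective half-life around
#' 96 h (~4 days), low-amplitude mono-exponential red marrow, and
#' uptake-washout (origin-anchored bi-exponential) tumour lesions whose
#' uptake phase plays out within the first day. Planar counts are Poisson
#' around `sensitivity × activity × view factor`, with a per-target-depth
#' anterior/posterior asymmetry so the geometric mean is non-trivial.
#'
#' @param n_patients Number of patients, default 10.
#' @param administered_gbq Administered activity per cycle (GBq).
#' @param times_h Planar sampling times (hours).
#' @param anchor_time_h SPECT anchor time; must be one of `times_h`.
#' @param sensitivity_counts_per_mbq Planar counts per MBq in the target.
#' @param view_asymmetry Named multiplicative posterior/anterior factors
#'   per target depth class (`kidney`, `red_marrow`, `lesion`).
#' @param liver_lesions,other_lesions Lesions per patient.
#' @param poisson_noise Draw Poisson counts (`TRUE`) or use noise-free
#'   expected counts (`FALSE`).
#' @param calibration_cv Relative SD of the SPECT anchor calibration error
#'   (0 = exact anchor).
#' @param kidney_teff_h,kidney_teff_gsd Lognormal prior for the kidney
#'   effective half-life (median, geometric SD as sdlog).
#' @param kidney_uptake_frac Median fraction of the administered activity
#'   in each kidney at time zero. The uptake-fraction defaults are
#'   calibrated so the cohort's dose coefficients land on the clinical
#'   scale of the published tables (kidneys ~0.5, red marrow ~0.06,
#'   lesions ~3 Gy/GBq) under the shipped S-value table.
#' @param rm_uptake_frac Median fraction of administered activity in the
#'   total red marrow.
#' @param rm_teff_h Median red-marrow effective half-life (h).
#' @param lesion_uptake_frac Median lesion amplitude as a fraction of the
#'   administered activity.
#' @param lesion_uptake_rate_per_h Median uptake rate of the lesion
#'   uptake-washout model (/h); washout shares the kidney half-life prior.
#' @param seed Integer seed; every stochastic path is derived from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 10,
                        administered_gbq = 7.4,
                        times_h = c(0.5, 4, 24, 72),
                        anchor_time_h = 24,
                        sensitivity_counts_per_mbq = 30,
                        view_asymmetry = c(kidney = 1.6, red_marrow = 1.2, lesion = 1.0),
                        liver_lesions = 2,
                        other_lesions = 1,
                        poisson_noise = TRUE,
                        calibration_cv = 0,
                        kidney_teff_h = 96,
                        kidney_teff_gsd = 0.2,
                        kidney_uptake_frac = 0.006,
                        rm_uptake_frac = 0.007,
                        rm_teff_h = 80,
                        lesion_uptake_frac = 0.0011,
                        lesion_uptake_rate_per_h = 0.35,
                        seed = 1L) {
  stopifnot(n_patients >= 1, administered_gbq > 0,
            length(times_h) >= 2, !is.unsorted(times_h, strictly = TRUE),
            anchor_time_h %in% times_h, sensitivity_counts_per_mbq > 0,
            all(view_asymmetry > 0), kidney_teff_h > 0, rm_teff_h > 0,
            lesion_uptake_rate_per_h > 0, calibration_cv >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-patient, per-target kinetic ground truth from the priors in
#' the spec, simulates the anterior/posterior planar count series and the
#' SPECT anchor, and returns everything alongside closed-form ground-truth
#' time-integrated activities and doses for recovery testing. Deterministic
#' for a fixed seed.
#'
#' Red-marrow entries describe the 4.2 ml humerus VOI: the planar counts
#' and the anchor carry VOI-scale activity, while the ground truth records
#' the total-marrow TIA and dose (VOI activity divided by the marrow
#' fraction of [red_marrow_fraction()]).
#'
#' @param spec A [cohort_spec()].
#' @return List with tibbles `planar` (`patient_id`, `target_label`,
#'   `time_h`, `anterior_counts`, `posterior_counts`), `anchors`
#'   (`patient_id`, `target_label`, `anchor_time_h`, `activity_mbq`) and
#'   `truth` (true model, rates, TIA, mass, dose and kidney BED per
#'   target), plus the `spec`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 2, seed = 7))
#' head(cohort$planar)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  admin_mbq <- spec$administered_gbq * 1000
  rm_frac <- red_marrow_fraction()$fraction
  stab <- s_value_table()
  s_kid <- stab[stab$target == "kidney_single", ]
  s_rm <- stab[stab$target == "red_marrow", ]

  planar <- list(); anchors <- list(); truth <- list()
  lam_from_teff <- function(teff) log(2) / teff

  for (p in seq_len(spec$n_patients)) {
    kid_lambda <- lam_from_teff(rlnorm(1, log(spec$kidney_teff_h), spec$kidney_teff_gsd))
    targets <- c("kidney_left", "kidney_right", "red_marrow",
                 if (spec$liver_lesions > 0) paste0("lesion_liver_", seq_len(spec$liver_lesions)),
                 if (spec$other_lesions > 0) paste0("lesion_other_", seq_len(spec$other_lesions)))
    for (tg in targets) {
      cls <- target_class(tg)
      if (cls == "kidney") {
        lam <- kid_lambda
        a0 <- admin_mbq * rlnorm(1, log(spec$kidney_uptake_frac), 0.3)
        model <- "mono"; lw <- lam; lu <- NA_real_
        a_true <- function(t) a0 * exp(-lam * t)
        tia_true <- a0 / lam
        mass <- max(rnorm(1, 150, 15), 80)
        dose <- mean_absorbed_dose(tia_true, s_kid$s_gy_per_mbq_h,
                                   s_kid$phantom_mass_g, mass)
      } else if (cls == "red_marrow") {
        lam <- lam_from_teff(rlnorm(1, log(spec$rm_teff_h), 0.2))
        a0_total <- admin_mbq * rlnorm(1, log(spec$rm_uptake_frac), 0.3)
        a0 <- a0_total * rm_frac  # VOI-scale amplitude
        model <- "mono"; lw <- lam; lu <- NA_real_
        a_true <- function(t) a0 * exp(-lam * t)
        tia_true <- a0_total / lam
        mass <- s_rm$phantom_mass_g
        dose <- mean_absorbed_dose(tia_true, s_rm$s_gy_per_mbq_h,
                                   s_rm$phantom_mass_g, mass)
      } else {
        lw <- lam_from_teff(rlnorm(1, log(spec$kidney_teff_h), 0.25))
        lu <- rlnorm(1, log(spec$lesion_uptake_rate_per_h), 0.3)
        if (lu <= lw) lu <- lw * 20
        a0 <- admin_mbq * rlnorm(1, log(spec$lesion_uptake_frac), 0.4)
        model <- "bi_origin"; lam <- lw
        a_true <- function(t) a0 * (exp(-lw * t) - exp(-lu * t))
        tia_true <- a0 * (1 / lw - 1 / lu)
        mass <- 4.19
        dose <- sphere_dose(tia_true, mass)
      }
      asym <- spec$view_asymmetry[[cls_asym_key(cls)]]
      act <- a_true(spec$times_h)
      mu_ant <- spec$sensitivity_counts_per_mbq * act / sqrt(asym)
      mu_post <- spec$sensitivity_counts_per_mbq * act * sqrt(asym)
      if (spec$poisson_noise) {
        ant <- rpois(length(mu_ant), mu_ant)
        post <- rpois(length(mu_post), mu_post)
      } else {
        ant <- mu_ant; post <- mu_post
      }
      anchor_act <- a_true(spec$anchor_time_h) *
        (1 + if (spec$calibration_cv > 0) rnorm(1, 0, spec$calibration_cv) else 0)
      planar[[length(planar) + 1L]] <- tibble(
        patient_id = p, target_label = tg, time_h = spec$times_h,
        anterior_counts = ant, posterior_counts = post
      )
      anchors[[length(anchors) + 1L]] <- tibble(
        patient_id = p, target_label = tg,
        anchor_time_h = spec$anchor_time_h, activity_mbq = anchor_act
      )
      truth[[length(truth) + 1L]] <- tibble(
        patient_id = p, target_label = tg, target_class = cls, model = model,
        a0_mbq = a0, lambda_w_per_h = lw, lambda_u_per_h = lu,
        lambda_e_per_h = lam, tia_mbq_h = tia_true, mass_g = mass,
        dose_gy = dose,
        dose_gy_per_gbq = dose / spec$administered_gbq
      )
    }
  }

  truth <- dplyr::bind_rows(truth)
  # kidney BED ground truth: paired-average dose with the patient's shared
  # kidney decay constant
  kid <- truth |>
    dplyr::filter(.data$target_class == "kidney") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dose_gy = mean(.data$dose_gy),
                     lambda_e_per_h = .data$lambda_e_per_h[1], .groups = "drop")
  kid$bed_gy <- bed_from_dose(kid$dose_gy, kid$lambda_e_per_h)$bed_gy
  list(
    planar = dplyr::bind_rows(planar),
    anchors = dplyr::bind_rows(anchors),
    truth = truth,
    kidney_bed_truth = kid,
    spec = spec
  )
}

# Target class from a label like "kidney_left" or "lesion_liver_2".
target_class <- function(label) {
  dplyr::case_when(
    grepl("^kidney", label) ~ "kidney",
    grepl("^red_marrow", label) ~ "red_marrow",
    grepl("^lesion_liver", label) ~ "lesion_liver",
    grepl("^lesion_other", label) ~ "lesion_other",
    .default = "lesion_other"
  )
}

cls_asym_key <- function(cls) {
  c(kidney = "kidney", red_marrow = "red_marrow",
    lesion_liver = "lesion", lesion_other = "lesion")[[cls]]
}

#' Process one synthetic cohort through two analysis arms
#'
#' Runs the full quantify-fit-integrate-dose chain twice per target, once
#' per analysis profile, and returns the paired dose coefficients by
#' stratum — the input the agreement module expects. Identical profiles
#' are allowed (a perfect-agreement control arm). Kidney pairs are
#' combined per each profile's kidney mode; targets whose fit fails in
#' either arm are kept with `NA` and dropped pairwise downstream.
#'
#' @param cohort A [generate_cohort()] result.
#' @param profile_a,profile_b [analysis_profile()]s.
#' @return Tibble: `patient_id`, `stratum` (`kidneys`, `red_marrow`,
#'   `tumour_lesions`), `unit_id`, `x` (profile_a Gy/GBq), `y` (profile_b).
#' @export
emulate_pipeline_variants <- function(cohort, profile_a, profile_b) {
  ra <- run_patient_dosimetry(cohort$planar, cohort$anchors, profile_a,
                              masses = cohort$truth[c("patient_id", "target_label", "mass_g")],
                              administered_gbq = cohort$spec$administered_gbq)
  rb <- run_patient_dosimetry(cohort$planar, cohort$anchors, profile_b,
                              masses = cohort$truth[c("patient_id", "target_label", "mass_g")],
                              administered_gbq = cohort$spec$administered_gbq)
  a <- ra$doses[c("patient_id", "target_label", "stratum", "dose_gy_per_gbq")]
  b <- rb$doses[c("patient_id", "target_label", "stratum", "dose_gy_per_gbq")]
  dplyr::inner_join(a, b, by = c("patient_id", "target_label", "stratum"),
                    suffix = c("_a", "_b")) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      stratum = .data$stratum,
      unit_id = .data$target_label,
      x = .data$dose_gy_per_gbq_a,
      y = .data$dose_gy_per_gbq_b
    )
}
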