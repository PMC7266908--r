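#' Load a packaged clinical-table fixture
#'
#' The package ships verbatim transcriptions of the published per-patient
#' tables of the ten-patient software-comparison cohort, so the full
#' agreement analysis is re-runnable without any image data:
#'
#' * `"table1"` — patient characteristics: administered activity (MBq) and
#'   the number of included liver / other tumour lesions per patient.
#' * `"table3"` — kidney and red-marrow mean absorbed dose coefficients
#'   (Gy/GBq) from both software systems, mono- and bi-exponential fits.
#' * `"table4"` — 28 per-lesion dose coefficients (20 liver, 8 other);
#'   the bi-exponential columns of patient 2 were not reported.
#'
#' Data-quality flags are preserved in a `data_flag` column:
#' `single_kidney` (patient 2 had one visible kidney on planar imaging),
#' `not_reliable` (one lesion entry with very high dose values),
#' `suspected_typo` (the 0.010 Gy/GBq red-marrow bi-exponential entry of
#' patient 5, inconsistent with the cohort's summary statistics; kept as
#' printed). Note: table1's lesion tally (21 liver) disagrees with
#' table4's records (20 liver); table4 is the authoritative count.
#'
#' @param name One of `"table1"`, `"table3"`, `"table4"`.
#' @return A tibble with the printed values and flags.
#' @export
#' @examples
#' load_fixture("table3")
load_fixture <- function(name = c("table1", "table3", "table4")) {
  name <- match.arg(name)
  file <- switch(name,
    table1 = "table1_patients.csv",
    table3 = "table3_organ_doses.csv",
    table4 = "table4_lesion_doses.csv"
  )
  path <- system.file("extdata", file, package = "hybridose", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("data_flag" %in% names(out)) {
    out$data_flag <- dplyr::coalesce(out$data_flag, "")
  }
  out
}
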