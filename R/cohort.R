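#' Build a per-class analysis cohort
#'
#' Applies the eligibility filters of the pre/post design and assembles one
#' cohort row per retained patient, carrying both period adherence flags and
#' the adjustment covariates. Filters, in application order:
#' \enumerate{
#'   \item age within `age_range` (evaluated at the baseline window start);
#'   \item enrollment covering both periods
#'     (`enroll_start <= baseline start` and `enroll_end >= follow-up end`);
#'   \item at least one fill of `drug_class` in each period.
#' }
#' Cohort membership is order-insensitive; only the attrition counts depend
#' on the order. The attrition log (patients removed per rule) is attached as
#' the `"attrition"` attribute.
#'
#' @param patients Roster tibble as from [read_patients()].
#' @param fills Fills tibble as from [read_fills()].
#' @param pdc PDC table as from [compute_pdc()] (both periods).
#' @param drug_class `"antihypertensive"` or `"antihyperlipidemic"`.
#' @param windows Baseline/follow-up windows, [study_windows()].
#' @param age_range Inclusive eligible age range, default `c(18, 89)`.
#' @return Tibble with `patient_id, group, drug_class, baseline_adherent,
#'   followup_adherent, baseline_pdc, followup_pdc` plus the roster
#'   covariates; attribute `"attrition"` is a named integer vector.
#' @export
build_cohort <- function(patients, fills, pdc, drug_class, windows,
                         age_range = c(18L, 89L)) {
  stopifnot(drug_class %in% DRUG_CLASSES)
  orphan <- setdiff(unique(fills$patient_id), patients$patient_id)
  if (length(orphan)) {
    abort(sprintf("fills reference %d patient(s) absent from the roster: %s",
                  length(orphan), paste(utils::head(orphan, 5L), collapse = ", ")),
          class = "pdcadhere_integrity_error")
  }
  bl <- windows$baseline; fu <- windows$follow_up
  attrition <- c(age = 0L, enrollment = 0L, missing_period_claim = 0L)

  cur <- patients
  ok_age <- cur$age >= age_range[1] & cur$age <= age_range[2]
  attrition["age"] <- sum(!ok_age)
  cur <- cur[ok_age, ]

  ok_enr <- cur$enroll_start <= bl$start &
    cur$enroll_end >= fu$start + fu$length_days
  attrition["enrollment"] <- sum(!ok_enr)
  cur <- cur[ok_enr, ]

  cls_fills <- fills[fills$drug_class == drug_class, ]
  day <- as.integer(cls_fills$fill_date - bl$start)
  in_bl <- day >= 0L & day < bl$length_days
  in_fu <- day >= bl$length_days & day < bl$length_days + fu$length_days
  has_both <- intersect(unique(cls_fills$patient_id[in_bl]),
                        unique(cls_fills$patient_id[in_fu]))
  ok_claim <- cur$patient_id %in% has_both
  attrition["missing_period_claim"] <- sum(!ok_claim)
  cur <- cur[ok_claim, ]

  out_cols <- c("patient_id", "group", "drug_class", "baseline_adherent",
                "followup_adherent", "baseline_pdc", "followup_pdc",
                setdiff(names(patients), c("patient_id", "group")))
  if (nrow(cur) == 0L) {
    out <- tibble::tibble(
      patient_id = character(), group = character(), drug_class = character(),
      baseline_adherent = logical(), followup_adherent = logical(),
      baseline_pdc = numeric(), followup_pdc = numeric()
    )
    out <- dplyr::bind_cols(out, patients[0, setdiff(names(patients),
                                                     c("patient_id", "group"))])
    attr(out, "attrition") <- attrition
    return(out)
  }
  cls_pdc <- pdc[pdc$drug_class == drug_class, ]
  wide <- tidyr::pivot_wider(
    cls_pdc[c("patient_id", "period", "pdc", "adherent")],
    names_from = "period", values_from = c("pdc", "adherent")
  )
  out <- dplyr::inner_join(cur, wide, by = "patient_id")
  if (nrow(out) != nrow(cur)) {
    abort("PDC results missing for eligible patients; run compute_pdc on the same fills",
          class = "pdcadhere_integrity_error")
  }
  out <- dplyr::mutate(
    out,
    drug_class = drug_class,
    baseline_adherent = .data$adherent_baseline,
    followup_adherent = .data$adherent_follow_up,
    baseline_pdc = .data$pdc_baseline,
    followup_pdc = .data$pdc_follow_up
  )
  out <- out[out_cols]
  attr(out, "attrition") <- attrition
  out
}

#' Overlap of the two drug-class cohorts
#'
#' Counts patients present in both class cohorts, in the antihypertensive
#' cohort only, and in the antihyperlipidemic cohort only. The three counts
#' are mutually exclusive and sum to the size of the union cohort.
#'
#' @param cohort_htn Antihypertensive cohort from [build_cohort()].
#' @param cohort_lipid Antihyperlipidemic cohort from [build_cohort()].
#' @return Tibble with columns `membership` and `n`.
#' @export
class_membership_summary <- function(cohort_htn, cohort_lipid) {
  h <- unique(cohort_htn$patient_id)
  l <- unique(cohort_lipid$patient_id)
  tibble::tibble(
    membership = c("both", "antihypertensive_only", "antihyperlipidemic_only"),
    n = c(length(intersect(h, l)), length(setdiff(h, l)), length(setdiff(l, h)))
  )
}
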