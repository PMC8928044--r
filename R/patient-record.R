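# Patient-level EMR extract model. A record stores only raw, observed
# fields (claims, feature flags, biopsies, measurements); every derived
# label (index of suspicion, case group, organs, stage, groups) is a pure
# function of these fields and is never stored on the record.

.stop_field <- function(patient_id, field, msg) {
  stop(sprintf("patient '%s', field '%s': %s", patient_id, field, msg),
       call. = FALSE)
}

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' Construct ICD claim rows
#'
#' @param code Character vector of ICD codes as they appear in the claims
#'   feed (e.g. `"135"`, `"D86.0"`). Stored verbatim; non-sarcoidosis codes
#'   are allowed.
#' @param setting `"inpatient"` or `"outpatient"`, recycled to the length
#'   of `code`.
#' @param date Optional ISO-8601 date strings (`NA` when unknown).
#' @return A data frame with columns `code`, `setting`, `date`.
#' @export
icd_claims <- function(code = character(), setting = "outpatient",
                       date = NA_character_) {
  n <- length(code)
  data.frame(code = as.character(code),
             setting = rep_len(as.character(setting), n),
             date = rep_len(as.character(date), n),
             stringsAsFactors = FALSE)
}

#' Construct biopsy record rows
#'
#' @param site Biopsy site code (see [biopsy_sites()]).
#' @param result `"nonnecrotizing_granuloma"` or `"other_finding"`.
#' @param provenance `"primary"` (pathology-report domain) or
#'   `"secondary"` (re-documented in clinical notes, e.g. an outside or
#'   remote biopsy).
#' @return A data frame with columns `site`, `result`, `provenance`.
#' @export
biopsy_records <- function(site = character(), result = "nonnecrotizing_granuloma",
                           provenance = "primary") {
  n <- length(site)
  data.frame(site = as.character(site),
             result = rep_len(as.character(result), n),
             provenance = rep_len(as.character(provenance), n),
             stringsAsFactors = FALSE)
}

#' Pulmonary function test measurements
#'
#' Measured values are paired with their lower limits of normal (LLN), as
#' reported by the PFT laboratory; pattern interpretation compares each
#' value against its own LLN (see [pft_pattern()]).
#'
#' @param available Logical; when `FALSE` no measurement field is read and
#'   the pattern is `"missing"`.
#' @param fev1_fvc_ratio,fev1_fvc_lln FEV1/FVC ratio and its LLN (fractions).
#' @param fvc,fvc_lln Forced vital capacity and its LLN (liters).
#' @param tlc,tlc_lln Optional total lung capacity and its LLN (liters).
#' @param dlco_pct_predicted,dlco_lln_pct Optional diffusing capacity
#'   (percent predicted) and its LLN.
#' @return A list of class-free PFT fields for use in [patient_record()].
#' @export
pft_measurements <- function(available = FALSE,
                             fev1_fvc_ratio = NA_real_, fev1_fvc_lln = NA_real_,
                             fvc = NA_real_, fvc_lln = NA_real_,
                             tlc = NA_real_, tlc_lln = NA_real_,
                             dlco_pct_predicted = NA_real_,
                             dlco_lln_pct = NA_real_) {
  list(available = available,
       fev1_fvc_ratio = as.numeric(fev1_fvc_ratio),
       fev1_fvc_lln = as.numeric(fev1_fvc_lln),
       fvc = as.numeric(fvc), fvc_lln = as.numeric(fvc_lln),
       tlc = as.numeric(tlc), tlc_lln = as.numeric(tlc_lln),
       dlco_pct_predicted = as.numeric(dlco_pct_predicted),
       dlco_lln_pct = as.numeric(dlco_lln_pct))
}

#' Chest imaging findings for Scadding staging
#'
#' @param report_available Logical; `FALSE` yields a `"missing"` stage.
#' @param cxr_normal Normal chest radiograph (implies all other findings
#'   are absent).
#' @param hilar_mediastinal_nodal_enlargement,parenchymal_disease,fibrosis_end_stage
#'   Logical staging findings.
#' @return A list of imaging fields for use in [patient_record()].
#' @export
imaging_findings <- function(report_available = FALSE, cxr_normal = FALSE,
                             hilar_mediastinal_nodal_enlargement = FALSE,
                             parenchymal_disease = FALSE,
                             fibrosis_end_stage = FALSE) {
  list(report_available = report_available, cxr_normal = cxr_normal,
       hilar_mediastinal_nodal_enlargement = hilar_mediastinal_nodal_enlargement,
       parenchymal_disease = parenchymal_disease,
       fibrosis_end_stage = fibrosis_end_stage)
}

#' Treatment and disease-activity history
#'
#' @param ever_treated Ever treated for sarcoidosis.
#' @param treated_within_3_months Treated within 3 months of data review
#'   (implies `ever_treated`).
#' @param acute_lofgren Acute presentation (Lofgren syndrome).
#' @param remitting_no_active_disease_gt_1yr No evidence of active
#'   clinical disease for more than one year.
#' @param cardiac_manifestations Cardiac manifestations of sarcoidosis in
#'   the clinical course.
#' @return A list of course fields for use in [patient_record()].
#' @export
clinical_course <- function(ever_treated = FALSE,
                            treated_within_3_months = FALSE,
                            acute_lofgren = FALSE,
                            remitting_no_active_disease_gt_1yr = FALSE,
                            cardiac_manifestations = FALSE) {
  list(ever_treated = ever_treated,
       treated_within_3_months = treated_within_3_months,
       acute_lofgren = acute_lofgren,
       remitting_no_active_disease_gt_1yr = remitting_no_active_disease_gt_1yr,
       cardiac_manifestations = cardiac_manifestations)
}

#' Construct and validate a patient record
#'
#' One record per patient, holding the structured EMR extract from which
#' every classification is derived: ICD claims, present clinical and
#' radiological feature flags, biopsy records, PFT measurements, chest
#' imaging findings, treatment/course history and demographics.
#'
#' @param patient_id Opaque unique identifier.
#' @param site Clinical site, `"SF"` or `"PA"`.
#' @param sex `"male"` or `"female"`.
#' @param race One of `african_american`, `non_hispanic_white`,
#'   `hispanic_white`, `unknown`, `other`.
#' @param age_years Age in years (0–120).
#' @param claims Data frame from [icd_claims()].
#' @param clinical_flags Character vector of *present* clinical features
#'   (subset of [clinical_features()], no duplicates).
#' @param radiologic_flags Character vector of *present* radiological
#'   features (subset of [radiologic_features()]).
#' @param biopsies Data frame from [biopsy_records()].
#' @param pft List from [pft_measurements()].
#' @param imaging List from [imaging_findings()].
#' @param course List from [clinical_course()].
#' @return A validated object of class `patient_record`.
#' @seealso [validate_patient_record()], [read_cohort()]
#' @examples
#' rec <- patient_record("P1", claims = icd_claims("D86.0"),
#'                       radiologic_flags = "bilateral_hilar_lymphadenopathy")
#' index_of_suspicion(rec)
#' @export
patient_record <- function(patient_id, site = "SF", sex = "male",
                           race = "unknown", age_years = 60,
                           claims = icd_claims(),
                           clinical_flags = character(),
                           radiologic_flags = character(),
                           biopsies = biopsy_records(),
                           pft = pft_measurements(),
                           imaging = imaging_findings(),
                           course = clinical_course()) {
  rec <- structure(list(
    patient_id = as.character(patient_id), site = site, sex = sex,
    race = race, age_years = as.numeric(age_years), claims = claims,
    # flag sets are stored in sorted order so records have one canonical form
    clinical_flags = sort(as.character(clinical_flags)),
    radiologic_flags = sort(as.character(radiologic_flags)),
    biopsies = biopsies, pft = pft, imaging = imaging, course = course),
    class = "patient_record")
  validate_patient_record(rec)
  rec
}

#' Validate a patient record against the domain invariants
#'
#' Checks every structural invariant of the record model: vocabulary
#' membership and uniqueness of feature flags, claim code shape, biopsy
#' enum fields, strictly positive LLN values, the
#' normal-radiograph-excludes-findings rule, and
#' treated-within-3-months-implies-ever-treated. Errors name the patient
#' and the offending field.
#'
#' @param rec A `patient_record`.
#' @return `rec`, invisibly, if valid; otherwise an error.
#' @export
validate_patient_record <- function(rec) {
  id <- rec$patient_id
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("patient_id must be a non-empty string", call. = FALSE)
  if (!(rec$site %in% .SITES)) .stop_field(id, "site", "must be 'SF' or 'PA'")
  if (!(rec$sex %in% .SEXES)) .stop_field(id, "sex", "must be 'male' or 'female'")
  if (!(rec$race %in% .RACES))
    .stop_field(id, "race", paste("must be one of", paste(.RACES, collapse = ", ")))
  if (!is.numeric(rec$age_years) || length(rec$age_years) != 1L ||
      is.na(rec$age_years) || rec$age_years < 0 || rec$age_years > 120)
    .stop_field(id, "age_years", "must be a number in [0, 120]")

  cl <- rec$claims
  if (!is.data.frame(cl) || !all(c("code", "setting", "date") %in% names(cl)))
    .stop_field(id, "claims", "must be a data frame with code/setting/date")
  if (nrow(cl)) {
    bad <- is.na(cl$code) | !nzchar(cl$code) | grepl("\\s", cl$code) |
      cl$code != toupper(cl$code)
    if (any(bad))
      .stop_field(id, "claims$code",
                  "codes must be non-empty, uppercase, without whitespace")
    if (!all(cl$setting %in% .CLAIM_SETTINGS))
      .stop_field(id, "claims$setting", "must be 'inpatient' or 'outpatient'")
  }

  for (fld in c("clinical_flags", "radiologic_flags")) {
    vocab <- if (fld == "clinical_flags") .CLINICAL_FEATURES else .RADIOLOGIC_FEATURES
    v <- rec[[fld]]
    if (anyDuplicated(v)) .stop_field(id, fld, "duplicate feature flag")
    if (!all(v %in% vocab))
      .stop_field(id, fld, paste("unknown feature:",
                                 paste(setdiff(v, vocab), collapse = ", ")))
  }

  bx <- rec$biopsies
  if (!is.data.frame(bx) || !all(c("site", "result", "provenance") %in% names(bx)))
    .stop_field(id, "biopsies", "must be a data frame with site/result/provenance")
  if (nrow(bx)) {
    if (any(is.na(bx$site)) || !all(bx$site %in% .BIOPSY_SITES))
      .stop_field(id, "biopsies$site", "unknown or missing biopsy site")
    if (any(is.na(bx$result)) || !all(bx$result %in% .BIOPSY_RESULTS))
      .stop_field(id, "biopsies$result", "unknown or missing biopsy result")
    if (!all(bx$provenance %in% .BIOPSY_PROVENANCE))
      .stop_field(id, "biopsies$provenance", "must be 'primary' or 'secondary'")
  }

  p <- rec$pft
  if (!.is_flag(p$available)) .stop_field(id, "pft$available", "must be TRUE/FALSE")
  if (isTRUE(p$available)) {
    for (fld in c("fev1_fvc_lln", "fvc_lln", "tlc_lln", "dlco_lln_pct")) {
      v <- p[[fld]]
      if (!is.na(v) && v <= 0)
        .stop_field(id, paste0("pft$", fld), "LLN must be strictly positive")
    }
  }

  im <- rec$imaging
  for (fld in c("report_available", "cxr_normal",
                "hilar_mediastinal_nodal_enlargement", "parenchymal_disease",
                "fibrosis_end_stage"))
    if (!.is_flag(im[[fld]]))
      .stop_field(id, paste0("imaging$", fld), "must be TRUE/FALSE")
  if (im$cxr_normal && (im$hilar_mediastinal_nodal_enlargement ||
                        im$parenchymal_disease || im$fibrosis_end_stage))
    .stop_field(id, "imaging",
                "cxr_normal excludes nodal, parenchymal and fibrotic findings")

  co <- rec$course
  for (fld in c("ever_treated", "treated_within_3_months", "acute_lofgren",
                "remitting_no_active_disease_gt_1yr", "cardiac_manifestations"))
    if (!.is_flag(co[[fld]]))
      .stop_field(id, paste0("course$", fld), "must be TRUE/FALSE")
  if (co$treated_within_3_months && !co$ever_treated)
    .stop_field(id, "course", "treated_within_3_months implies ever_treated")

  invisible(rec)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> %s, %s, %s, %.1f y\n", x$patient_id,
              x$site, x$sex, x$race, x$age_years))
  cat(sprintf("  claims: %d | clinical flags: %d | radiologic flags: %d | biopsies: %d\n",
              nrow(x$claims), length(x$clinical_flags),
              length(x$radiologic_flags), nrow(x$biopsies)))
  invisible(x)
}

# Validate a full cohort: each record plus cohort-level id uniqueness.
validate_cohort <- function(records) {
  for (r in records) validate_patient_record(r)
  ids <- vapply(records, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  invisible(records)
}
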