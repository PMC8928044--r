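# The classification rule set: ICD capture, index of suspicion, case
# grouping, organ involvement, Scadding staging, PFT pattern and clinical
# phenotype groups. All functions are pure and deterministic.

#' Match sarcoidosis ICD codes in a patient's claims
#'
#' A claim qualifies when its code is exactly `"135"`, starts with
#' `"135."` (ICD-9 sarcoidosis with subcodes), or starts with `"D86"`
#' case-insensitively (ICD-10 with subcodes). Plain prefix matching on
#' `"135"` is deliberately avoided so that unrelated codes beginning with
#' the digits 135 cannot qualify. `icd_version_first` is the code system
#' of the earliest qualifying claim by date; claims without dates rank
#' earliest, and ties prefer ICD-9 (the only ordering consistent with a
#' cohort window that predates ICD-10 adoption).
#'
#' @param record A validated [patient_record()].
#' @return A list with `icd_captured` (logical) and `icd_version_first`
#'   (`"icd9"`, `"icd10"` or `"none"`).
#' @examples
#' match_icd_codes(patient_record("P1", claims = icd_claims("D86.0")))
#' @export
match_icd_codes <- function(record) {
  codes <- record$claims$code
  is9 <- codes == "135" | startsWith(codes, "135.")
  is10 <- startsWith(toupper(codes), "D86")
  qual <- is9 | is10
  if (!any(qual))
    return(list(icd_captured = FALSE, icd_version_first = "none"))
  version <- ifelse(is9[qual], "icd9", "icd10")
  dates <- record$claims$date[qual]
  # undated claims sort before dated ones; ICD-9 breaks ties
  date_key <- ifelse(is.na(dates) | !nzchar(dates), "", dates)
  ord <- order(date_key, match(version, c("icd9", "icd10")))
  list(icd_captured = TRUE, icd_version_first = version[ord[1L]])
}

#' Index of suspicion for sarcoidosis
#'
#' A patient is assigned a *high* index of suspicion when at least one of
#' the supportive clinical or radiological features is documented, and
#' *low* otherwise. Biopsy data are never consulted: the index is meant to
#' capture probable cases for whom no confirmatory biopsy exists, so it is
#' a function of clinical and radiographic information only.
#'
#' @param record A validated [patient_record()].
#' @return `"high"` or `"low"`.
#' @export
index_of_suspicion <- function(record) {
  if (length(record$clinical_flags) || length(record$radiologic_flags))
    "high" else "low"
}

# any biopsy documenting nonnecrotizing granuloma, primary or secondary
has_granuloma_biopsy <- function(record) {
  nrow(record$biopsies) > 0 &&
    any(record$biopsies$result == "nonnecrotizing_granuloma")
}

#' Three-way case classification
#'
#' High-index patients with a biopsy (primary or secondary provenance)
#' documenting nonnecrotizing granuloma are `confirmed_biopsy`; high-index
#' patients without such a biopsy are `probable_no_biopsy`; low-index
#' patients are `unlikely` regardless of biopsy findings (histopathology
#' without supportive clinical/radiological features does not make a
#' case).
#'
#' @param record A validated [patient_record()].
#' @return One of `"confirmed_biopsy"`, `"probable_no_biopsy"`,
#'   `"unlikely"`.
#' @export
classify_case <- function(record) {
  if (index_of_suspicion(record) == "low") return("unlikely")
  if (has_granuloma_biopsy(record)) "confirmed_biopsy" else "probable_no_biopsy"
}

#' Organ involvement assessment
#'
#' For each organ, involvement holds when a granulomatous biopsy was taken
#' at one of the organ's qualifying sites, or any of the organ's clinical
#' or radiologic criteria flags is present (see [organ_criteria()] for the
#' full mapping).
#'
#' @param record A validated [patient_record()].
#' @return Character vector of involved organs (subset of
#'   [sarcoidosis_organs()]).
#' @export
assess_organ_involvement <- function(record) {
  bx <- record$biopsies
  gran_sites <- bx$site[bx$result == "nonnecrotizing_granuloma"]
  involved <- vapply(.ORGANS, function(org) {
    cr <- .ORGAN_CRITERIA[[org]]
    any(gran_sites %in% cr$biopsy_sites) ||
      any(record$clinical_flags %in% cr$clinical) ||
      any(record$radiologic_flags %in% cr$radiologic)
  }, logical(1))
  .ORGANS[involved]
}

#' Multi-organ phenotype predicate
#'
#' Multi-organ disease is defined as involvement of at least 3 organs.
#'
#' @param organs Character vector of involved organs.
#' @return Logical.
#' @export
is_multi_organ <- function(organs) {
  stopifnot(all(organs %in% .ORGANS))
  length(unique(organs)) >= 3L
}

#' Scadding stage from chest imaging findings
#'
#' Stage 0: normal radiograph; stage I: hilar/mediastinal nodal
#' enlargement only; stage II: nodal enlargement and parenchymal disease;
#' stage III: parenchymal disease only; stage IV: end-stage fibrotic lung
#' disease (dominant over coexisting findings); `missing` when no imaging
#' report is available.
#'
#' @param imaging An [imaging_findings()] list.
#' @return One of `"stage0"` ... `"stage4"`, `"missing"`.
#' @export
scadding_stage <- function(imaging) {
  if (!isTRUE(imaging$report_available)) return("missing")
  if (imaging$fibrosis_end_stage) return("stage4")
  nodal <- imaging$hilar_mediastinal_nodal_enlargement
  parench <- imaging$parenchymal_disease
  if (nodal && parench) return("stage2")
  if (parench) return("stage3")
  if (nodal) return("stage1")
  if (imaging$cxr_normal) return("stage0")
  stop("inconsistent imaging record: report available but no finding set ",
       "and radiograph not marked normal", call. = FALSE)
}

#' Pulmonary function test pattern
#'
#' Obstruction is FEV1/FVC below its lower limit of normal; restriction is
#' TLC below its LLN when TLC was measured, otherwise FVC below its LLN.
#' Both give `mixed`, exactly one gives that pattern, neither gives
#' `normal`; `missing` when no PFT is available. An isolated low diffusing
#' capacity with normal mechanics is classified `normal` for the four-level
#' pattern — report it separately via [pft_low_dlco()].
#'
#' @param pft A [pft_measurements()] list.
#' @return One of `"obstructive"`, `"restrictive"`, `"mixed"`, `"normal"`,
#'   `"missing"`.
#' @export
pft_pattern <- function(pft) {
  if (!isTRUE(pft$available)) return("missing")
  if (is.na(pft$fev1_fvc_ratio) || is.na(pft$fev1_fvc_lln))
    stop("PFT marked available but FEV1/FVC ratio or its LLN is absent",
         call. = FALSE)
  obstruction <- pft$fev1_fvc_ratio < pft$fev1_fvc_lln
  if (!is.na(pft$tlc) && !is.na(pft$tlc_lln)) {
    restriction <- pft$tlc < pft$tlc_lln
  } else {
    if (is.na(pft$fvc) || is.na(pft$fvc_lln))
      stop("PFT marked available but neither TLC nor FVC (with LLN) present",
           call. = FALSE)
    restriction <- pft$fvc < pft$fvc_lln
  }
  if (obstruction && restriction) return("mixed")
  if (obstruction) return("obstructive")
  if (restriction) return("restrictive")
  "normal"
}

#' @rdname pft_pattern
#' @return `pft_low_dlco()`: logical, `TRUE` when the diffusing capacity
#'   is measured and below its LLN; `NA` when not measured.
#' @export
pft_low_dlco <- function(pft) {
  if (!isTRUE(pft$available) || is.na(pft$dlco_pct_predicted) ||
      is.na(pft$dlco_lln_pct)) return(NA)
  pft$dlco_pct_predicted < pft$dlco_lln_pct
}

#' Clinical phenotype group assignment
#'
#' Assigns the nine (non-exclusive) clinical phenotype groups to a case
#' already adjudicated as sarcoidosis: 1 multi-organ (>= 3 organs); 2
#' nonacute stage I never treated; 3 stage II–III treated (ever); 4 stage
#' II–III never treated; 5 stage IV treated; 6 stage IV never treated; 7
#' acute (Lofgren); 8 remitting (> 1 year without active disease) and not
#' treated within 3 months of review; 9 cardiac manifestations, treated.
#' A patient may belong to several groups.
#'
#' @param record A validated [patient_record()].
#' @param partial A list with the already-derived fields `case_group`,
#'   `scadding` and `multi_organ` (as produced inside [classify_cohort()]).
#' @return Integer vector of group numbers (possibly empty).
#' @export
assign_phenotype_groups <- function(record, partial) {
  if (partial$case_group == "unlikely")
    stop("phenotype groups are defined only for sarcoidosis cases ",
         "(confirmed or probable), not 'unlikely'", call. = FALSE)
  co <- record$course
  st <- partial$scadding
  nonacute <- !co$acute_lofgren
  groups <- c(
    if (partial$multi_organ) 1L,
    if (nonacute && st == "stage1" && !co$ever_treated) 2L,
    if (st %in% c("stage2", "stage3") && co$ever_treated) 3L,
    if (st %in% c("stage2", "stage3") && !co$ever_treated) 4L,
    if (st == "stage4" && co$ever_treated) 5L,
    if (st == "stage4" && !co$ever_treated) 6L,
    if (co$acute_lofgren) 7L,
    if (co$remitting_no_active_disease_gt_1yr && !co$treated_within_3_months) 8L,
    if (co$cardiac_manifestations && co$ever_treated) 9L)
  as.integer(groups)
}

#' Classify a cohort of patient records
#'
#' Runs the full rule set over a cohort: ICD capture, index of suspicion,
#' three-way case grouping, organ involvement, multi-organ phenotype,
#' Scadding stage, PFT pattern and clinical phenotype groups. Phenotype
#' groups are assigned only to sarcoidosis cases (confirmed or probable);
#' `unlikely` patients get an empty group set, a defined `organs` set and
#' stage/pattern fields, so the output is rectangular.
#'
#' @param records List of validated [patient_record()] objects.
#' @return A data frame of class `sarc_classification` with one row per
#'   patient and columns `patient_id`, `icd_captured`, `icd_version_first`,
#'   `index_of_suspicion`, `case_group`, `granuloma_documented`, `organs`
#'   (list column), `n_organs`, `multi_organ`, `scadding`, `pft_pattern`,
#'   `low_dlco` and `phenotype_groups` (list column).
#' @examples
#' cohort <- build_fixture_cohort()
#' cls <- classify_cohort(cohort)
#' summary(cls)
#' @export
classify_cohort <- function(records) {
  validate_cohort(records)
  rows <- lapply(records, function(rec) {
    icd <- match_icd_codes(rec)
    idx <- index_of_suspicion(rec)
    grp <- classify_case(rec)
    organs <- assess_organ_involvement(rec)
    multi <- is_multi_organ(organs)
    st <- scadding_stage(rec$imaging)
    pat <- pft_pattern(rec$pft)
    pheno <- if (grp == "unlikely") integer() else
      assign_phenotype_groups(rec, list(case_group = grp, scadding = st,
                                        multi_organ = multi))
    # classification-level invariants
    stopifnot((grp == "unlikely") == (idx == "low"),
              multi == (length(organs) >= 3L),
              (1L %in% pheno) == (multi && grp != "unlikely"))
    list(patient_id = rec$patient_id, icd_captured = icd$icd_captured,
         icd_version_first = icd$icd_version_first,
         index_of_suspicion = idx, case_group = grp,
         granuloma_documented = has_granuloma_biopsy(rec), organs = organs,
         n_organs = length(organs), multi_organ = multi, scadding = st,
         pft_pattern = pat, low_dlco = pft_low_dlco(rec$pft),
         phenotype_groups = pheno)
  })
  out <- data.frame(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    icd_captured = vapply(rows, `[[`, logical(1), "icd_captured"),
    icd_version_first = vapply(rows, `[[`, character(1), "icd_version_first"),
    index_of_suspicion = vapply(rows, `[[`, character(1), "index_of_suspicion"),
    case_group = vapply(rows, `[[`, character(1), "case_group"),
    granuloma_documented = vapply(rows, `[[`, logical(1),
                                  "granuloma_documented"),
    n_organs = vapply(rows, `[[`, integer(1), "n_organs"),
    multi_organ = vapply(rows, `[[`, logical(1), "multi_organ"),
    scadding = vapply(rows, `[[`, character(1), "scadding"),
    pft_pattern = vapply(rows, `[[`, character(1), "pft_pattern"),
    low_dlco = vapply(rows, `[[`, logical(1), "low_dlco"),
    stringsAsFactors = FALSE)
  out$organs <- lapply(rows, `[[`, "organs")
  out$phenotype_groups <- lapply(rows, `[[`, "phenotype_groups")
  class(out) <- c("sarc_classification", "data.frame")
  out
}

#' @export
print.sarc_classification <- function(x, ...) {
  cat(sprintf("<sarc_classification> %d patients\n", nrow(x)))
  tab <- table(factor(x$case_group, levels = .CASE_GROUPS))
  cat(sprintf("  confirmed_biopsy: %d | probable_no_biopsy: %d | unlikely: %d\n",
              tab[["confirmed_biopsy"]], tab[["probable_no_biopsy"]],
              tab[["unlikely"]]))
  invisible(x)
}

#' @export
summary.sarc_classification <- function(object, ...) {
  high <- object[object$index_of_suspicion == "high", , drop = FALSE]
  groups <- tabulate(unlist(high$phenotype_groups), nbins = 9L)
  out <- list(
    n = nrow(object),
    case_group = table(factor(object$case_group, levels = .CASE_GROUPS)),
    icd_version_high = table(factor(high$icd_version_first,
                                    levels = c("icd9", "icd10", "none"))),
    multi_organ = sum(high$multi_organ),
    pulmonary = sum(vapply(high$organs, function(o) "lung" %in% o, logical(1))),
    scadding = table(factor(high$scadding, levels = .SCADDING_LEVELS)),
    pft_pattern = table(factor(high$pft_pattern, levels = .PFT_LEVELS)),
    phenotype_groups = stats::setNames(groups, paste0("group", 1:9)))
  class(out) <- "summary.sarc_classification"
  out
}

#' @export
print.summary.sarc_classification <- function(x, ...) {
  cat(sprintf("Cohort of %d ICD-captured patients\n", x$n))
  cat("Case groups:\n"); print(x$case_group)
  cat("ICD version of first qualifying claim (high-index patients):\n")
  print(x$icd_version_high)
  cat(sprintf("Pulmonary involvement: %d | multi-organ (>=3): %d\n",
              x$pulmonary, x$multi_organ))
  cat("Scadding stage (high-index):\n"); print(x$scadding)
  cat("PFT pattern (high-index):\n"); print(x$pft_pattern)
  cat("Clinical phenotype groups (non-exclusive):\n")
  print(x$phenotype_groups)
  invisible(x)
}
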