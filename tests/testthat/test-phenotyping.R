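test_that("ICD capture matches 135/135.x/D86x and nothing else", {
  rec <- function(codes, dates = NA_character_)
    make_record("P1", claims = icd_claims(codes, date = dates))
  expect_identical(match_icd_codes(rec("D86.0")),
                   list(icd_captured = TRUE, icd_version_first = "icd10"))
  expect_identical(match_icd_codes(rec("J44.9")),
                   list(icd_captured = FALSE, icd_version_first = "none"))
  expect_identical(match_icd_codes(make_record("P1", claims = icd_claims()))$
                     icd_captured, FALSE)
  # "135" must be exact or a "135." prefix: ICD-10 codes that merely start
  # with the digits 135 do not qualify
  expect_false(match_icd_codes(rec("1355"))$icd_captured)
  expect_true(match_icd_codes(rec("135.1"))$icd_captured)
  # D86 matching ignores case at the claim-matching layer
  r <- make_record("P1")
  r$claims <- icd_claims("D86")   # base code without subcode
  expect_identical(match_icd_codes(r)$icd_version_first, "icd10")
})

test_that("first-version tie-breaking prefers ICD-9 when dates are absent", {
  rec <- make_record("P1", claims = icd_claims(c("135.1", "D86"),
                                               c("inpatient", "outpatient")))
  expect_identical(match_icd_codes(rec)$icd_version_first, "icd9")
  # with dates, the earliest qualifying claim wins regardless of version
  dated <- make_record("P1", claims = icd_claims(
    c("135", "D86.0"), date = c("2016-05-01", "2015-01-01")))
  expect_identical(match_icd_codes(dated)$icd_version_first, "icd10")
  # an undated qualifying claim ranks before any dated one
  mixed <- make_record("P1", claims = icd_claims(
    c("D86.0", "135"), date = c(NA, "1995-01-01")))
  expect_identical(match_icd_codes(mixed)$icd_version_first, "icd10")
})

test_that("index of suspicion is any-feature-present and biopsy-blind", {
  expect_identical(index_of_suspicion(
    make_record("P1", radiologic = "bilateral_hilar_lymphadenopathy")), "high")
  expect_identical(index_of_suspicion(make_record("P1")), "low")
  # a granulomatous biopsy alone never raises the index
  gran <- biopsy_records("lung", "nonnecrotizing_granuloma")
  expect_identical(index_of_suspicion(make_record("P1", biopsies = gran)),
                   "low")
})

test_that("case grouping follows index plus histopathology", {
  gran <- biopsy_records("lung", "nonnecrotizing_granuloma")
  other <- biopsy_records("lung", "other_finding")
  high <- function(b) make_record("P1", clinical = "respiratory_symptoms",
                                  biopsies = b)
  expect_identical(classify_case(high(gran)), "confirmed_biopsy")
  expect_identical(classify_case(high(biopsy_records())), "probable_no_biopsy")
  # a biopsy without granulomas does not confirm
  expect_identical(classify_case(high(other)), "probable_no_biopsy")
  # secondary-provenance histopathology confirms just like primary
  gran2 <- biopsy_records("skin", "nonnecrotizing_granuloma", "secondary")
  expect_identical(classify_case(high(gran2)), "confirmed_biopsy")
  expect_identical(classify_case(make_record("P1", biopsies = gran)),
                   "unlikely")
})

test_that("organ involvement follows the per-organ criteria mapping", {
  expect_identical(assess_organ_involvement(
    make_record("P1", clinical = "pft_abnormal")), "lung")
  expect_setequal(assess_organ_involvement(make_record("P1",
    clinical = c("lupus_pernio_or_erythema_nodosum", "ocular_inflammation"),
    radiologic = "cardiac_mri_or_pet_consistent")),
    c("skin", "eye", "cardiac"))
  expect_length(assess_organ_involvement(make_record("P1")), 0)
  # biopsy-driven involvement needs granulomas at a qualifying site
  expect_identical(assess_organ_involvement(make_record("P1",
    biopsies = biopsy_records("heart_pericardium",
                              "nonnecrotizing_granuloma"))), "cardiac")
  expect_length(assess_organ_involvement(make_record("P1",
    biopsies = biopsy_records("lung", "other_finding"))), 0)
  expect_length(assess_organ_involvement(make_record("P1",
    biopsies = biopsy_records("other", "nonnecrotizing_granuloma"))), 0)
  # respiratory symptoms support the index but are not an organ criterion
  expect_length(assess_organ_involvement(
    make_record("P1", clinical = "respiratory_symptoms")), 0)
})

test_that("multi-organ means three or more organs", {
  expect_false(is_multi_organ(c("lung", "skin")))
  expect_true(is_multi_organ(c("lung", "skin", "eye")))
  expect_false(is_multi_organ(character()))
  expect_error(is_multi_organ("pancreas"))
})

test_that("Scadding staging covers all findings with stage IV dominant", {
  expect_identical(scadding_stage(imaging_findings(TRUE, cxr_normal = TRUE)),
                   "stage0")
  expect_identical(scadding_stage(imaging_findings(TRUE,
    hilar_mediastinal_nodal_enlargement = TRUE)), "stage1")
  expect_identical(scadding_stage(imaging_findings(TRUE,
    hilar_mediastinal_nodal_enlargement = TRUE, parenchymal_disease = TRUE)),
    "stage2")
  expect_identical(scadding_stage(imaging_findings(TRUE,
    parenchymal_disease = TRUE)), "stage3")
  expect_identical(scadding_stage(imaging_findings(TRUE,
    hilar_mediastinal_nodal_enlargement = TRUE, parenchymal_disease = TRUE,
    fibrosis_end_stage = TRUE)), "stage4")
  expect_identical(scadding_stage(imaging_findings(FALSE)), "missing")
  expect_error(scadding_stage(imaging_findings(TRUE)), "inconsistent")
})

test_that("PFT pattern compares each value against its own LLN", {
  pft <- function(ratio, lln = 0.7, tlc = NA, tlc_lln = NA, fvc = NA,
                  fvc_lln = NA)
    pft_measurements(TRUE, fev1_fvc_ratio = ratio, fev1_fvc_lln = lln,
                     tlc = tlc, tlc_lln = tlc_lln, fvc = fvc,
                     fvc_lln = fvc_lln)
  expect_identical(pft_pattern(pft(0.60, 0.70, tlc = 6.0, tlc_lln = 5.0)),
                   "obstructive")
  expect_identical(pft_pattern(pft(0.78, 0.70, tlc = 3.9, tlc_lln = 5.0)),
                   "restrictive")
  expect_identical(pft_pattern(pft(0.60, 0.70, tlc = 3.9, tlc_lln = 5.0)),
                   "mixed")
  expect_identical(pft_pattern(pft(0.78, 0.70, tlc = 6.0, tlc_lln = 5.0)),
                   "normal")
  # FVC stands in for restriction when TLC was not measured
  expect_identical(pft_pattern(pft(0.78, 0.70, fvc = 2.0, fvc_lln = 3.0)),
                   "restrictive")
  expect_identical(pft_pattern(pft_measurements(available = FALSE)), "missing")
  expect_error(pft_pattern(pft_measurements(available = TRUE)), "available")
  expect_error(pft_pattern(pft(0.78, 0.70)), "neither TLC nor FVC")
})

test_that("isolated low DLCO is reported separately, not as a pattern", {
  p <- pft_measurements(TRUE, fev1_fvc_ratio = 0.78, fev1_fvc_lln = 0.70,
                        tlc = 6, tlc_lln = 5, dlco_pct_predicted = 60,
                        dlco_lln_pct = 75)
  expect_identical(pft_pattern(p), "normal")
  expect_true(pft_low_dlco(p))
  expect_true(is.na(pft_low_dlco(pft_measurements(available = FALSE))))
})

test_that("phenotype groups are non-exclusive and follow stage/treatment", {
  rec <- function(...) make_record("P1", clinical = "respiratory_symptoms",
                                   course = clinical_course(...))
  partial <- function(st, multi = FALSE, grp = "probable_no_biopsy")
    list(case_group = grp, scadding = st, multi_organ = multi)
  expect_identical(assign_phenotype_groups(rec(ever_treated = TRUE),
                                           partial("stage2")), 3L)
  expect_identical(assign_phenotype_groups(rec(), partial("stage1", TRUE)),
                   c(1L, 2L))
  expect_true(7L %in% assign_phenotype_groups(rec(acute_lofgren = TRUE),
                                              partial("stage3")))
  # stage IV splits into treated / untreated groups 5 and 6
  expect_identical(assign_phenotype_groups(rec(ever_treated = TRUE),
                                           partial("stage4")), 5L)
  expect_identical(assign_phenotype_groups(rec(), partial("stage4")), 6L)
  # remitting counts only without treatment in the last 3 months
  expect_identical(assign_phenotype_groups(
    rec(remitting_no_active_disease_gt_1yr = TRUE), partial("missing")), 8L)
  expect_length(assign_phenotype_groups(
    rec(ever_treated = TRUE, treated_within_3_months = TRUE,
        remitting_no_active_disease_gt_1yr = TRUE), partial("missing")), 0)
  expect_identical(assign_phenotype_groups(
    rec(ever_treated = TRUE, cardiac_manifestations = TRUE),
    partial("stage0")), 9L)
  expect_error(assign_phenotype_groups(rec(), partial("stage1",
                                                      grp = "unlikely")),
               "unlikely")
})

test_that("adding features never lowers the index; removing all forces low", {
  set.seed(7)
  all_feats <- c(clinical_features(), radiologic_features())
  for (i in 1:60) {
    rec <- random_record(sprintf("M%02d", i))
    before <- index_of_suspicion(rec)
    extra <- sample(all_feats, 1)
    rec2 <- rec
    if (extra %in% clinical_features()) {
      rec2$clinical_flags <- sort(union(rec2$clinical_flags, extra))
    } else {
      rec2$radiologic_flags <- sort(union(rec2$radiologic_flags, extra))
    }
    expect_identical(index_of_suspicion(rec2), "high")
    if (before == "high") expect_identical(index_of_suspicion(rec2), "high")
    rec3 <- rec
    rec3$clinical_flags <- character()
    rec3$radiologic_flags <- character()
    expect_identical(index_of_suspicion(rec3), "low")
  }
})

test_that("the index of suspicion is invariant to any biopsy change", {
  set.seed(8)
  for (i in 1:60) {
    rec <- random_record(sprintf("B%02d", i))
    idx <- index_of_suspicion(rec)
    rec$biopsies <- biopsy_records("lung", "nonnecrotizing_granuloma")
    expect_identical(index_of_suspicion(rec), idx)
    rec$biopsies <- biopsy_records()
    expect_identical(index_of_suspicion(rec), idx)
  }
})

test_that("case groups partition the cohort by index of suspicion", {
  set.seed(9)
  recs <- lapply(sprintf("C%02d", 1:80), random_record)
  cls <- classify_cohort(recs)
  high <- cls$index_of_suspicion == "high"
  expect_true(all(cls$case_group[high] %in%
                    c("confirmed_biopsy", "probable_no_biopsy")))
  expect_true(all(cls$case_group[!high] == "unlikely"))
  expect_identical(sum(high), sum(cls$case_group != "unlikely"))
})

test_that("classify_cohort agrees with the literal-condition oracle", {
  set.seed(10)
  for (trial in 1:40) {
    n <- sample(1:6, 1)
    recs <- lapply(sprintf("O%d_%d", trial, seq_len(n)), random_record)
    cls <- classify_cohort(recs)
    for (j in seq_len(n)) {
      expect_identical(cls$index_of_suspicion[j], oracle_index(recs[[j]]))
      expect_identical(cls$case_group[j], oracle_case(recs[[j]]))
      expect_setequal(cls$organs[[j]], oracle_organs(recs[[j]]))
      expect_identical(cls$multi_organ[j],
                       length(oracle_organs(recs[[j]])) >= 3)
    }
  }
})

test_that("classify_cohort handles the empty cohort", {
  cls <- classify_cohort(list())
  expect_s3_class(cls, "sarc_classification")
  expect_identical(nrow(cls), 0L)
})
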