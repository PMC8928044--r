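# Deterministic 200-patient synthetic fixture cohort. Records store raw
# features only (claims, flags, biopsies, measurements); every contractual
# marginal in the manifest is re-derived by the real pipeline. The joint
# assignment across characteristics is one concrete solution of the
# marginal constraints: only the manifest's marginals are contractual, not
# the per-patient joint layout.
#
# Layout (158 high-index + 42 low-index):
#   confirmed (142): organ categories lung-only 86, multi-organ pulmonary
#     without cardiac 39, pulmonary+cardiac 4, cardiac without pulmonary 2,
#     neither 11. The 13 non-pulmonary confirmed and 2 non-pulmonary
#     probable patients carry no imaging report and no PFT, so stage and
#     pattern marginals are carried entirely by the 143 pulmonary cases.
#   probable (16): no biopsy records at all.
#   unlikely (42): zero feature flags and zero biopsies.

.STAGES5 <- c("stage0", "stage1", "stage2", "stage3", "stage4")

.fixture_plan <- function() {
  # --- confirmed (142) ---
  cat_c <- rep(c("lung", "mp_nc", "mp_c", "mc_np", "m_nn"),
               c(86, 39, 4, 2, 11))
  st_c <- c(rep(.STAGES5, c(15, 16, 28, 12, 15)),   # lung-only
            rep(.STAGES5, c(7, 7, 13, 5, 7)),       # multi, pulm w/o cardiac
            rep("stage2", 4),                        # multi, pulm + cardiac
            rep("missing", 13))                      # non-pulmonary
  pft_c <- c(rep(c("obstructive", "restrictive", "mixed", "normal", "missing"),
                 c(27, 30, 20, 39, 13)),             # pulmonary 129
             rep("missing", 13))                     # non-pulmonary
  treated_c <- rep(FALSE, 142)
  s1 <- which(st_c == "stage1")
  treated_c[s1] <- TRUE
  treated_c[s1[1:6]] <- FALSE                        # 6 stage-I never treated
  s23 <- which(st_c %in% c("stage2", "stage3"))
  mpc <- which(cat_c == "mp_c")
  other23 <- setdiff(s23, mpc)
  treated_c[c(mpc, other23[1:38])] <- TRUE           # 42 stage II-III treated
  s4 <- which(st_c == "stage4")
  treated_c[s4[1:17]] <- TRUE                        # 17 stage IV treated
  treated_c[cat_c == "mc_np"] <- TRUE                # cardiac cases treated
  remit_c <- st_c == "stage0"                        # 22 remitting ...
  s1t <- which(st_c == "stage1" & treated_c)
  remit_c[s1t[1:8]] <- TRUE                          # ... plus 8 = 30
  cardiac_c <- cat_c %in% c("mp_c", "mc_np")         # 6 cardiac, all treated
  sex_c <- rep("male", 142)
  sex_c[seq(9, 135, by = 9)] <- "female"             # 15 women
  race_c <- rep(.RACES, c(74, 49, 3, 12, 4))
  icd_c <- rep(c("icd9", "icd10"), c(98, 44))
  age_c <- rep(c(54.7, 76.3), length.out = 142)      # mean 65.5, SD 10.8

  # --- probable (16): no biopsies ---
  cat_p <- rep(c("lung", "mp_nc", "m_nn"), c(12, 2, 2))
  st_p <- c(rep(c("stage0", "stage1", "stage3"), c(5, 3, 4)),
            rep("stage2", 2), rep("missing", 2))
  pft_p <- c("restrictive", "restrictive", "restrictive", "mixed", "mixed",
             "obstructive", "restrictive", "restrictive",
             "restrictive", "mixed", "normal", "missing",
             "mixed", "mixed", "missing", "missing")
  treated_p <- rep(FALSE, 16)
  treated_p[which(st_p == "stage1")[3]] <- TRUE      # 2 stage-I untreated
  s23p <- which(st_p %in% c("stage2", "stage3"))
  treated_p[s23p[1:3]] <- TRUE                       # 3 stage II-III treated
  remit_p <- st_p == "stage0"                        # 5 remitting
  cardiac_p <- rep(FALSE, 16)
  sex_p <- rep("male", 16); sex_p[8] <- "female"
  race_p <- rep(.RACES, c(11, 3, 0, 2, 0))
  icd_p <- rep(c("icd9", "icd10"), c(10, 6))
  age_p <- rep(c(59.3, 79.3), length.out = 16)       # mean 69.3, SD 10.3

  # --- unlikely (42): zero flags, zero biopsies ---
  n_u <- 42
  sex_u <- rep("male", n_u); sex_u[c(10, 20, 30, 40)] <- "female"
  data.frame(
    group = rep(c("confirmed", "probable", "unlikely"), c(142, 16, n_u)),
    category = c(cat_c, cat_p, rep("none", n_u)),
    scadding = c(st_c, st_p, rep("missing", n_u)),
    pft = c(pft_c, pft_p, rep("missing", n_u)),
    treated = c(treated_c, treated_p, rep(FALSE, n_u)),
    remitting = c(remit_c, remit_p, rep(FALSE, n_u)),
    cardiac = c(cardiac_c, cardiac_p, rep(FALSE, n_u)),
    icd = c(icd_c, icd_p, rep(c("icd9", "icd10"), c(30, 12))),
    sex = c(sex_c, sex_p, sex_u),
    race = c(race_c, race_p, rep(.RACES, c(20, 12, 2, 6, 2))),
    age = c(age_c, age_p, round(seq(48, 89, length.out = n_u), 1)),
    stringsAsFactors = FALSE)
}

.fixture_pft <- function(pattern) {
  base <- list(fev1_fvc_lln = 0.70, fvc_lln = 3.1, tlc_lln = 5.2,
               dlco_lln_pct = 75)
  vals <- switch(pattern,
    obstructive = list(fev1_fvc_ratio = 0.58, fvc = 3.9, tlc = 6.1,
                       dlco_pct_predicted = 82),
    restrictive = list(fev1_fvc_ratio = 0.79, fvc = 2.6, tlc = 4.1,
                       dlco_pct_predicted = 62),
    mixed = list(fev1_fvc_ratio = 0.58, fvc = 2.6, tlc = 4.1,
                 dlco_pct_predicted = 58),
    normal = list(fev1_fvc_ratio = 0.79, fvc = 3.9, tlc = 6.1,
                  dlco_pct_predicted = 82),
    missing = NULL)
  if (is.null(vals)) return(pft_measurements(available = FALSE))
  do.call(pft_measurements, c(list(available = TRUE), base, vals))
}

.fixture_imaging <- function(stage) {
  switch(stage,
    missing = imaging_findings(report_available = FALSE),
    stage0 = imaging_findings(TRUE, cxr_normal = TRUE),
    stage1 = imaging_findings(TRUE, hilar_mediastinal_nodal_enlargement = TRUE),
    stage2 = imaging_findings(TRUE, hilar_mediastinal_nodal_enlargement = TRUE,
                              parenchymal_disease = TRUE),
    stage3 = imaging_findings(TRUE, parenchymal_disease = TRUE),
    stage4 = imaging_findings(TRUE, parenchymal_disease = TRUE,
                              fibrosis_end_stage = TRUE))
}

# multi-organ feature templates; each names the clinical/radiologic flags
# that create the extra organs, and the biopsy site used for confirmed
# cases in the "neither pulmonary nor cardiac" category
.MPNC_TEMPLATES <- list(
  list(clin = c("lupus_pernio_or_erythema_nodosum", "ocular_inflammation"),
       rad = character()),                                   # skin + eye
  list(clin = c("lupus_pernio_or_erythema_nodosum", "hepatosplenomegaly"),
       rad = character()),                                   # skin + liver
  list(clin = "ocular_inflammation", rad = "brain_mri_inflammation"))
.MNN_TEMPLATES <- list(
  list(clin = c("lupus_pernio_or_erythema_nodosum", "ocular_inflammation",
                "hepatosplenomegaly"), rad = character(), biopsy = "skin"),
  list(clin = "lupus_pernio_or_erythema_nodosum",
       rad = c("liver_spleen_lesions", "brain_mri_inflammation"),
       biopsy = "liver"),
  list(clin = c("ocular_inflammation", "laryngoscopy_granulomatous"),
       rad = "liver_spleen_lesions", biopsy = "ear_nose_throat"),
  list(clin = c("lupus_pernio_or_erythema_nodosum", "ocular_inflammation"),
       rad = "brain_mri_inflammation", biopsy = "skin"))

.STAGE_RAD_FLAGS <- list(
  stage0 = character(), missing = character(),
  stage1 = "bilateral_hilar_lymphadenopathy",
  stage2 = c("bilateral_hilar_lymphadenopathy",
             "diffuse_infiltrates_or_fibrosis"),
  stage3 = "diffuse_infiltrates_or_fibrosis",
  stage4 = "diffuse_infiltrates_or_fibrosis")

#' Build the packaged synthetic fixture cohort
#'
#' Constructs, fully deterministically (no randomness), the 200-patient
#' synthetic validation cohort shipped with the package: 100 patients per
#' clinical site, 158 with supportive clinical/radiological features (142
#' of whom carry a granulomatous biopsy, 16 without any biopsy) and 42
#' with neither features nor biopsies. Records hold raw fields only;
#' running [classify_cohort()] and [sarc_validate()] over them reproduces
#' every marginal in [fixture_manifest()]. Two builds are byte-identical.
#'
#' @param check Verify the manifest marginals after building (default
#'   `TRUE`); any violated marginal is a hard error naming the marginal.
#' @return A list of 200 [patient_record()] objects.
#' @examples
#' cohort <- build_fixture_cohort()
#' print(classify_cohort(cohort))
#' @export
build_fixture_cohort <- function(check = TRUE) {
  plan <- .fixture_plan()
  n <- nrow(plan)
  within_cat <- stats::ave(seq_len(n), plan$group, plan$category,
                           FUN = seq_along)
  icd10_idx <- cumsum(plan$icd == "icd10")
  d86_cycle <- c("D86.0", "D86.1", "D86.2", "D86.9")
  pulm_cats <- c("lung", "mp_nc", "mp_c")
  pulm_biopsy_idx <- cumsum(plan$group == "confirmed" &
                              plan$category %in% pulm_cats)

  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- plan[i, ]
    k <- within_cat[i]

    # claims: one qualifying claim per patient; the first five confirmed
    # patients carry a dated ICD-9 + ICD-10 pair to exercise date ordering
    setting <- if (i %% 2 == 1) "outpatient" else "inpatient"
    if (p$group == "confirmed" && i <= 5) {
      claims <- icd_claims(c("135", "D86.0"), c("inpatient", "outpatient"),
                           c("1998-03-14", "2016-09-01"))
    } else if (p$icd == "icd9") {
      claims <- icd_claims("135", setting)
    } else {
      claims <- icd_claims(d86_cycle[(icd10_idx[i] - 1L) %% 4L + 1L], setting)
    }

    clin <- character(); rad <- character(); biopsies <- biopsy_records()
    if (p$group != "unlikely") {
      rad <- .STAGE_RAD_FLAGS[[p$scadding]]
      if (p$pft %in% c("obstructive", "restrictive", "mixed"))
        clin <- c(clin, "pft_abnormal")
      if (p$category %in% pulm_cats)
        clin <- c(clin, "respiratory_symptoms")
      if (p$category == "mp_nc") {
        tpl <- .MPNC_TEMPLATES[[(k - 1L) %% 3L + 1L]]
        clin <- c(clin, tpl$clin); rad <- c(rad, tpl$rad)
        if (k %% 13L == 0L) rad <- c(rad, "liver_spleen_lesions")
      } else if (p$category == "mp_c") {
        clin <- c(clin, "cardiac_manifestation",
                  "lupus_pernio_or_erythema_nodosum")
        rad <- c(rad, "cardiac_mri_or_pet_consistent")
      } else if (p$category == "mc_np") {
        clin <- c(clin, "cardiac_manifestation",
                  "lupus_pernio_or_erythema_nodosum", "ocular_inflammation")
      } else if (p$category == "m_nn") {
        tpl <- .MNN_TEMPLATES[[(k - 1L) %% 4L + 1L]]
        clin <- c(clin, tpl$clin); rad <- c(rad, tpl$rad)
      } else if (p$category == "lung") {
        if (k %% 4L == 0L) clin <- c(clin, "calcium_vitd_abnormal")
        if (k %% 7L == 0L) clin <- c(clin, "ace_or_sil2r_elevated")
        if (k %% 10L == 0L) clin <- c(clin, "bal_lymphocytosis")
        if (k %% 6L == 0L) rad <- c(rad, "extrathoracic_lymphadenopathy")
      }
      if (p$group == "confirmed") {
        if (p$category %in% pulm_cats) {
          b <- pulm_biopsy_idx[i]
          site <- if (b %% 2L == 1L) "lung" else "mediastinal_hilar_node"
          prov <- if (b %% 5L == 0L) "secondary" else "primary"
          biopsies <- biopsy_records(site, "nonnecrotizing_granuloma", prov)
        } else if (p$category == "mc_np") {
          biopsies <- biopsy_records("heart_pericardium",
                                     "nonnecrotizing_granuloma", "primary")
        } else {
          tpl <- .MNN_TEMPLATES[[(k - 1L) %% 4L + 1L]]
          biopsies <- biopsy_records(tpl$biopsy, "nonnecrotizing_granuloma",
                                     if (k %% 3L == 0L) "secondary" else "primary")
        }
      }
    }

    records[[i]] <- patient_record(
      patient_id = sprintf("SARC-%03d", i),
      site = if (i %% 2 == 1) "SF" else "PA",
      sex = p$sex, race = p$race, age_years = p$age,
      claims = claims,
      clinical_flags = unique(clin), radiologic_flags = unique(rad),
      biopsies = biopsies,
      pft = .fixture_pft(p$pft),
      imaging = .fixture_imaging(p$scadding),
      course = clinical_course(
        ever_treated = p$treated,
        treated_within_3_months = p$treated && !p$remitting && i %% 3L == 0L,
        acute_lofgren = FALSE,
        remitting_no_active_disease_gt_1yr = p$remitting,
        cardiac_manifestations = p$cardiac))
  }

  if (check) {
    report <- check_fixture(records)
    if (!all(report$pass))
      stop("fixture internal consistency failure: ",
           paste(report$marginal[!report$pass], collapse = ", "),
           call. = FALSE)
  }
  records
}

#' Path to the shipped fixture cohort file
#'
#' The fixture cohort is also shipped as a CSV data file (the CSV dialect
#' of [write_cohort()]); it is byte-identical to
#' `write_cohort(build_fixture_cohort(), ...)`.
#'
#' @return Path to `fixture_cohort.csv` inside the installed package.
#' @export
fixture_cohort_path <- function() {
  system.file("extdata", "fixture_cohort.csv", package = "sarcphen",
              mustWork = TRUE)
}

#' Fixture manifest: contractual marginals of the synthetic cohort
#'
#' Reads the manifest shipped with the package: the named marginal counts
#' that the fixture cohort must reproduce when run through the real
#' pipeline (case groups, validation-table cells, ICD version split,
#' demographics, organ involvement, Scadding stages, PFT patterns,
#' phenotype groups and age summaries), plus the MD5 checksum of the
#' shipped cohort CSV.
#'
#' @return A list with `expected_marginals` (named numeric vector) and
#'   `checksum` (MD5 string of the shipped CSV).
#' @export
fixture_manifest <- function() {
  path <- system.file("extdata", "fixture-manifest.json",
                      package = "sarcphen", mustWork = TRUE)
  m <- jsonlite::fromJSON(path)
  m$expected_marginals <- unlist(m$expected_marginals)
  m
}

.fixture_observed <- function(records) {
  cls <- classify_cohort(records)
  high <- cls[cls$index_of_suspicion == "high", , drop = FALSE]
  conf <- cls$case_group == "confirmed_biopsy"
  prob <- cls$case_group == "probable_no_biopsy"
  gran <- vapply(records, has_granuloma_biopsy, logical(1))
  is_high <- cls$index_of_suspicion == "high"
  pulm <- vapply(cls$organs, function(o) "lung" %in% o, logical(1))
  sex <- vapply(records, `[[`, character(1), "sex")
  race <- vapply(records, `[[`, character(1), "race")
  site <- vapply(records, `[[`, character(1), "site")
  age <- vapply(records, `[[`, numeric(1), "age_years")
  groups <- tabulate(unlist(high$phenotype_groups), nbins = 9L)
  st_tab <- table(factor(high$scadding, levels = .SCADDING_LEVELS))
  pft_tab <- table(factor(high$pft_pattern, levels = .PFT_LEVELS))
  c(n_total = nrow(cls),
    n_site_sf = sum(site == "SF"), n_site_pa = sum(site == "PA"),
    n_high = sum(is_high), n_low = sum(!is_high),
    n_confirmed = sum(conf), n_probable = sum(prob),
    n_unlikely = sum(cls$case_group == "unlikely"),
    table_granuloma_high = sum(gran & is_high),
    table_granuloma_low = sum(gran & !is_high),
    table_nogranuloma_high = sum(!gran & is_high),
    table_nogranuloma_low = sum(!gran & !is_high),
    icd9_first_high = sum(high$icd_version_first == "icd9"),
    icd10_first_high = sum(high$icd_version_first == "icd10"),
    icd9_first_confirmed = sum(cls$icd_version_first == "icd9" & conf),
    male_high = sum(sex == "male" & is_high),
    male_confirmed = sum(sex == "male" & conf),
    african_american_high = sum(race == "african_american" & is_high),
    african_american_confirmed = sum(race == "african_american" & conf),
    pulmonary_high = sum(pulm & is_high),
    multi_organ_high = sum(high$multi_organ),
    stage2_pulmonary = sum(cls$scadding == "stage2" & pulm & is_high),
    pft_available_pulmonary = sum(pulm & is_high &
                                    cls$pft_pattern != "missing"),
    scadding_stage0 = unname(st_tab[["stage0"]]),
    scadding_stage1 = unname(st_tab[["stage1"]]),
    scadding_stage2 = unname(st_tab[["stage2"]]),
    scadding_stage3 = unname(st_tab[["stage3"]]),
    scadding_stage4 = unname(st_tab[["stage4"]]),
    scadding_missing = unname(st_tab[["missing"]]),
    pft_obstructive = unname(pft_tab[["obstructive"]]),
    pft_restrictive = unname(pft_tab[["restrictive"]]),
    pft_mixed = unname(pft_tab[["mixed"]]),
    pft_normal = unname(pft_tab[["normal"]]),
    pft_missing = unname(pft_tab[["missing"]]),
    stats::setNames(groups, paste0("group", 1:9)),
    age_mean_confirmed = round(mean(age[conf]), 1),
    age_sd_confirmed = round(stats::sd(age[conf]), 1),
    age_mean_probable = round(mean(age[prob]), 1),
    age_sd_probable = round(stats::sd(age[prob]), 1))
}

#' Check a cohort against the fixture manifest
#'
#' Recomputes every expected marginal through the real pipeline
#' ([classify_cohort()] and the validation-table counts) and reports
#' pass/fail per marginal. Age summaries are compared after rounding to
#' one decimal; all counts must match exactly.
#'
#' @param records A cohort (list of [patient_record()]s).
#' @param manifest A manifest as returned by [fixture_manifest()]; by
#'   default the shipped manifest (falling back to the built-in expected
#'   marginals when the package is not yet installed).
#' @return A data frame of class `fixture_report` with columns `marginal`,
#'   `expected`, `observed`, `pass`.
#' @examples
#' report <- check_fixture(build_fixture_cohort(check = FALSE))
#' all(report$pass)
#' @export
check_fixture <- function(records, manifest = NULL) {
  expected <- if (is.null(manifest)) .FIXTURE_EXPECTED else
    manifest$expected_marginals
  observed <- .fixture_observed(records)
  shared <- names(expected)
  obs <- observed[shared]
  out <- data.frame(marginal = shared, expected = unname(expected),
                    observed = unname(obs),
                    pass = !is.na(obs) & unname(obs == expected),
                    stringsAsFactors = FALSE)
  class(out) <- c("fixture_report", "data.frame")
  out
}

#' @export
print.fixture_report <- function(x, ...) {
  n_fail <- sum(!x$pass)
  cat(sprintf("Fixture check: %d marginals, %d failing\n", nrow(x), n_fail))
  if (n_fail) {
    bad <- x[!x$pass, , drop = FALSE]
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  FAIL %s: expected %s, observed %s\n", bad$marginal[i],
                  format(bad$expected[i]), format(bad$observed[i])))
  }
  invisible(x)
}

# Expected marginals, also serialized to inst/extdata/fixture-manifest.json.
# Phenotype-group counts are the values the group definitions force given
# the Scadding and treatment marginals (groups are non-exclusive; groups 3
# to 6 partition the stage II-IV patients by treatment).
.FIXTURE_EXPECTED <- c(
  n_total = 200, n_site_sf = 100, n_site_pa = 100,
  n_high = 158, n_low = 42,
  n_confirmed = 142, n_probable = 16, n_unlikely = 42,
  table_granuloma_high = 142, table_granuloma_low = 0,
  table_nogranuloma_high = 16, table_nogranuloma_low = 42,
  icd9_first_high = 108, icd10_first_high = 50, icd9_first_confirmed = 98,
  male_high = 142, male_confirmed = 127,
  african_american_high = 85, african_american_confirmed = 74,
  pulmonary_high = 143, multi_organ_high = 60,
  stage2_pulmonary = 47, pft_available_pulmonary = 129,
  scadding_stage0 = 27, scadding_stage1 = 26, scadding_stage2 = 47,
  scadding_stage3 = 21, scadding_stage4 = 22, scadding_missing = 15,
  pft_obstructive = 28, pft_restrictive = 36, pft_mixed = 25,
  pft_normal = 40, pft_missing = 29,
  group1 = 60, group2 = 8, group3 = 45, group4 = 23, group5 = 17,
  group6 = 5, group7 = 0, group8 = 35, group9 = 6,
  age_mean_confirmed = 65.5, age_sd_confirmed = 10.8,
  age_mean_probable = 69.3, age_sd_probable = 10.3)
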