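# Shared test helpers: compact record builders, a seeded random-record
# generator, and independent brute-force oracles (literal re-statements of
# the rule set and exact statistics) kept deliberately separate from the
# package's code paths.

make_record <- function(id = "T1", clinical = character(),
                        radiologic = character(), biopsies = biopsy_records(),
                        claims = icd_claims("135"), ...) {
  patient_record(id, claims = claims, clinical_flags = clinical,
                 radiologic_flags = radiologic, biopsies = biopsies, ...)
}

# random but always-valid record; caller controls the RNG seed
random_record <- function(id, p_flag = 0.25, p_biopsy = 0.5) {
  clin <- clinical_features()[runif(16) < p_flag]
  rad <- radiologic_features()[runif(7) < p_flag]
  biopsies <- if (runif(1) < p_biopsy) {
    n <- sample(1:2, 1)
    biopsy_records(sample(biopsy_sites(), n, replace = TRUE),
                   sample(c("nonnecrotizing_granuloma", "other_finding"), n,
                          replace = TRUE),
                   sample(c("primary", "secondary"), n, replace = TRUE))
  } else biopsy_records()
  nodal <- runif(1) < 0.3
  parench <- runif(1) < 0.3
  report <- runif(1) < 0.8
  ever <- runif(1) < 0.5
  pft_avail <- runif(1) < 0.7
  patient_record(
    id, site = sample(c("SF", "PA"), 1),
    sex = sample(c("male", "female"), 1),
    race = sample(c("african_american", "non_hispanic_white", "unknown"), 1),
    age_years = round(runif(1, 25, 95), 1),
    claims = icd_claims(sample(c("135", "135.1", "D86.0", "D86.9", "J44.9"),
                               sample(0:3, 1), replace = TRUE)),
    clinical_flags = clin, radiologic_flags = rad, biopsies = biopsies,
    pft = if (pft_avail) pft_measurements(
      available = TRUE,
      fev1_fvc_ratio = round(runif(1, 0.4, 0.9), 4), fev1_fvc_lln = 0.7,
      fvc = round(runif(1, 2, 5), 4), fvc_lln = 3.1,
      tlc = round(runif(1, 3.5, 7), 4), tlc_lln = 5.2)
      else pft_measurements(),
    imaging = imaging_findings(
      report_available = report,
      cxr_normal = report && !nodal && !parench,
      hilar_mediastinal_nodal_enlargement = report && nodal,
      parenchymal_disease = report && parench,
      fibrosis_end_stage = report && parench && runif(1) < 0.3),
    course = clinical_course(
      ever_treated = ever,
      treated_within_3_months = ever && runif(1) < 0.4,
      acute_lofgren = runif(1) < 0.1,
      remitting_no_active_disease_gt_1yr = runif(1) < 0.3,
      cardiac_manifestations = runif(1) < 0.2))
}

# ---- independent rule-set oracle: literal condition lists ----

ORACLE_FEATURES <- c(
  "lofgren_syndrome", "heerfordt_syndrome",
  "lupus_pernio_or_erythema_nodosum", "maculopapular_lesions",
  "facial_nerve_palsy", "parotid_enlargement", "ocular_inflammation",
  "lacrimal_swelling", "laryngoscopy_granulomatous", "hepatosplenomegaly",
  "respiratory_symptoms", "pft_abnormal", "cardiac_manifestation",
  "calcium_vitd_abnormal", "ace_or_sil2r_elevated", "bal_lymphocytosis",
  "bilateral_hilar_lymphadenopathy", "perilymphatic_nodules",
  "diffuse_infiltrates_or_fibrosis", "cardiac_mri_or_pet_consistent",
  "liver_spleen_lesions", "brain_mri_inflammation",
  "extrathoracic_lymphadenopathy")

oracle_index <- function(rec) {
  present <- c(rec$clinical_flags, rec$radiologic_flags)
  if (sum(ORACLE_FEATURES %in% present) >= 1) "high" else "low"
}

oracle_case <- function(rec) {
  if (oracle_index(rec) == "low") return("unlikely")
  gran <- nrow(rec$biopsies) > 0 &&
    any(rec$biopsies$result == "nonnecrotizing_granuloma")
  if (gran) "confirmed_biopsy" else "probable_no_biopsy"
}

oracle_organs <- function(rec) {
  gs <- rec$biopsies$site[rec$biopsies$result == "nonnecrotizing_granuloma"]
  f <- c(rec$clinical_flags, rec$radiologic_flags)
  out <- character()
  if ("lung" %in% gs || "mediastinal_hilar_node" %in% gs ||
      "pft_abnormal" %in% f || "bilateral_hilar_lymphadenopathy" %in% f ||
      "perilymphatic_nodules" %in% f ||
      "diffuse_infiltrates_or_fibrosis" %in% f) out <- c(out, "lung")
  if ("skin" %in% gs || "lupus_pernio_or_erythema_nodosum" %in% f)
    out <- c(out, "skin")
  if ("conjunctiva_sclera" %in% gs || "ocular_inflammation" %in% f)
    out <- c(out, "eye")
  if ("heart_pericardium" %in% gs || "cardiac_manifestation" %in% f ||
      "cardiac_mri_or_pet_consistent" %in% f) out <- c(out, "cardiac")
  if ("liver" %in% gs || "spleen" %in% gs || "hepatosplenomegaly" %in% f ||
      "liver_spleen_lesions" %in% f) out <- c(out, "liver_spleen")
  if ("brain_dura_nerve" %in% gs || "brain_mri_inflammation" %in% f)
    out <- c(out, "neuro")
  if ("ear_nose_throat" %in% gs || "laryngoscopy_granulomatous" %in% f)
    out <- c(out, "ent")
  out
}

# ---- Clopper-Pearson oracle: bisection on the binomial tails ----

cp_oracle <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  high <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(low, high)
}

# ---- Fisher exact oracle: full enumeration of margin-preserving tables ----

enumerate_margin_tables <- function(rs, cs) {
  r <- length(rs)
  out <- list()
  fill_row <- function(rows_done, col_left) {
    i <- length(rows_done) + 1L
    if (i == r) {
      if (all(col_left >= 0) && sum(col_left) == rs[r]) {
        out[[length(out) + 1L]] <<- do.call(rbind, c(rows_done, list(col_left)))
      }
      return(invisible())
    }
    compositions(rs[i], col_left, function(row) {
      fill_row(c(rows_done, list(row)), col_left - row)
    })
  }
  compositions <- function(total, caps, cb, prefix = integer()) {
    j <- length(prefix) + 1L
    if (j == length(caps)) {
      last <- total - sum(prefix)
      if (last >= 0 && last <= caps[j]) cb(c(prefix, last))
      return(invisible())
    }
    for (v in 0:min(total - sum(prefix), caps[j]))
      compositions(total, caps, cb, c(prefix, v))
  }
  fill_row(list(), cs)
  out
}

fisher_oracle <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  logp <- function(t) sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(sum(rs)) - sum(lfactorial(t))
  tabs <- enumerate_margin_tables(rs, cs)
  lp <- vapply(tabs, logp, numeric(1))
  lp_obs <- logp(m)
  # point-probability rule with the conventional 1e-7 relative tie tolerance
  sum(exp(lp[lp <= lp_obs + log1p(1e-7)]))
}

expect_exit <- function(object, status) {
  expect_identical(as.integer(object), as.integer(status))
}
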