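# Seeded stochastic cohort generator for robustness studies: records are
# drawn independently per patient, with feature flags Bernoulli at the
# configured prevalences and downstream fields (biopsy, imaging, PFT
# values) generated coherently with the drawn flags.

#' Specify a stochastic cohort
#'
#' Parameters of the per-patient sampling model used by
#' [simulate_cohort()]. Feature flags are independent Bernoulli draws;
#' conditional on a high index of suspicion a biopsy is present with
#' probability `biopsy_given_high`, and a present biopsy shows
#' nonnecrotizing granuloma with probability `granuloma_given_biopsy`.
#'
#' @param n_patients Number of patients (> 0).
#' @param seed Integer seed; the same seed and spec give a byte-identical
#'   cohort.
#' @param feature_prevalence Named vector of per-feature presence
#'   probabilities over [clinical_features()] and [radiologic_features()];
#'   unnamed scalar recycles to all features. Default 0.05.
#' @param biopsy_given_high Probability of a documented biopsy given high
#'   index (default 0.9).
#' @param granuloma_given_biopsy Probability a biopsy shows granuloma
#'   (default 0.95).
#' @param icd9_fraction Probability the qualifying claim is ICD-9 `135`
#'   rather than an ICD-10 `D86.x` code (default 0.68).
#' @param site_split Probability of site `"SF"` (default 0.5).
#' @param male_fraction Probability of male sex (default 0.9).
#' @param race_probs Named probabilities over the race categories.
#' @param treated_rate,remitting_rate Course-history rates.
#' @param age_mean,age_sd Age distribution (normal, truncated to 20-100).
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, seed = 1,
                        feature_prevalence = 0.05,
                        biopsy_given_high = 0.9,
                        granuloma_given_biopsy = 0.95,
                        icd9_fraction = 0.68, site_split = 0.5,
                        male_fraction = 0.9,
                        race_probs = c(african_american = 0.5,
                                       non_hispanic_white = 0.33,
                                       hispanic_white = 0.02,
                                       unknown = 0.1, other = 0.05),
                        treated_rate = 0.6, remitting_rate = 0.2,
                        age_mean = 66, age_sd = 11) {
  if (!is.numeric(n_patients) || n_patients < 1 ||
      n_patients != round(n_patients))
    stop("n_patients must be a positive integer", call. = FALSE)
  features <- c(.CLINICAL_FEATURES, .RADIOLOGIC_FEATURES)
  if (is.null(names(feature_prevalence))) {
    if (length(feature_prevalence) != 1L)
      stop("unnamed feature_prevalence must be a single number", call. = FALSE)
    feature_prevalence <- stats::setNames(rep(feature_prevalence,
                                              length(features)), features)
  } else {
    missing_f <- setdiff(names(feature_prevalence), features)
    if (length(missing_f))
      stop("unknown features in feature_prevalence: ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    full <- stats::setNames(rep(0, length(features)), features)
    full[names(feature_prevalence)] <- feature_prevalence
    feature_prevalence <- full
  }
  fracs <- c(feature_prevalence, biopsy_given_high, granuloma_given_biopsy,
             icd9_fraction, site_split, male_fraction, race_probs,
             treated_rate, remitting_rate)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (!setequal(names(race_probs), .RACES) ||
      abs(sum(race_probs) - 1) > 1e-8)
    stop("race_probs must cover all race categories and sum to 1",
         call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 feature_prevalence = feature_prevalence,
                 biopsy_given_high = biopsy_given_high,
                 granuloma_given_biopsy = granuloma_given_biopsy,
                 icd9_fraction = icd9_fraction, site_split = site_split,
                 male_fraction = male_fraction, race_probs = race_probs,
                 treated_rate = treated_rate, remitting_rate = remitting_rate,
                 age_mean = as.numeric(age_mean), age_sd = as.numeric(age_sd)),
            class = "cohort_spec")
}

#' Per-feature prevalence yielding a target high-index rate
#'
#' With independent features at a common prevalence `p`, the probability
#' of a high index of suspicion (any feature present) is
#' `1 - (1 - p)^K`; this returns the `p` that attains a given target over
#' the `K = 23` feature flags.
#'
#' @param target_high_rate Desired probability of a high index.
#' @param n_features Number of independent flags (default all 23).
#' @return The common per-feature prevalence.
#' @examples
#' prevalence_for_high_rate(0.79)
#' @export
prevalence_for_high_rate <- function(target_high_rate,
                                     n_features = length(c(clinical_features(),
                                                           radiologic_features()))) {
  if (target_high_rate < 0 || target_high_rate >= 1)
    stop("target_high_rate must lie in [0, 1)", call. = FALSE)
  1 - (1 - target_high_rate)^(1 / n_features)
}

#' Simulate a stochastic cohort
#'
#' Draws `n_patients` independent records under a [cohort_spec()]. Flags
#' are Bernoulli; biopsy presence and result follow the conditional
#' probabilities in the spec; imaging findings and PFT values are
#' generated consistently with the drawn radiologic flags and
#' `pft_abnormal` flag, so re-deriving classifications from the raw
#' records reproduces the intended feature structure. Reproducible: the
#' same seed and spec give an identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [patient_record()] objects.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(50, seed = 42))
#' print(classify_cohort(cohort))
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("spec must be a cohort_spec", call. = FALSE)
  set.seed(spec$seed)
  n <- spec$n_patients
  features <- names(spec$feature_prevalence)
  d86_cycle <- c("D86.0", "D86.1", "D86.2", "D86.9")
  records <- vector("list", n)
  for (i in seq_len(n)) {
    present <- stats::runif(length(features)) < spec$feature_prevalence
    flags <- features[present]
    clin <- intersect(flags, .CLINICAL_FEATURES)
    rad <- intersect(flags, .RADIOLOGIC_FEATURES)
    high <- length(flags) > 0L

    biopsies <- biopsy_records()
    if (high && stats::runif(1) < spec$biopsy_given_high) {
      result <- if (stats::runif(1) < spec$granuloma_given_biopsy)
        "nonnecrotizing_granuloma" else "other_finding"
      site <- sample(c("lung", "mediastinal_hilar_node", "skin"), 1L,
                     prob = c(0.6, 0.3, 0.1))
      prov <- if (stats::runif(1) < 0.8) "primary" else "secondary"
      biopsies <- biopsy_records(site, result, prov)
    }

    icd9 <- stats::runif(1) < spec$icd9_fraction
    claims <- icd_claims(
      if (icd9) "135" else sample(d86_cycle, 1L),
      if (stats::runif(1) < 0.5) "inpatient" else "outpatient")

    nodal <- "bilateral_hilar_lymphadenopathy" %in% rad
    parench <- "diffuse_infiltrates_or_fibrosis" %in% rad
    report <- stats::runif(1) < 0.9
    imaging <- imaging_findings(
      report_available = report,
      cxr_normal = report && !nodal && !parench,
      hilar_mediastinal_nodal_enlargement = report && nodal,
      parenchymal_disease = report && parench,
      fibrosis_end_stage = report && parench && stats::runif(1) < 0.2)

    pft_avail <- stats::runif(1) < 0.8 || "pft_abnormal" %in% clin
    pft <- if (!pft_avail) pft_measurements(available = FALSE) else {
      if ("pft_abnormal" %in% clin) {
        kind <- sample(c("obstructive", "restrictive", "mixed"), 1L)
        .fixture_pft(kind)
      } else .fixture_pft("normal")
    }

    treated <- stats::runif(1) < spec$treated_rate
    remitting <- stats::runif(1) < spec$remitting_rate
    records[[i]] <- patient_record(
      patient_id = sprintf("SIM-%06d", i),
      site = if (stats::runif(1) < spec$site_split) "SF" else "PA",
      sex = if (stats::runif(1) < spec$male_fraction) "male" else "female",
      race = sample(names(spec$race_probs), 1L, prob = spec$race_probs),
      age_years = round(min(100, max(20, stats::rnorm(1, spec$age_mean,
                                                      spec$age_sd))), 1),
      claims = claims, clinical_flags = clin, radiologic_flags = rad,
      biopsies = biopsies, pft = pft, imaging = imaging,
      course = clinical_course(
        ever_treated = treated,
        treated_within_3_months = treated && stats::runif(1) < 0.3,
        acute_lofgren = "lofgren_syndrome" %in% clin,
        remitting_no_active_disease_gt_1yr = remitting,
        cardiac_manifestations = "cardiac_manifestation" %in% clin))
  }
  records
}
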