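# Controlled vocabularies for the phenotyping rule set.
# Vocabulary items listed with "or" alternatives are merged into one flag:
# the rule engine only ever tests presence-of-any, so finer granularity
# would add states that no downstream rule distinguishes.

.CLINICAL_FEATURES <- c(
  "lofgren_syndrome",
  "heerfordt_syndrome",
  "lupus_pernio_or_erythema_nodosum",
  "maculopapular_lesions",
  "facial_nerve_palsy",
  "parotid_enlargement",
  "ocular_inflammation",
  "lacrimal_swelling",
  "laryngoscopy_granulomatous",
  "hepatosplenomegaly",
  "respiratory_symptoms",
  "pft_abnormal",
  "cardiac_manifestation",
  "calcium_vitd_abnormal",
  "ace_or_sil2r_elevated",
  "bal_lymphocytosis"
)

.RADIOLOGIC_FEATURES <- c(
  "bilateral_hilar_lymphadenopathy",
  "perilymphatic_nodules",
  "diffuse_infiltrates_or_fibrosis",
  "cardiac_mri_or_pet_consistent",
  "liver_spleen_lesions",
  "brain_mri_inflammation",
  "extrathoracic_lymphadenopathy"
)

.ORGANS <- c("lung", "skin", "eye", "cardiac", "liver_spleen", "neuro", "ent")

.BIOPSY_SITES <- c(
  "lung", "mediastinal_hilar_node", "skin", "conjunctiva_sclera",
  "heart_pericardium", "liver", "spleen", "brain_dura_nerve",
  "ear_nose_throat", "other"
)

.BIOPSY_RESULTS <- c("nonnecrotizing_granuloma", "other_finding")
.BIOPSY_PROVENANCE <- c("primary", "secondary")
.CLAIM_SETTINGS <- c("inpatient", "outpatient")
.SITES <- c("SF", "PA")
.SEXES <- c("male", "female")
.RACES <- c("african_american", "non_hispanic_white", "hispanic_white",
            "unknown", "other")
.SCADDING_LEVELS <- c("stage0", "stage1", "stage2", "stage3", "stage4",
                      "missing")
.PFT_LEVELS <- c("obstructive", "restrictive", "mixed", "normal", "missing")
.CASE_GROUPS <- c("confirmed_biopsy", "probable_no_biopsy", "unlikely")

# Per-organ involvement criteria: an organ is involved when a granulomatous
# biopsy was taken at one of its sites, or any of its clinical/radiologic
# flags is present. Liver-enzyme-only abnormality is not a trigger; the
# liver/spleen pathway requires the exam or imaging flag.
.ORGAN_CRITERIA <- list(
  lung = list(
    biopsy_sites = c("lung", "mediastinal_hilar_node"),
    clinical = "pft_abnormal",
    radiologic = c("bilateral_hilar_lymphadenopathy", "perilymphatic_nodules",
                   "diffuse_infiltrates_or_fibrosis")
  ),
  skin = list(
    biopsy_sites = "skin",
    clinical = "lupus_pernio_or_erythema_nodosum",
    radiologic = character()
  ),
  eye = list(
    biopsy_sites = "conjunctiva_sclera",
    clinical = "ocular_inflammation",
    radiologic = character()
  ),
  cardiac = list(
    biopsy_sites = "heart_pericardium",
    clinical = "cardiac_manifestation",
    radiologic = "cardiac_mri_or_pet_consistent"
  ),
  liver_spleen = list(
    biopsy_sites = c("liver", "spleen"),
    clinical = "hepatosplenomegaly",
    radiologic = "liver_spleen_lesions"
  ),
  neuro = list(
    biopsy_sites = "brain_dura_nerve",
    clinical = character(),
    radiologic = "brain_mri_inflammation"
  ),
  ent = list(
    biopsy_sites = "ear_nose_throat",
    clinical = "laryngoscopy_granulomatous",
    radiologic = character()
  )
)

#' Feature and category vocabularies
#'
#' Accessors for the controlled vocabularies used throughout the package:
#' the 16 clinical and 7 radiological "index of suspicion" feature flags,
#' the 7 assessable organs, and the biopsy site codes.
#'
#' @return A character vector of vocabulary tokens, or for
#'   [organ_criteria()] a named list with one entry per organ giving the
#'   qualifying biopsy sites and clinical/radiologic feature flags.
#' @examples
#' clinical_features()
#' organ_criteria()[["lung"]]
#' @export
clinical_features <- function() .CLINICAL_FEATURES

#' @rdname clinical_features
#' @export
radiologic_features <- function() .RADIOLOGIC_FEATURES

#' @rdname clinical_features
#' @export
sarcoidosis_organs <- function() .ORGANS

#' @rdname clinical_features
#' @export
biopsy_sites <- function() .BIOPSY_SITES

#' @rdname clinical_features
#' @export
organ_criteria <- function() .ORGAN_CRITERIA
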