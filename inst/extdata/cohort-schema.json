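{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sarcphen cohort (JSON dialect)",
  "description": "Array of per-patient structured EMR extract records. All derived labels (index of suspicion, case group, organ set, stage, phenotype groups) are functions of these raw fields and are never stored.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["patient_id", "site", "sex", "race", "age_years", "claims",
                 "clinical_flags", "radiologic_flags", "biopsies", "pft",
                 "imaging", "course"],
    "properties": {
      "patient_id": {"type": "string", "minLength": 1},
      "site": {"enum": ["SF", "PA"]},
      "sex": {"enum": ["male", "female"]},
      "race": {"enum": ["african_american", "non_hispanic_white",
                        "hispanic_white", "unknown", "other"]},
      "age_years": {"type": "number", "minimum": 0, "maximum": 120},
      "claims": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["code", "setting"],
          "properties": {
            "code": {"type": "string", "pattern": "^\\S+$"},
            "setting": {"enum": ["inpatient", "outpatient"]},
            "date": {"type": "string", "format": "date"}
          }
        }
      },
      "clinical_flags": {
        "type": "array", "uniqueItems": true,
        "items": {"enum": ["lofgren_syndrome", "heerfordt_syndrome",
          "lupus_pernio_or_erythema_nodosum", "maculopapular_lesions",
          "facial_nerve_palsy", "parotid_enlargement", "ocular_inflammation",
          "lacrimal_swelling", "laryngoscopy_granulomatous",
          "hepatosplenomegaly", "respiratory_symptoms", "pft_abnormal",
          "cardiac_manifestation", "calcium_vitd_abnormal",
          "ace_or_sil2r_elevated", "bal_lymphocytosis"]}
      },
      "radiologic_flags": {
        "type": "array", "uniqueItems": true,
        "items": {"enum": ["bilateral_hilar_lymphadenopathy",
          "perilymphatic_nodules", "diffuse_infiltrates_or_fibrosis",
          "cardiac_mri_or_pet_consistent", "liver_spleen_lesions",
          "brain_mri_inflammation", "extrathoracic_lymphadenopathy"]}
      },
      "biopsies": {
        "type": "array",
        "items": {
          "type": "object",
          "required": ["site", "result", "provenance"],
          "properties": {
            "site": {"enum": ["lung", "mediastinal_hilar_node", "skin",
              "conjunctiva_sclera", "heart_pericardium", "liver", "spleen",
              "brain_dura_nerve", "ear_nose_throat", "other"]},
            "result": {"enum": ["nonnecrotizing_granuloma", "other_finding"]},
            "provenance": {"enum": ["primary", "secondary"]}
          }
        }
      },
      "pft": {
        "type": "object",
        "required": ["available"],
        "properties": {
          "available": {"type": "boolean"},
          "fev1_fvc_ratio": {"type": ["number", "null"]},
          "fev1_fvc_lln": {"type": ["number", "null"], "exclusiveMinimum": 0},
          "fvc": {"type": ["number", "null"]},
          "fvc_lln": {"type": ["number", "null"], "exclusiveMinimum": 0},
          "tlc": {"type": ["number", "null"]},
          "tlc_lln": {"type": ["number", "null"], "exclusiveMinimum": 0},
          "dlco_pct_predicted": {"type": ["number", "null"]},
          "dlco_lln_pct": {"type": ["number", "null"], "exclusiveMinimum": 0}
        }
      },
      "imaging": {
        "type": "object",
        "required": ["report_available", "cxr_normal",
                     "hilar_mediastinal_nodal_enlargement",
                     "parenchymal_disease", "fibrosis_end_stage"],
        "additionalProperties": {"type": "boolean"}
      },
      "course": {
        "type": "object",
        "required": ["ever_treated", "treated_within_3_months",
                     "acute_lofgren", "remitting_no_active_disease_gt_1yr",
                     "cardiac_manifestations"],
        "additionalProperties": {"type": "boolean"}
      }
    }
  }
}
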