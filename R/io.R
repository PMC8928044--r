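# Cohort serialization. Two dialects:
#  * JSON: one array of nested patient objects (schema shipped in
#    inst/extdata/cohort-schema.json); optional scalars are null.
#  * CSV: one row per patient; set-valued fields are semicolon-joined
#    tokens (flag sets sorted lexicographically so output is byte-stable);
#    claims and biopsies keep their list order with '|'-separated fields.
# Both round-trip exactly: read_cohort(write_cohort(x)) == x.

.CSV_COLUMNS <- c(
  "patient_id", "site", "sex", "race", "age_years", "claims",
  "clinical_flags", "radiologic_flags", "biopsies",
  "pft_available", "fev1_fvc_ratio", "fev1_fvc_lln", "fvc", "fvc_lln",
  "tlc", "tlc_lln", "dlco_pct_predicted", "dlco_lln_pct",
  "imaging_report_available", "cxr_normal",
  "hilar_mediastinal_nodal_enlargement", "parenchymal_disease",
  "fibrosis_end_stage",
  "ever_treated", "treated_within_3_months", "acute_lofgren",
  "remitting_no_active_disease_gt_1yr", "cardiac_manifestations"
)

.fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v)
    format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1)))
}
.parse_num <- function(x) ifelse(nzchar(x), suppressWarnings(as.numeric(x)), NA_real_)
.fmt_bool <- function(x) ifelse(x, "true", "false")
.parse_bool <- function(x) x == "true"

.check_tokens <- function(id, field, x) {
  if (any(grepl("[|;]", x)))
    .stop_field(id, field, "values may not contain '|' or ';' in the CSV dialect")
}

.encode_group <- function(id, field, df) {
  if (!nrow(df)) return("")
  for (cn in names(df)) .check_tokens(id, field, df[[cn]][!is.na(df[[cn]])])
  rows <- apply(df, 1L, function(r) paste(ifelse(is.na(r), "", r), collapse = "|"))
  paste(rows, collapse = ";")
}

.decode_group <- function(x, cols) {
  if (!nzchar(x)) {
    out <- as.data.frame(matrix(character(), 0, length(cols)),
                         stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) {
    length(p) <- length(cols)
    ifelse(is.na(p) | !nzchar(p), NA_character_, p)
  }))
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

record_to_row <- function(rec) {
  cl <- rec$claims
  cl$date <- ifelse(is.na(cl$date), NA_character_, cl$date)
  flags_c <- sort(rec$clinical_flags)
  flags_r <- sort(rec$radiologic_flags)
  .check_tokens(rec$patient_id, "clinical_flags", flags_c)
  .check_tokens(rec$patient_id, "radiologic_flags", flags_r)
  p <- rec$pft; im <- rec$imaging; co <- rec$course
  data.frame(
    patient_id = rec$patient_id, site = rec$site, sex = rec$sex,
    race = rec$race, age_years = .fmt_num(rec$age_years),
    claims = .encode_group(rec$patient_id, "claims", cl),
    clinical_flags = paste(flags_c, collapse = ";"),
    radiologic_flags = paste(flags_r, collapse = ";"),
    biopsies = .encode_group(rec$patient_id, "biopsies", rec$biopsies),
    pft_available = .fmt_bool(p$available),
    fev1_fvc_ratio = .fmt_num(p$fev1_fvc_ratio),
    fev1_fvc_lln = .fmt_num(p$fev1_fvc_lln),
    fvc = .fmt_num(p$fvc), fvc_lln = .fmt_num(p$fvc_lln),
    tlc = .fmt_num(p$tlc), tlc_lln = .fmt_num(p$tlc_lln),
    dlco_pct_predicted = .fmt_num(p$dlco_pct_predicted),
    dlco_lln_pct = .fmt_num(p$dlco_lln_pct),
    imaging_report_available = .fmt_bool(im$report_available),
    cxr_normal = .fmt_bool(im$cxr_normal),
    hilar_mediastinal_nodal_enlargement =
      .fmt_bool(im$hilar_mediastinal_nodal_enlargement),
    parenchymal_disease = .fmt_bool(im$parenchymal_disease),
    fibrosis_end_stage = .fmt_bool(im$fibrosis_end_stage),
    ever_treated = .fmt_bool(co$ever_treated),
    treated_within_3_months = .fmt_bool(co$treated_within_3_months),
    acute_lofgren = .fmt_bool(co$acute_lofgren),
    remitting_no_active_disease_gt_1yr =
      .fmt_bool(co$remitting_no_active_disease_gt_1yr),
    cardiac_manifestations = .fmt_bool(co$cardiac_manifestations),
    stringsAsFactors = FALSE)
}

row_to_record <- function(row) {
  cl <- .decode_group(row[["claims"]], c("code", "setting", "date"))
  bx <- .decode_group(row[["biopsies"]], c("site", "result", "provenance"))
  split_set <- function(x) if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1]] else character()
  patient_record(
    patient_id = row[["patient_id"]], site = row[["site"]],
    sex = row[["sex"]], race = row[["race"]],
    age_years = .parse_num(row[["age_years"]]),
    claims = icd_claims(cl$code, cl$setting,
                        ifelse(is.na(cl$date), NA_character_, cl$date)),
    clinical_flags = split_set(row[["clinical_flags"]]),
    radiologic_flags = split_set(row[["radiologic_flags"]]),
    biopsies = biopsy_records(bx$site, bx$result, bx$provenance),
    pft = pft_measurements(
      available = .parse_bool(row[["pft_available"]]),
      fev1_fvc_ratio = .parse_num(row[["fev1_fvc_ratio"]]),
      fev1_fvc_lln = .parse_num(row[["fev1_fvc_lln"]]),
      fvc = .parse_num(row[["fvc"]]), fvc_lln = .parse_num(row[["fvc_lln"]]),
      tlc = .parse_num(row[["tlc"]]), tlc_lln = .parse_num(row[["tlc_lln"]]),
      dlco_pct_predicted = .parse_num(row[["dlco_pct_predicted"]]),
      dlco_lln_pct = .parse_num(row[["dlco_lln_pct"]])),
    imaging = imaging_findings(
      report_available = .parse_bool(row[["imaging_report_available"]]),
      cxr_normal = .parse_bool(row[["cxr_normal"]]),
      hilar_mediastinal_nodal_enlargement =
        .parse_bool(row[["hilar_mediastinal_nodal_enlargement"]]),
      parenchymal_disease = .parse_bool(row[["parenchymal_disease"]]),
      fibrosis_end_stage = .parse_bool(row[["fibrosis_end_stage"]])),
    course = clinical_course(
      ever_treated = .parse_bool(row[["ever_treated"]]),
      treated_within_3_months = .parse_bool(row[["treated_within_3_months"]]),
      acute_lofgren = .parse_bool(row[["acute_lofgren"]]),
      remitting_no_active_disease_gt_1yr =
        .parse_bool(row[["remitting_no_active_disease_gt_1yr"]]),
      cardiac_manifestations = .parse_bool(row[["cardiac_manifestations"]])))
}

record_to_json_list <- function(rec) {
  cl <- rec$claims
  claims <- lapply(seq_len(nrow(cl)), function(i) {
    x <- list(code = cl$code[i], setting = cl$setting[i])
    x$date <- if (is.na(cl$date[i])) NULL else cl$date[i]
    x
  })
  bx <- rec$biopsies
  biopsies <- lapply(seq_len(nrow(bx)), function(i)
    list(site = bx$site[i], result = bx$result[i],
         provenance = bx$provenance[i]))
  num_or_null <- function(v) if (is.na(v)) NULL else v
  p <- rec$pft
  list(patient_id = rec$patient_id, site = rec$site, sex = rec$sex,
       race = rec$race, age_years = rec$age_years, claims = claims,
       clinical_flags = as.list(sort(rec$clinical_flags)),
       radiologic_flags = as.list(sort(rec$radiologic_flags)),
       biopsies = biopsies,
       pft = list(available = p$available,
                  fev1_fvc_ratio = num_or_null(p$fev1_fvc_ratio),
                  fev1_fvc_lln = num_or_null(p$fev1_fvc_lln),
                  fvc = num_or_null(p$fvc), fvc_lln = num_or_null(p$fvc_lln),
                  tlc = num_or_null(p$tlc), tlc_lln = num_or_null(p$tlc_lln),
                  dlco_pct_predicted = num_or_null(p$dlco_pct_predicted),
                  dlco_lln_pct = num_or_null(p$dlco_lln_pct)),
       imaging = rec$imaging, course = rec$course)
}

json_list_to_record <- function(x) {
  get_chr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  get_num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  claims <- x$claims
  cl <- icd_claims(
    vapply(claims, function(c) as.character(c$code), character(1)),
    vapply(claims, function(c) as.character(c$setting), character(1)),
    vapply(claims, function(c) get_chr(c$date), character(1)))
  bx <- x$biopsies
  biopsies <- biopsy_records(
    vapply(bx, function(b) as.character(b$site), character(1)),
    vapply(bx, function(b) as.character(b$result), character(1)),
    vapply(bx, function(b) as.character(b$provenance), character(1)))
  p <- x$pft
  patient_record(
    patient_id = x$patient_id, site = x$site, sex = x$sex, race = x$race,
    age_years = x$age_years, claims = cl,
    clinical_flags = unlist(x$clinical_flags) %||% character(),
    radiologic_flags = unlist(x$radiologic_flags) %||% character(),
    biopsies = biopsies,
    pft = pft_measurements(
      available = isTRUE(p$available),
      fev1_fvc_ratio = get_num(p$fev1_fvc_ratio),
      fev1_fvc_lln = get_num(p$fev1_fvc_lln),
      fvc = get_num(p$fvc), fvc_lln = get_num(p$fvc_lln),
      tlc = get_num(p$tlc), tlc_lln = get_num(p$tlc_lln),
      dlco_pct_predicted = get_num(p$dlco_pct_predicted),
      dlco_lln_pct = get_num(p$dlco_lln_pct)),
    imaging = do.call(imaging_findings, lapply(x$imaging, isTRUE)),
    course = do.call(clinical_course, lapply(x$course, isTRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a patient cohort from disk
#'
#' Reads and validates a cohort file in either the JSON or the CSV dialect
#' (see the package vignette for the schemas; the JSON schema is also
#' shipped at `system.file("extdata", "cohort-schema.json", package =
#' "sarcphen")`). Every record-level invariant is enforced and duplicate
#' patient ids are rejected; row order is preserved.
#'
#' @param path Path to the cohort file.
#' @param format `"json"` or `"csv"`; defaults to the file extension.
#' @return A list of [patient_record()] objects.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, format = c("json", "csv")) {
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  records <- if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(raw, json_list_to_record)
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE)
    missing_cols <- setdiff(.CSV_COLUMNS, names(df))
    if (length(missing_cols))
      stop("cohort CSV is missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, , drop = FALSE]))
  }
  validate_cohort(records)
  records
}

#' Write a patient cohort to disk
#'
#' Serializes validated records in the JSON or CSV dialect. Serialization
#' is deterministic: flag sets are written in sorted order and numeric
#' fields with a fixed 15-significant-digit format, so repeated writes of
#' the same cohort are byte-identical and `read_cohort()` reproduces the
#' input exactly.
#'
#' @param records List of [patient_record()] objects.
#' @param path Output path.
#' @param format `"json"` or `"csv"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, format = c("json", "csv")) {
  if (missing(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format)
  validate_cohort(records)
  if (format == "json") {
    payload <- lapply(records, record_to_json_list)
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = FALSE)
    writeLines(json, path, useBytes = TRUE)
  } else {
    rows <- do.call(rbind, lapply(records, record_to_row))
    if (is.null(rows)) {
      rows <- as.data.frame(matrix(character(), 0, length(.CSV_COLUMNS)),
                            stringsAsFactors = FALSE)
      names(rows) <- .CSV_COLUMNS
    }
    utils::write.csv(rows, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}
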