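# Diagnostic-accuracy estimation and contingency-table tests. The exact
# binomial (Clopper-Pearson) interval is computed in its beta-quantile
# form; the chi-square and Fisher tests delegate to the standard stats
# routines behind this module's interface.

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Computes the exact interval by inverting the binomial tail
#' probabilities via the beta-quantile formulation:
#' `low = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `high = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`, in which
#' case `low = (alpha/2)^(1/n)` in closed form).
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (> 0).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' clopper_pearson(142, 158)
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop("level must be a number strictly between 0 and 1", call. = FALSE)
  if (n <= 0 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("need integer counts with 0 <= x <= n and n > 0", call. = FALSE)
  alpha <- 1 - level
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

new_proportion_estimate <- function(numerator, denominator, level, what) {
  ci <- clopper_pearson(numerator, denominator, level)
  out <- list(what = what, numerator = as.integer(numerator),
              denominator = as.integer(denominator),
              estimate = numerator / denominator,
              ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
              level = level)
  stopifnot(out$ci_low <= out$estimate + 1e-12,
            out$estimate <= out$ci_high + 1e-12)
  class(out) <- "proportion_estimate"
  out
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%s: %d/%d = %.1f%% (%d%% CI %.1f%%-%.1f%%)\n",
              x$what, x$numerator, x$denominator, 100 * x$estimate,
              round(100 * x$level), 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Positive predictive value with exact confidence interval
#'
#' PPV = (gold-standard-verified patients among those flagged by the
#' algorithm) / (all flagged patients), with a Clopper-Pearson interval.
#'
#' @param n_true Flagged patients verified by the gold standard.
#' @param n_flagged Total flagged patients (> 0).
#' @param level Confidence level; default 0.95.
#' @return A `proportion_estimate` object.
#' @examples
#' ppv(158, 200)
#' @export
ppv <- function(n_true, n_flagged, level = 0.95) {
  if (n_flagged <= 0)
    stop("PPV undefined: no flagged patients", call. = FALSE)
  if (n_true < 0 || n_true > n_flagged)
    stop("need 0 <= n_true <= n_flagged", call. = FALSE)
  new_proportion_estimate(n_true, n_flagged, level, "PPV")
}

#' Sensitivity with exact confidence interval
#'
#' Sensitivity = detected / all with the condition, with a Clopper-Pearson
#' interval.
#'
#' @param n_detected Condition-positive patients detected by the test.
#' @param n_condition All condition-positive patients (> 0).
#' @param level Confidence level; default 0.95.
#' @return A `proportion_estimate` object.
#' @export
sensitivity <- function(n_detected, n_condition, level = 0.95) {
  if (n_condition <= 0)
    stop("sensitivity undefined: no condition-positive patients", call. = FALSE)
  if (n_detected < 0 || n_detected > n_condition)
    stop("need 0 <= n_detected <= n_condition", call. = FALSE)
  new_proportion_estimate(n_detected, n_condition, level, "Sensitivity")
}

#' Specificity and positive likelihood ratio
#'
#' In a case-only validation design (every reviewed patient carries the
#' diagnostic code; no code-negative controls are reviewed) the
#' false-positive fraction is unobservable, so specificity — and with it
#' the positive likelihood ratio — is not estimable. These functions
#' compute the usual estimates under `design = "case_control"` and raise a
#' descriptive error under the default `design = "case_only"`.
#'
#' @param n_true_neg Controls correctly not flagged.
#' @param n_condition_neg All condition-negative controls.
#' @param design `"case_only"` or `"case_control"`.
#' @param level Confidence level; default 0.95.
#' @return A `proportion_estimate` (specificity) or a number (likelihood
#'   ratio); an error under the case-only design.
#' @export
specificity <- function(n_true_neg, n_condition_neg,
                        design = c("case_only", "case_control"),
                        level = 0.95) {
  design <- match.arg(design)
  if (design == "case_only")
    stop("specificity is not estimable from this design: the cohort ",
         "contains no code-negative controls", call. = FALSE)
  if (n_condition_neg <= 0)
    stop("specificity undefined: no condition-negative patients", call. = FALSE)
  new_proportion_estimate(n_true_neg, n_condition_neg, level, "Specificity")
}

#' @rdname specificity
#' @param sens,spec Sensitivity and specificity estimates in (0, 1).
#' @export
positive_likelihood_ratio <- function(sens, spec,
                                      design = c("case_only", "case_control")) {
  design <- match.arg(design)
  if (design == "case_only")
    stop("positive likelihood ratio is not estimable from this design: ",
         "specificity cannot be calculated without code-negative controls",
         call. = FALSE)
  sens / (1 - spec)
}

#' Construct a labeled contingency table
#'
#' @param counts Integer matrix of nonnegative counts, at least 2x2.
#' @param row_labels,col_labels Optional dimension labels.
#' @return An integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", "matrix", "array"))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  m <- rbind(cbind(m, Total = rowSums(m)), Total = c(colSums(m), sum(m)))
  print(m)
  invisible(x)
}

#' Histopathology vs index-of-suspicion validation table
#'
#' Cross-tabulates, over an ICD-captured cohort, documented granulomatous
#' histopathology (rows: `granuloma_confirmed`, `not_available`) against
#' the index of suspicion (columns: `high`, `low`). Cells sum to the
#' cohort size. Granuloma-positive low-index patients land in the
#' `granuloma_confirmed`/`low` cell: histopathology without supportive
#' clinical/radiological features does not make a case.
#'
#' @param classification A `sarc_classification` from [classify_cohort()].
#' @return A 2x2 `contingency_table`.
#' @export
build_validation_table <- function(classification) {
  if (!inherits(classification, "sarc_classification"))
    stop("classification must come from classify_cohort()", call. = FALSE)
  if (nrow(classification) == 0L)
    stop("empty cohort: nothing to tabulate", call. = FALSE)
  if (!all(classification$icd_captured))
    stop("validation table is defined for ICD-captured cohorts only",
         call. = FALSE)
  gran <- classification$granuloma_documented
  high <- classification$index_of_suspicion == "high"
  counts <- matrix(c(sum(gran & high), sum(!gran & high),
                     sum(gran & !high), sum(!gran & !high)), nrow = 2L)
  contingency_table(counts,
                    row_labels = c("granuloma_confirmed", "not_available"),
                    col_labels = c("high", "low"))
}

#' Pearson chi-square test on a contingency table
#'
#' @param table A `contingency_table` (or plain count matrix).
#' @param yates Apply the Yates continuity correction (2x2 only); default
#'   `FALSE`.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(contingency_table(matrix(c(127, 15, 15, 1), 2)))
#' @export
chi_square_test <- function(table, yates = FALSE) {
  m <- unclass(as.matrix(table))
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(res$statistic),
       df = as.integer(res$parameter), p_value = unname(res$p.value))
}

#' Fisher exact test on an r x c contingency table
#'
#' Exact two-sided p-value over all margin-preserving tables, summing the
#' multivariate hypergeometric probabilities of tables no more probable
#' than the observed one (the point-probability rule). Exact enumeration
#' is restricted to tables with total at most 500 and at most 6 rows and
#' columns; larger tables must use the seeded Monte-Carlo mode.
#'
#' @param table A `contingency_table` (or plain count matrix).
#' @param mode `"exact"` (default) or `"monte_carlo"`.
#' @param B Monte-Carlo replicates (default 10000).
#' @param seed Seed for the Monte-Carlo mode (default 1).
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table, mode = c("exact", "monte_carlo"),
                         B = 10000, seed = 1) {
  m <- unclass(as.matrix(table))
  mode <- match.arg(mode)
  if (mode == "exact") {
    if (sum(m) > 500 || nrow(m) > 6 || ncol(m) > 6)
      stop("table too large for exact enumeration (total <= 500, at most ",
           "6x6); use mode = 'monte_carlo' with a fixed seed", call. = FALSE)
    stats::fisher.test(m)$p.value
  } else {
    set.seed(seed)
    stats::fisher.test(m, simulate.p.value = TRUE, B = B)$p.value
  }
}

#' Welch two-sample t test from summary statistics
#'
#' Welch statistic with Satterthwaite degrees of freedom and two-sided
#' p-value, computed from group means, SDs and sizes (for comparing
#' published summary rows without patient-level data).
#'
#' @param mean1,sd1,n1 First group summary (n1 >= 2, sd1 > 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p_value`.
#' @examples
#' welch_t_from_summary(65.5, 10.8, 142, 69.3, 10.3, 16)
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("need positive SDs", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Diagnostic-accuracy validation of the phenotyping algorithm
#'
#' Computes, over an ICD-captured cohort, the validation contingency table
#' (histopathology vs index of suspicion) and the four headline accuracy
#' estimates with exact binomial intervals: PPV of ICD capture alone
#' against chart-style adjudication (high index), PPV of ICD capture for
#' histopathologically confirmed disease, PPV of ICD capture combined with
#' the high index of suspicion, and sensitivity of histopathology
#' documentation alone relative to the high index of suspicion.
#'
#' @param classification A `sarc_classification` from [classify_cohort()].
#' @param level Confidence level for the intervals; default 0.95.
#' @return An object of class `sarc_validation`: the table, the four
#'   `proportion_estimate`s (`NULL` with an explanatory note when a
#'   denominator is empty), and the cohort size.
#' @examples
#' cohort <- build_fixture_cohort()
#' cls <- classify_cohort(cohort)
#' sarc_validate(cls)
#' @export
sarc_validate <- function(classification, level = 0.95) {
  tab <- build_validation_table(classification)
  n <- sum(tab)
  n_high <- sum(tab[, "high"])
  n_conf <- tab["granuloma_confirmed", "high"]
  adjudicated <- classification$case_group %in%
    c("confirmed_biopsy", "probable_no_biopsy")
  high <- classification$index_of_suspicion == "high"
  notes <- character()
  est <- list(
    ppv_icd_alone = ppv(n_high, n, level),
    ppv_icd_confirmed = ppv(n_conf, n, level),
    ppv_icd_plus_index = NULL,
    sensitivity_histopath = NULL)
  if (n_high > 0) {
    est$ppv_icd_plus_index <- ppv(sum(adjudicated & high), n_high, level)
    est$sensitivity_histopath <- sensitivity(n_conf, n_high, level)
  } else {
    notes <- c(notes, paste("ICD + high-index PPV and histopathology",
                            "sensitivity not estimable: no high-index patients"))
  }
  out <- c(list(table = tab, n = n, level = level, notes = notes), est)
  class(out) <- "sarc_validation"
  out
}

#' @export
print.sarc_validation <- function(x, ...) {
  cat(sprintf("Validation of ICD-based sarcoidosis capture (N = %d)\n\n", x$n))
  cat("Histopathology vs high index of suspicion:\n")
  print(x$table)
  cat("\n")
  for (nm in c("ppv_icd_alone", "ppv_icd_confirmed", "ppv_icd_plus_index",
               "sensitivity_histopath")) {
    label <- switch(nm,
      ppv_icd_alone = "PPV, ICD codes alone (vs high index)",
      ppv_icd_confirmed = "PPV, ICD codes (vs biopsy-confirmed)",
      ppv_icd_plus_index = "PPV, ICD codes + high index",
      sensitivity_histopath = "Sensitivity, histopathology alone")
    e <- x[[nm]]
    if (is.null(e)) {
      cat(sprintf("%-42s not estimable\n", label))
    } else {
      cat(sprintf("%-42s %3d/%3d = %5.1f%% (%d%% CI %.1f%%-%.1f%%)\n",
                  label, e$numerator, e$denominator, 100 * e$estimate,
                  round(100 * e$level), 100 * e$ci_low, 100 * e$ci_high))
    }
  }
  for (note in x$notes) cat("note: ", note, "\n", sep = "")
  invisible(x)
}
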