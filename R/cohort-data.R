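# Published cohort characteristics of the peripheral-blood ischaemic-stroke
# biomarker study whose discovery microarray data are deposited as GEO
# series GSE16561. The package does not need the expression data: the
# printed per-group counts and summary statistics are sufficient input for
# the statistics module (chi-square from 2x2 counts, Welch t from
# mean/sd/n), and they double as reference fixtures for validating that
# module against the published statistic columns.

#' Published cohort characteristics (GSE16561 stroke biomarker study)
#'
#' Per-variable group summaries of the discovery cohort (24 neurologically
#' asymptomatic controls vs 39 acute ischaemic stroke patients) and the
#' validation cohort (30 controls vs 39 AIS; 20 stroke mimics vs 39 AIS),
#' as printed: counts for dichotomous variables, mean/sd for continuous
#' ones, alongside the published statistic for cross-checking.
#'
#' Not every printed statistic is reproducible from the printed counts
#' (some rows appear to use missing-data denominators that were not
#' published); `reproducible` flags the rows that recompute exactly at
#' printed precision with [pearson_chi_square()] (no continuity
#' correction) or [welch_t()] from summaries.
#'
#' @return A named list of three data.frames (`discovery`,
#'   `validation_control`, `validation_mimic`), each with columns
#'   `variable`, `type` (`"dichotomous"`/`"continuous"`), group-1 and
#'   group-2 summaries (`yes1`, `n1`, `yes2`, `n2` or `mean1`, `sd1`,
#'   `n1`, `mean2`, `sd2`, `n2`), `published_statistic`, and
#'   `reproducible`. Group 1 is the reference group (control or mimic),
#'   group 2 is AIS.
#' @export
published_cohort_characteristics <- function() {
  dich <- function(variable, yes1, n1, yes2, n2, stat, repro) {
    data.frame(variable = variable, type = "dichotomous",
               yes1 = yes1, n1 = n1, yes2 = yes2, n2 = n2,
               mean1 = NA_real_, sd1 = NA_real_, mean2 = NA_real_,
               sd2 = NA_real_, published_statistic = stat,
               reproducible = repro, stringsAsFactors = FALSE)
  }
  cont <- function(variable, mean1, sd1, n1, mean2, sd2, n2, stat, repro) {
    data.frame(variable = variable, type = "continuous",
               yes1 = NA_real_, n1 = n1, yes2 = NA_real_, n2 = n2,
               mean1 = mean1, sd1 = sd1, mean2 = mean2, sd2 = sd2,
               published_statistic = stat, reproducible = repro,
               stringsAsFactors = FALSE)
  }
  discovery <- rbind(
    cont("age", 59.9, 9.7, 24, 73.1, 14.0, 39, -4.40, FALSE),
    dich("female", 14, 24, 22, 39, 0.12, FALSE),
    cont("nihss", 0, 0.0, 24, 5.3, 6.4, 39, 5.17, TRUE),
    dich("family_history_stroke", 4, 24, 15, 39, 7.02, FALSE),
    dich("hypertension", 7, 24, 25, 39, 11.2, FALSE),
    dich("dyslipidaemia", 0, 24, 18, 39, 15.5, TRUE),
    dich("diabetes", 2, 24, 11, 39, 3.58, TRUE),
    dich("previous_stroke", 2, 24, 6, 39, 0.67, TRUE),
    dich("atrial_fibrillation", 0, 24, 6, 39, 4.08, TRUE),
    dich("myocardial_infarction", 0, 24, 6, 39, 4.08, TRUE),
    dich("hypertension_medication", 8, 24, 29, 39, 10.3, TRUE),
    dich("diabetes_medication", 1, 24, 7, 39, 2.55, TRUE),
    dich("cholesterol_medication", 5, 24, 17, 39, 3.39, TRUE),
    dich("anticoagulant_or_antiplatelet", 1, 24, 20, 39, 14.9, FALSE),
    dich("rtpa", 0, 24, 9, 39, 6.46, TRUE),
    dich("current_smoker", 2, 24, 2, 39, 0.26, TRUE))
  validation_control <- rbind(
    cont("age", 51.5, 14.3, 30, 73.1, 13.3, 39, -6.41, TRUE),
    dich("female", 25, 30, 25, 39, 3.14, TRUE),
    cont("nihss", 0, 0.0, 30, 8.6, 7.5, 39, 7.16, TRUE),
    dich("family_history_stroke", 16, 30, 15, 39, 1.52, TRUE),
    dich("hypertension", 17, 30, 32, 39, 5.31, TRUE),
    dich("dyslipidaemia", 11, 30, 16, 39, 0.14, TRUE),
    dich("diabetes", 2, 30, 8, 39, 2.62, TRUE),
    dich("previous_stroke", 1, 30, 7, 39, 3.53, TRUE),
    dich("atrial_fibrillation", 0, 30, 13, 39, 12.3, TRUE),
    dich("myocardial_infarction", 0, 30, 11, 39, 10.0, FALSE),
    dich("hypertension_medication", 15, 30, 27, 39, 2.63, TRUE),
    dich("diabetes_medication", 2, 30, 8, 39, 2.62, TRUE),
    dich("cholesterol_medication", 7, 30, 14, 39, 1.26, TRUE),
    dich("anticoagulant_or_antiplatelet", 1, 30, 23, 39, 23.1, TRUE),
    dich("rtpa", 0, 30, 13, 39, 12.3, TRUE),
    dich("current_smoker", 1, 30, 9, 39, 5.33, TRUE))
  validation_mimic <- rbind(
    cont("age", 58.0, 17.0, 20, 73.1, 13.3, 39, -3.78, FALSE),
    dich("female", 9, 20, 25, 39, 1.98, TRUE),
    cont("nihss", 4.7, 4.9, 20, 8.6, 7.5, 39, -2.11, FALSE),
    dich("family_history_stroke", 5, 20, 15, 39, 1.07, TRUE),
    dich("hypertension", 17, 20, 32, 39, 0.08, TRUE),
    dich("dyslipidaemia", 13, 20, 16, 39, 3.08, FALSE),
    dich("diabetes", 7, 20, 8, 39, 1.46, TRUE),
    dich("previous_stroke", 5, 20, 7, 39, 0.52, FALSE),
    dich("atrial_fibrillation", 3, 20, 13, 39, 2.25, TRUE),
    dich("myocardial_infarction", 6, 20, 11, 39, 0.02, TRUE),
    dich("hypertension_medication", 16, 20, 27, 39, 0.78, TRUE),
    dich("diabetes_medication", 6, 20, 8, 39, 0.66, TRUE),
    dich("cholesterol_medication", 12, 20, 14, 39, 3.12, TRUE),
    dich("anticoagulant_or_antiplatelet", 12, 20, 23, 39, 0.01, TRUE),
    dich("rtpa", 0, 20, 13, 39, 8.55, TRUE),
    dich("current_smoker", 2, 20, 9, 39, 1.49, TRUE))
  list(discovery = discovery, validation_control = validation_control,
       validation_mimic = validation_mimic)
}

#' Recompute a published cohort table from its printed summaries
#'
#' Applies [pearson_chi_square()] (counts rows) and [welch_t()]
#' (mean/sd/n rows) to one of the tables from
#' [published_cohort_characteristics()] and returns the recomputed
#' statistic next to the published one.
#'
#' @param tab One element of [published_cohort_characteristics()].
#' @return The table with columns `statistic` (recomputed), `df`, `p`
#'   appended.
#' @export
recompute_cohort_table <- function(tab) {
  stat <- df <- p <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    tr <- if (r$type == "dichotomous") {
      pearson_chi_square(counts_2x2(r$yes1, r$n1, r$yes2, r$n2))
    } else {
      welch_t(summary_stats(r$mean1, r$sd1, r$n1),
              summary_stats(r$mean2, r$sd2, r$n2))
    }
    stat[i] <- unname(tr$statistic); df[i] <- tr$df; p[i] <- tr$p
  }
  cbind(tab, statistic = stat, df = df, p = p)
}
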