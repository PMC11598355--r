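#' Build a prediction table
#'
#' Applies the 0.5 decision threshold to male probabilities.  A probability
#' of exactly 0.5 classifies as Female (the negative class), making the
#' decision rule total.
#'
#' @param subject_id Character ids.
#' @param prob_male Probabilities of the Male class.
#' @param true_sex "F"/"M" labels.
#' @return Data frame `subject_id`, `prob_male`, `pred`, `true`.
#' @export
prediction_table <- function(subject_id, prob_male, true_sex) {
  stopifnot(length(subject_id) == length(prob_male),
            length(prob_male) == length(true_sex),
            all(true_sex %in% c("F", "M")))
  data.frame(subject_id = subject_id, prob_male = prob_male,
             pred = ifelse(prob_male > 0.5, "M", "F"), true = true_sex,
             stringsAsFactors = FALSE)
}

#' Confusion counts with Male as positive class
#'
#' @param preds Prediction table from [prediction_table()].
#' @return Named vector `TP`, `FP`, `TN`, `FN` (counts sum to `nrow(preds)`).
#' @export
confusion <- function(preds) {
  stopifnot(nrow(preds) > 0)
  c(TP = sum(preds$pred == "M" & preds$true == "M"),
    FP = sum(preds$pred == "M" & preds$true == "F"),
    TN = sum(preds$pred == "F" & preds$true == "F"),
    FN = sum(preds$pred == "F" & preds$true == "M"))
}

#' Classification metrics
#'
#' Accuracy, balanced accuracy (mean of per-class recalls), precision,
#' recall and F1 for the Male-positive convention, plus rank-based AUC-ROC
#' (Mann-Whitney statistic with average ranks).  Metrics requiring both
#' classes are `NA` (undefined) when a class is absent, never 0.
#'
#' @param preds Prediction table.
#' @return List of metrics, including per-sex recalls `recall_f`,
#'   `recall_m`, and `n`.
#' @export
compute_metrics <- function(preds) {
  cm <- confusion(preds)
  n <- sum(cm)
  tp <- cm["TP"]; fp <- cm["FP"]; tn <- cm["TN"]; fn <- cm["FN"]
  has_m <- (tp + fn) > 0
  has_f <- (tn + fp) > 0
  recall_m <- if (has_m) tp / (tp + fn) else NA_real_
  recall_f <- if (has_f) tn / (tn + fp) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall_m) && precision + recall_m > 0)
    2 * precision * recall_m / (precision + recall_m) else NA_real_
  auc <- if (has_m && has_f) {
    r <- rank(preds$prob_male)
    n1 <- sum(preds$true == "M")
    (sum(r[preds$true == "M"]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
  } else NA_real_
  list(n = unname(n),
       accuracy = unname((tp + tn) / n),
       balanced_accuracy = unname(if (has_m && has_f) (recall_f + recall_m) / 2
                                  else NA_real_),
       precision = unname(precision),
       recall = unname(recall_m),
       recall_f = unname(recall_f),
       recall_m = unname(recall_m),
       f1 = unname(f1),
       auc_roc = unname(auc))
}

#' Balanced accuracy from printed per-sex accuracies
#'
#' Convenience for reproducing published per-tertile arithmetic: the mean of
#' two per-sex accuracies (in percent), rounded half-up to one decimal.
#'
#' @param acc_f,acc_m Per-sex accuracies in percent.
#' @return Balanced accuracy in percent, 1 decimal.
#' @export
balanced_accuracy_pct <- function(acc_f, acc_m) {
  round_half_up((acc_f + acc_m) / 2, 1)
}

#' Assign age bins
#'
#' Bins follow the brain-aging thresholds at 55 and 70 years: `<55`,
#' `55-70` (55 inclusive), `>=70`.
#'
#' @param age Numeric ages.
#' @return Factor with levels `<55`, `55-70`, `>=70`.
#' @export
age_bins <- function(age) {
  cut(age, breaks = c(-Inf, 55, 70, Inf), labels = c("<55", "55-70", ">=70"),
      right = FALSE)
}

#' Subgroup performance report
#'
#' Computes [compute_metrics()] within subgroups keyed by metadata columns
#' (site/vendor, field strength) and by age bin, mirroring per-subgroup
#' test-set reporting.
#'
#' @param preds Prediction table.
#' @param cohort Cohort data frame with `subject_id` and the key columns.
#' @param keys Columns of `cohort` to stratify on; `"age_bin"` is derived
#'   from `age`.
#' @return Named list: for each key, a list of per-level metric reports
#'   (each with subgroup `n`).
#' @export
subgroup_report <- function(preds, cohort, keys = c("site", "field", "age_bin")) {
  j <- merge(preds, cohort, by = "subject_id", sort = FALSE)
  if (nrow(j) != nrow(preds)) stop("some predictions have no cohort row")
  if ("age_bin" %in% keys) {
    if (!"age" %in% names(cohort)) stop("age_bin key requires an age column")
    j$age_bin <- as.character(age_bins(j$age))
  }
  bad <- setdiff(keys, names(j))
  if (length(bad)) stop("unknown subgroup key(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (k in keys) {
    lev <- unique(j[[k]])
    out[[k]] <- lapply(stats::setNames(lev, lev), function(l)
      compute_metrics(j[j[[k]] == l, c("subject_id", "prob_male", "pred", "true")]))
  }
  out
}
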