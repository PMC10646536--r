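# CD/UCD allocation diagnostics and grouped cross-validation. The positive
# class is UCD (the clinically dangerous state). Observed labels follow the
# CD / indeterminate / UCD thresholds; indeterminate observations are
# excluded from the confusion matrix and reported separately, because the
# CD/UCD definitions leave the 5-10% decrease band unlabelled.

#' CD/UCD allocation metrics from predicted and observed eGFR changes
#'
#' Labels the observed changes with [classify_outcome()], drops
#' indeterminate observations, calls a prediction positive (UCD) when the
#' predicted change falls below \code{ucd_cutoff}, and reports the
#' confusion matrix with accuracy, sensitivity and specificity. A metric
#' whose denominator is empty is reported as \code{NA}, not 0.
#'
#' @param predicted Predicted annual eGFR changes (%/yr).
#' @param observed Observed annual eGFR changes (%/yr).
#' @param ucd_cutoff Predicted-positive threshold (default -10, mirroring
#'   the observed UCD definition).
#' @param arm,model_id Optional labels carried into the report.
#' @return Object of class \code{"dkd_eval_report"}: counts \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}, metrics \code{acc}, \code{se},
#'   \code{sp}, and \code{n_evaluated} / \code{n_indeterminate}.
#' @export
evaluate_allocation <- function(predicted, observed, ucd_cutoff = -10,
                                arm = NA, model_id = NA) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  obs_label <- classify_outcome(observed)
  keep <- obs_label != "indeterminate"
  p <- predicted[keep]
  obs_pos <- obs_label[keep] == "UCD"
  pred_pos <- p < ucd_cutoff
  tp <- sum(pred_pos & obs_pos)
  fp <- sum(pred_pos & !obs_pos)
  tn <- sum(!pred_pos & !obs_pos)
  fn <- sum(!pred_pos & obs_pos)
  n <- tp + fp + tn + fn
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = if (n > 0) (tp + tn) / n else NA_real_,
    se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_evaluated = n,
    n_indeterminate = sum(!keep),
    ucd_cutoff = ucd_cutoff, arm = arm, model_id = model_id
  ), class = "dkd_eval_report")
}

#' @export
print.dkd_eval_report <- function(x, ...) {
  cat(sprintf("CD/UCD allocation (positive = UCD, cutoff %g): n = %d (+%d indeterminate excluded)\n",
              x$ucd_cutoff, x$n_evaluated, x$n_indeterminate))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d | ACC=%s SE=%s SP=%s\n",
              x$tp, x$fp, x$tn, x$fn,
              format(round(x$acc, 3)), format(round(x$se, 3)),
              format(round(x$sp, 3))))
  invisible(x)
}

# Sum confusion counts of several reports and recompute the metrics.
pool_eval_reports <- function(reports, ucd_cutoff = -10) {
  tp <- sum(vapply(reports, `[[`, 0, "tp"))
  fp <- sum(vapply(reports, `[[`, 0, "fp"))
  tn <- sum(vapply(reports, `[[`, 0, "tn"))
  fn <- sum(vapply(reports, `[[`, 0, "fn"))
  n <- tp + fp + tn + fn
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = if (n > 0) (tp + tn) / n else NA_real_,
    se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n_evaluated = n,
    n_indeterminate = sum(vapply(reports, `[[`, 0, "n_indeterminate")),
    ucd_cutoff = ucd_cutoff, arm = NA, model_id = "pooled"
  ), class = "dkd_eval_report")
}

#' Grouped cross-validation of a PLSNN model
#'
#' Folds partition patients, never single pairs, so repeated pairs from
#' the same patient are always held out together. Each fold's model is fit
#' on the remaining folds and evaluated on the held-out pairs; the pooled
#' report sums the per-fold confusion matrices (micro-average).
#'
#' @param cmatrix A \code{"dkd_cohort_matrix"}.
#' @param k Number of folds (>= 2, at most the number of patients).
#' @param control A [plsnn_control()].
#' @param seed Seed for fold assignment and per-fold fits.
#' @param ucd_cutoff Predicted-positive threshold for the reports.
#' @return List of class \code{"dkd_cv"}: \code{folds} (per-fold
#'   reports), \code{pooled}, \code{predictions} (pair id, fold, predicted,
#'   observed), and the held-out \code{rmse}.
#' @export
grouped_cv <- function(cmatrix, k = 5, control = plsnn_control(), seed = 1,
                       ucd_cutoff = -10) {
  stopifnot(inherits(cmatrix, "dkd_cohort_matrix"))
  patients <- sort(unique(cmatrix$groups))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (length(patients) < k) {
    stop(sprintf("only %d patients for %d folds", length(patients), k),
         call. = FALSE)
  }
  fold_of <- with_local_seed(seed, sample(rep_len(seq_len(k), length(patients))))
  names(fold_of) <- patients
  row_fold <- fold_of[cmatrix$groups]

  reports <- vector("list", k)
  preds <- vector("list", k)
  for (fold in seq_len(k)) {
    test <- row_fold == fold
    fit <- fit_plsnn(subset_cohort_matrix(cmatrix, which(!test)), control,
                     seed = seed + fold)
    p <- plsnn_predict(fit, cmatrix$X[test, , drop = FALSE])
    reports[[fold]] <- evaluate_allocation(p, cmatrix$y[test], ucd_cutoff,
                                           model_id = sprintf("fold%d", fold))
    preds[[fold]] <- data.frame(pair_id = cmatrix$pair_ids[test], fold = fold,
                                predicted = p, observed = cmatrix$y[test],
                                stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  structure(list(folds = reports,
                 pooled = pool_eval_reports(reports, ucd_cutoff),
                 predictions = predictions,
                 rmse = sqrt(mean((predictions$observed - predictions$predicted)^2)),
                 fold_of = fold_of),
            class = "dkd_cv")
}

#' @export
print.dkd_cv <- function(x, ...) {
  cat(sprintf("Grouped %d-fold cross-validation: held-out RMSE %.2f %%/yr\n",
              length(x$folds), x$rmse))
  print(x$pooled)
  invisible(x)
}
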