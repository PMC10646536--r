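# Per-arm PLSNN models and counterfactual benefit estimation. The four
# models share one marker panel; evaluating all of them at the same
# baseline marker values gives Delta_R (the composite biomarker) and
# Delta_G / Delta_M / Delta_S, and the vertical distance
# benefit_X = Delta_X - Delta_R is the expected gain in annual eGFR change
# from adding drug X. Benefits are differences of model expectations in an
# observational cohort, not individual causal effects.

ADDON_ARMS <- c("GLP1a", "MCRa", "SGLT2i")

#' Fit the four per-arm treatment models
#'
#' Splits the follow-up pairs by treatment arm and fits one PLSNN model per
#' arm on the shared panel. Per-arm seeds are derived deterministically
#' from the master seed.
#'
#' @param pairs Pair table from [build_followup_pairs()] (columns
#'   \code{arm}, \code{delta_egfr}, \code{patient_id}, markers).
#' @param panel Marker names (character or panel data frame); all four
#'   models use it in identical order.
#' @param control A [plsnn_control()].
#' @param seed Master seed.
#' @param arms Arms to fit (default RASi + the three add-ons).
#' @param min_n Minimum pairs per arm (default 30).
#' @return Object of class \code{"treatment_model_set"}.
#' @export
fit_treatment_models <- function(pairs, panel, control = plsnn_control(),
                                 seed = 1,
                                 arms = c("RASi", ADDON_ARMS), min_n = 30) {
  markers <- panel_markers(panel)
  models <- list()
  n_arm <- integer(0)
  for (i in seq_along(arms)) {
    arm <- arms[i]
    sub <- pairs[pairs$arm == arm, , drop = FALSE]
    if (nrow(sub) < min_n) {
      stop(sprintf("arm '%s' has %d pairs; at least %d required",
                   arm, nrow(sub), min_n), call. = FALSE)
    }
    cm <- assemble_matrix(sub, markers)
    models[[arm]] <- fit_plsnn(cm, control, seed = seed + i, arm = arm)
    n_arm[arm] <- nrow(cm$X)
  }
  structure(list(models = models, panel = markers, n = n_arm, seed = seed),
            class = "treatment_model_set")
}

#' @export
print.treatment_model_set <- function(x, ...) {
  cat("Treatment model set on panel:", paste(x$panel, collapse = ", "), "\n")
  for (arm in names(x$models)) {
    cat(sprintf("  %-7s n = %3d, %d PLS comp., %d centers\n", arm, x$n[arm],
                x$models[[arm]]$pls$ncomp, nrow(x$models[[arm]]$rbf$centers)))
  }
  invisible(x)
}

#' @export
predict.treatment_model_set <- function(object, newdata, ...) {
  out <- vapply(object$models, plsnn_predict, newdata = newdata,
                numeric(nrow(as.data.frame(newdata))))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(object$models)))
  colnames(out) <- paste0("delta_", colnames(out))
  out
}

#' Composite biomarker and counterfactual add-on benefits
#'
#' Evaluates all four arm models at the same baseline marker values.
#' \code{delta_RASi} is the composite biomarker Delta_R;
#' \code{benefit_X = delta_X - delta_RASi} is the expected change in the
#' annual eGFR trend when drug X is added. Predicted CD/UCD labels under
#' each arm come from [classify_outcome()].
#'
#' @param model_set A [fit_treatment_models()] result.
#' @param newdata Rows of baseline marker values (full panel present).
#' @return Data frame of class \code{"benefit_estimate"} with
#'   \code{delta_*}, \code{benefit_*} and \code{label_*} columns.
#' @export
estimate_benefit <- function(model_set, newdata) {
  stopifnot(inherits(model_set, "treatment_model_set"))
  deltas <- predict(model_set, newdata)
  out <- as.data.frame(deltas)
  addons <- setdiff(names(model_set$models), "RASi")
  for (arm in addons) {
    out[[paste0("benefit_", arm)]] <- out[[paste0("delta_", arm)]] - out$delta_RASi
  }
  for (arm in names(model_set$models)) {
    out[[paste0("label_", arm)]] <- classify_outcome(out[[paste0("delta_", arm)]])
  }
  class(out) <- c("benefit_estimate", "data.frame")
  out
}

#' Treatment recommendation from a benefit estimate
#'
#' If the composite biomarker predicts controlled disease
#' (\code{delta_RASi >= cd_threshold}), the patient stays on RASi alone.
#' Otherwise the add-on with the highest predicted \code{delta_X} is
#' recommended, provided its benefit is positive; when no add-on improves
#' on RASi the recommendation is to stay, with a warning flag. Ties go to
#' the larger benefit, then to the fixed order GLP1a, MCRa, SGLT2i.
#'
#' @param estimate A [estimate_benefit()] result.
#' @param cd_threshold Prognosis boundary used for the stay/add decision
#'   (default -5, the CD boundary).
#' @return Data frame with columns \code{action} (\code{"stay"} or
#'   \code{"add_<arm>"}), \code{flagged}, \code{delta_RASi},
#'   \code{best_addon}, \code{best_benefit}.
#' @export
recommend_treatment <- function(estimate, cd_threshold = -5) {
  stopifnot(inherits(estimate, "benefit_estimate"))
  addons <- intersect(ADDON_ARMS,
                      sub("^delta_", "", grep("^delta_", names(estimate), value = TRUE)))
  dmat <- as.matrix(estimate[, paste0("delta_", addons), drop = FALSE])
  best_idx <- apply(dmat, 1, which.max)  # first max: fixed-order tie-break
  best_addon <- addons[best_idx]
  best_delta <- dmat[cbind(seq_len(nrow(dmat)), best_idx)]
  best_benefit <- best_delta - estimate$delta_RASi
  cd_predicted <- estimate$delta_RASi >= cd_threshold
  add <- !cd_predicted & best_benefit > 0
  data.frame(
    action = ifelse(cd_predicted, "stay",
                    ifelse(add, paste0("add_", best_addon), "stay")),
    flagged = !cd_predicted & !add,
    delta_RASi = estimate$delta_RASi,
    best_addon = best_addon,
    best_benefit = best_benefit,
    stringsAsFactors = FALSE
  )
}

#' Apply the RASi-only model across arms and stratify the residuals
#'
#' Predicts the composite biomarker Delta_R for a set of pairs (typically
#' an add-on arm) and summarizes the residual observed - predicted by
#' strata of Delta_R. If the add-on has no effect, residuals scatter
#' around zero; a positive mean residual in the poor-prognosis strata is
#' the signature of drug rescue (the lower Delta_R, the larger the add-on
#' effect).
#'
#' @param model_set A [fit_treatment_models()] result (its RASi model is
#'   used), or a single RASi-arm \code{"plsnn_model"}.
#' @param pairs Pair table with observed \code{delta_egfr} and the panel
#'   markers.
#' @param strata_edges Delta_R cut points (default -5 and -10, the CD/UCD
#'   boundaries).
#' @return List of class \code{"cross_prediction"}: \code{per_pair} data
#'   frame (prediction, observed, residual, stratum) and \code{summary}
#'   (per-stratum n, mean residual, SE, t).
#' @export
cross_predict <- function(model_set, pairs, strata_edges = c(-5, -10)) {
  model <- if (inherits(model_set, "treatment_model_set")) {
    model_set$models[["RASi"]]
  } else {
    model_set
  }
  stopifnot(inherits(model, "plsnn_model"))
  pred <- plsnn_predict(model, pairs)
  obs <- pairs$delta_egfr
  resid <- obs - pred
  edges <- sort(strata_edges)  # e.g. -10, -5
  stratum <- cut(pred, breaks = c(-Inf, edges, Inf), right = FALSE,
                 labels = c(sprintf("< %g", edges[1]),
                            sprintf("[%g, %g)", edges[1], edges[2]),
                            sprintf(">= %g", edges[2])))
  per_pair <- data.frame(pair_id = pairs$pair_id, arm = pairs$arm,
                         delta_R = pred, observed = obs, residual = resid,
                         stratum = stratum, stringsAsFactors = FALSE)
  agg <- lapply(levels(stratum), function(s) {
    r <- resid[stratum == s]
    data.frame(stratum = s, n = length(r),
               mean_residual = if (length(r)) mean(r) else NA_real_,
               se = if (length(r) > 1) sd(r) / sqrt(length(r)) else NA_real_)
  })
  summary <- do.call(rbind, agg)
  summary$t <- summary$mean_residual / summary$se
  structure(list(per_pair = per_pair, summary = summary,
                 overall_mean_residual = mean(resid)),
            class = "cross_prediction")
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat(sprintf("Cross-prediction with the RASi-only model: %d pairs, overall mean residual %.2f %%/yr\n",
              nrow(x$per_pair), x$overall_mean_residual))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
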