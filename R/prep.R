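#' Estimated glomerular filtration rate (MDRD study equation)
#'
#' Computes eGFR from serum creatinine with the 4-variable MDRD study
#' equation, by default the IDMS-traceable form with leading constant 175:
#' \deqn{eGFR = 175 \cdot Scr^{-1.154} \cdot age^{-0.203} \cdot 0.742^{[female]}
#'   \cdot 1.212^{[black]}}
#'
#' @param scr Serum creatinine in mg/dL (vector, all > 0).
#' @param age Age in years (vector, all > 0).
#' @param is_female Logical; applies the 0.742 factor.
#' @param is_black Logical; applies the 1.212 factor.
#' @param constant Leading constant; 175 (IDMS-traceable, default) or 186
#'   (original assay calibration).
#' @return eGFR in ml/min/1.73 m^2.
#' @examples
#' compute_egfr_mdrd(1.0, 50, is_female = FALSE, is_black = FALSE)
#' @export
compute_egfr_mdrd <- function(scr, age, is_female = FALSE, is_black = FALSE,
                              constant = 175) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("serum creatinine must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("age must be positive and finite", call. = FALSE)
  }
  constant * scr^-1.154 * age^-0.203 *
    ifelse(is_female, 0.742, 1) * ifelse(is_black, 1.212, 1)
}

#' Annual percent change in eGFR
#'
#' The outcome used throughout the package: the percent change in eGFR
#' between two visits, linearly annualized by the interval length:
#' \code{100 * (followup - baseline) / baseline / interval_years} (%/yr).
#'
#' @param egfr_baseline Baseline eGFR (> 0).
#' @param egfr_followup Follow-up eGFR.
#' @param interval_years Interval between the visits in years (> 0, default 1).
#' @return Annual percent change, %/yr.
#' @export
compute_delta_egfr <- function(egfr_baseline, egfr_followup, interval_years = 1) {
  if (any(!is.finite(egfr_baseline)) || any(egfr_baseline <= 0)) {
    stop("baseline eGFR must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(interval_years)) || any(interval_years <= 0)) {
    stop("interval_years must be positive", call. = FALSE)
  }
  100 * (egfr_followup - egfr_baseline) / egfr_baseline / interval_years
}

#' Controlled / uncontrolled disease label from the annual eGFR change
#'
#' Controlled disease (CD) is an annual eGFR decrease not exceeding 5%
#' (delta >= -5); uncontrolled disease (UCD) a drop of more than 10%
#' (delta < -10). Decreases between 5% and 10% fall in neither definition
#' and are labelled \code{"indeterminate"}; downstream binary evaluation
#' excludes them.
#'
#' @param delta_egfr Annual percent change in eGFR (%/yr), finite.
#' @param cd_threshold CD boundary, default -5.
#' @param ucd_threshold UCD boundary, default -10.
#' @return Character vector with values \code{"CD"}, \code{"UCD"},
#'   \code{"indeterminate"}.
#' @export
classify_outcome <- function(delta_egfr, cd_threshold = -5, ucd_threshold = -10) {
  if (any(!is.finite(delta_egfr))) {
    stop("delta_egfr must be finite", call. = FALSE)
  }
  ifelse(delta_egfr >= cd_threshold, "CD",
         ifelse(delta_egfr < ucd_threshold, "UCD", "indeterminate"))
}

#' Apply the eGFR inclusion window to a visit table
#'
#' Retains visits whose eGFR lies in the closed interval
#' \[\code{lower}, \code{upper}\] (default 30-90 ml/min/1.73 m^2: advanced
#' disease below 30 and atypical hyperfiltration above 90 are excluded from
#' model building). An exclusion log is attached as attribute
#' \code{"exclusion_log"}.
#'
#' @param visits Visit table with an \code{egfr} column.
#' @param lower,upper Inclusion bounds (closed interval).
#' @return The filtered visit table.
#' @export
filter_inclusion <- function(visits, lower = 30, upper = 90) {
  if (!"egfr" %in% names(visits)) stop("visit table lacks an 'egfr' column", call. = FALSE)
  keep <- !is.na(visits$egfr) & visits$egfr >= lower & visits$egfr <= upper
  out <- visits[keep, , drop = FALSE]
  log <- data.frame(
    reason = c("egfr_missing", "egfr_below_lower", "egfr_above_upper"),
    n = c(sum(is.na(visits$egfr)),
          sum(visits$egfr < lower, na.rm = TRUE),
          sum(visits$egfr > upper, na.rm = TRUE))
  )
  if (nrow(out) == 0L) warning("no visits remain after inclusion filtering")
  attr(out, "exclusion_log") <- log
  rownames(out) <- NULL
  out
}

#' Build annual follow-up pairs from a visit table
#'
#' Pairs each visit with the next consecutive annual visit of the same
#' patient. The pair's treatment arm is taken from the baseline visit's
#' \code{arm} column (the add-on, if any, started after that baseline); the
#' outcome is the annualized percent change in eGFR between the two visits.
#' Pairs with missing eGFR at either end are dropped and logged, as are
#' pairs whose baseline eGFR falls outside the inclusion window. The same
#' patient may contribute several pairs.
#'
#' @param visits Visit table with columns \code{patient_id},
#'   \code{visit_idx} (0-based consecutive), \code{arm}, \code{egfr}, plus
#'   marker columns.
#' @param interval_years Visit spacing in years (default 1).
#' @param inclusion Length-2 numeric inclusion window applied to baseline
#'   eGFR (closed; default \code{c(30, 90)}), or \code{NULL} to skip.
#' @param inclusion_scope \code{"baseline"} (default) applies the window to
#'   the baseline visit only; \code{"both"} to both visits of a pair.
#' @return Data frame with one row per pair: \code{pair_id},
#'   \code{patient_id}, \code{baseline_visit_idx}, \code{arm},
#'   \code{egfr_baseline}, \code{egfr_followup}, \code{delta_egfr},
#'   \code{outcome_label}, and the baseline value of every marker column.
#'   A drop log is attached as attribute \code{"pair_log"}.
#' @export
build_followup_pairs <- function(visits, interval_years = 1,
                                 inclusion = c(30, 90),
                                 inclusion_scope = c("baseline", "both")) {
  inclusion_scope <- match.arg(inclusion_scope)
  required <- c("patient_id", "visit_idx", "arm", "egfr")
  missing_cols <- setdiff(required, names(visits))
  if (length(missing_cols)) {
    stop("visit table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  marker_cols <- setdiff(names(visits),
                         c(required, "visit_year", "scr_mg_dl"))

  visits <- visits[order(visits$patient_id, visits$visit_idx), , drop = FALSE]
  dup <- duplicated(visits[c("patient_id", "visit_idx")])
  if (any(dup)) stop("duplicated visit_idx within a patient", call. = FALSE)

  idx_b <- which(c(visits$patient_id[-nrow(visits)] == visits$patient_id[-1], FALSE) &
                 c(visits$visit_idx[-nrow(visits)] + 1L == visits$visit_idx[-1], FALSE))
  idx_f <- idx_b + 1L

  n_candidates <- length(idx_b)
  egfr_b <- visits$egfr[idx_b]
  egfr_f <- visits$egfr[idx_f]

  drop_missing <- is.na(egfr_b) | is.na(egfr_f)
  drop_range <- rep(FALSE, n_candidates)
  if (!is.null(inclusion)) {
    in_win <- function(x) !is.na(x) & x >= inclusion[1] & x <= inclusion[2]
    drop_range <- !drop_missing & !in_win(egfr_b)
    if (inclusion_scope == "both") {
      drop_range <- drop_range | (!drop_missing & !in_win(egfr_f))
    }
  }
  keep <- !drop_missing & !drop_range

  pairs <- data.frame(
    pair_id = sprintf("%s_p%d", visits$patient_id[idx_b], visits$visit_idx[idx_b]),
    patient_id = visits$patient_id[idx_b],
    baseline_visit_idx = visits$visit_idx[idx_b],
    arm = visits$arm[idx_b],
    egfr_baseline = egfr_b,
    egfr_followup = egfr_f,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  pairs$delta_egfr <- compute_delta_egfr(pairs$egfr_baseline, pairs$egfr_followup,
                                         interval_years)
  pairs$outcome_label <- classify_outcome(pairs$delta_egfr)
  for (mc in marker_cols) pairs[[mc]] <- visits[[mc]][idx_b][keep]
  rownames(pairs) <- NULL
  attr(pairs, "pair_log") <- data.frame(
    reason = c("candidate_pairs", "dropped_missing_egfr", "dropped_inclusion_window"),
    n = c(n_candidates, sum(drop_missing), sum(drop_range))
  )
  pairs
}

#' Assemble the model design matrix for a set of follow-up pairs
#'
#' Extracts the baseline values of the panel markers as the feature matrix
#' X (columns in panel order), the annual eGFR change as the outcome y, and
#' patient ids as grouping labels for grouped cross-validation. Rows with
#' any missing panel value are dropped (complete-case) and logged. Training
#' column means/SDs are stored for later standardization.
#'
#' @param pairs Output of [build_followup_pairs()].
#' @param panel Character vector of marker names, or a panel data frame
#'   from [rank_variables()] / [merge_and_rerank()].
#' @return An object of class \code{"dkd_cohort_matrix"}: list with
#'   \code{X}, \code{y}, \code{groups}, \code{arms}, \code{pair_ids},
#'   \code{panel}, \code{center}, \code{scale}, \code{n_dropped}.
#' @export
assemble_matrix <- function(pairs, panel) {
  markers <- panel_markers(panel)
  unknown <- setdiff(markers, names(pairs))
  if (length(unknown)) {
    stop("panel markers absent from the pair table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(pairs[, markers, drop = FALSE])
  storage.mode(X) <- "double"
  ok <- complete.cases(X) & is.finite(pairs$delta_egfr)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("assemble_matrix: %d rows dropped (missing panel values)", n_dropped))
  }
  X <- X[ok, , drop = FALSE]
  if (nrow(X) == 0L) stop("no complete-case rows remain", call. = FALSE)
  structure(list(
    X = X,
    y = pairs$delta_egfr[ok],
    groups = as.character(pairs$patient_id[ok]),
    arms = if ("arm" %in% names(pairs)) as.character(pairs$arm[ok]) else NULL,
    pair_ids = as.character(pairs$pair_id[ok]),
    panel = markers,
    center = colMeans(X),
    scale = apply(X, 2, sd),
    n_dropped = n_dropped
  ), class = "dkd_cohort_matrix")
}

# Subset a cohort matrix by row index (used by grouped CV).
subset_cohort_matrix <- function(cm, idx) {
  structure(list(
    X = cm$X[idx, , drop = FALSE],
    y = cm$y[idx],
    groups = cm$groups[idx],
    arms = cm$arms[idx],
    pair_ids = cm$pair_ids[idx],
    panel = cm$panel,
    center = cm$center,
    scale = cm$scale,
    n_dropped = 0L
  ), class = "dkd_cohort_matrix")
}

#' @export
print.dkd_cohort_matrix <- function(x, ...) {
  cat(sprintf("DKD cohort matrix: %d pairs x %d markers (%d patients)\n",
              nrow(x$X), ncol(x$X), length(unique(x$groups))))
  cat("markers:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

# Accept either a character vector or a panel data frame.
panel_markers <- function(panel) {
  if (is.character(panel)) return(panel)
  if (is.data.frame(panel) && "marker" %in% names(panel)) return(panel$marker)
  stop("panel must be a character vector or a data frame with a 'marker' column",
       call. = FALSE)
}
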