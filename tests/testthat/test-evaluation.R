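# Brute-force counting oracle for the confusion matrix: loop over elements,
# label observations with the CD/UCD thresholds, call a prediction positive
# below the cutoff.
oracle_confusion <- function(pred, obs, cutoff = -10) {
  tp <- fp <- tn <- fn <- 0L; excl <- 0L
  for (i in seq_along(pred)) {
    if (obs[i] >= -5) pos_obs <- FALSE
    else if (obs[i] < -10) pos_obs <- TRUE
    else { excl <- excl + 1L; next }
    pos_pred <- pred[i] < cutoff
    if (pos_pred && pos_obs) tp <- tp + 1L
    else if (pos_pred && !pos_obs) fp <- fp + 1L
    else if (!pos_pred && pos_obs) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn, excl = excl)
}

test_that("allocation metrics match hand-counted confusion matrices", {
  # constructed to give TP=3, FN=1, TN=5, FP=1
  obs <- c(-12, -13, -14, -11, -1, 0, -2, -3, -4, -1)
  pred <- c(-12, -12, -12, -8, -1, -1, -1, -1, -1, -12)
  rep <- evaluate_allocation(pred, obs)
  expect_equal(c(rep$tp, rep$fn, rep$tn, rep$fp), c(3, 1, 5, 1))
  expect_equal(rep$se, 0.75)
  expect_equal(rep$sp, 5 / 6)
  expect_equal(rep$acc, 0.8)
})

test_that("perfect predictions on a CD/UCD-only set score 1 everywhere", {
  obs <- c(-15, -12, -20, -2, 0, -4)
  rep <- evaluate_allocation(obs, obs)
  expect_equal(c(rep$acc, rep$se, rep$sp), c(1, 1, 1))
  expect_equal(rep$n_indeterminate, 0)
})

test_that("empty classes give NA metrics, not zero", {
  obs <- c(-1, -2, -3)          # no observed UCD
  rep <- evaluate_allocation(c(-12, -1, -1), obs)
  expect_true(is.na(rep$se))
  expect_equal(rep$sp, 2 / 3)
  expect_equal(rep$acc, 2 / 3)
  expect_error(evaluate_allocation(1:3, 1:4), "equal length")
})

test_that("metrics agree with the counting oracle on random vectors", {
  set.seed(9)
  for (rep_i in 1:100) {
    n <- sample(5:40, 1)
    obs <- runif(n, -20, 5)
    pred <- runif(n, -20, 5)
    got <- evaluate_allocation(pred, obs)
    want <- oracle_confusion(pred, obs)
    expect_identical(c(got$tp, got$fp, got$tn, got$fn, got$n_indeterminate),
                     c(want$tp, want$fp, want$tn, want$fn, want$excl))
    n_eval <- with(want, tp + fp + tn + fn)
    if (n_eval > 0) {
      expect_equal(got$acc, (want$tp + want$tn) / n_eval, tolerance = 1e-12)
    }
  }
})

test_that("grouped CV keeps patients intact and pools by summed confusion", {
  pairs <- fixture_pairs()
  rasi <- pairs[pairs$arm == "RASi", ]
  cm <- assemble_matrix(rasi, reduced_panel()$marker)
  cv <- grouped_cv(cm, k = 4, plsnn_control(ncomp = 2), seed = 13)

  # every patient's pairs land in exactly one test fold
  fold_by_patient <- tapply(cv$predictions$fold,
                            cm$groups[match(cv$predictions$pair_id, cm$pair_ids)],
                            function(f) length(unique(f)))
  expect_true(all(fold_by_patient == 1))
  # a patient with repeated pairs exists in the fixture and stays together
  expect_gt(max(table(cm$groups)), 1)

  pooled <- cv$pooled
  for (fld in c("tp", "fp", "tn", "fn")) {
    expect_equal(pooled[[fld]], sum(vapply(cv$folds, `[[`, 0, fld)))
  }
  expect_equal(nrow(cv$predictions), nrow(cm$X))
  expect_error(grouped_cv(cm, k = 1e6), "folds")
})

test_that("leave-one-patient-out is supported", {
  set.seed(10)
  X <- matrix(rnorm(24 * 3), 24)
  colnames(X) <- paste0("x", 1:3)
  pairs <- as.data.frame(X)
  pairs$pair_id <- sprintf("p%d", 1:24)
  pairs$patient_id <- sprintf("pt%d", rep(1:12, each = 2))
  pairs$arm <- "RASi"
  pairs$delta_egfr <- drop(X %*% c(-4, 2, 0)) + rnorm(24, -6, 3)
  cm <- assemble_matrix(pairs, colnames(X))
  cv <- grouped_cv(cm, k = 12, plsnn_control(ncomp = 1, k_centers = 4), seed = 2)
  expect_length(cv$folds, 12)
  expect_equal(cv$pooled$n_evaluated + cv$pooled$n_indeterminate, 24)
})
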