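as_benefit <- function(df) {
  class(df) <- c("benefit_estimate", "data.frame")
  df
}

test_that("benefit is exactly the vertical distance between arm models", {
  est <- estimate_benefit(fixture_model_set(), fixture_pairs())
  for (arm in c("GLP1a", "MCRa", "SGLT2i")) {
    expect_identical(est[[paste0("benefit_", arm)]],
                     est[[paste0("delta_", arm)]] - est$delta_RASi)
  }
  expect_identical(est$label_RASi, classify_outcome(est$delta_RASi))
})

test_that("using one model for two arms yields zero benefit", {
  mset <- fixture_model_set()
  twin <- mset
  twin$models$GLP1a <- mset$models$RASi
  est <- estimate_benefit(twin, fixture_pairs()[1:20, ])
  expect_equal(est$benefit_GLP1a, rep(0, 20))
})

test_that("recommendations follow the stay/add decision rule", {
  est <- as_benefit(data.frame(
    delta_RASi = c(2, -12, -12, -6),
    delta_GLP1a = c(1, -8, -13, -6),
    delta_MCRa = c(1, -6, -14, -6),
    delta_SGLT2i = c(1, -2, -15, -6)
  ))
  rec <- recommend_treatment(est)
  # CD predicted -> stay regardless of add-on predictions
  expect_equal(rec$action[1], "stay")
  expect_false(rec$flagged[1])
  # argmax over add-on deltas
  expect_equal(rec$action[2], "add_SGLT2i")
  expect_equal(rec$best_benefit[2], 10)
  # no positive benefit -> stay, flagged
  expect_equal(rec$action[3], "stay")
  expect_true(rec$flagged[3])
  # tie on deltas -> fixed order GLP1a first; benefit 0 is not positive
  expect_equal(rec$best_addon[4], "GLP1a")
  expect_equal(rec$action[4], "stay")
})

test_that("undersized arms are rejected by name", {
  pairs <- fixture_pairs()
  small <- pairs[pairs$arm != "GLP1a" | seq_len(nrow(pairs)) %in%
                   head(which(pairs$arm == "GLP1a"), 10), ]
  expect_error(fit_treatment_models(small, reduced_panel()$marker, min_n = 30),
               "'GLP1a' has 10 pairs")
})

test_that("identical data and seed give byte-identical serialized models", {
  pairs <- fixture_pairs()
  panel <- reduced_panel()$marker
  ctrl <- plsnn_control(ncomp = 2)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  write_model_set(fit_treatment_models(pairs, panel, ctrl, seed = 42), f1)
  write_model_set(fit_treatment_models(pairs, panel, ctrl, seed = 42), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("cross-prediction recovers calibration and rescue structure", {
  mset <- fixture_model_set()
  pairs <- fixture_pairs()
  # RASi model on its own arm: roughly calibrated overall
  cp_r <- cross_predict(mset, pairs[pairs$arm == "RASi", ])
  expect_lt(abs(cp_r$overall_mean_residual), 1)
  # add-on arms: positive mean residual where poor prognosis is predicted
  cp_a <- cross_predict(mset, pairs[pairs$arm != "RASi", ])
  s <- cp_a$summary
  expect_equal(s$n, as.vector(table(cp_a$per_pair$stratum)[s$stratum]))
  expect_gt(s$mean_residual[s$stratum == "< -10"], 0)
})

test_that("a null add-on arm shows no systematic residual", {
  cfg <- generator_config(
    n_pairs = c(RASi = 150, GLP1a = 60, MCRa = 40, SGLT2i = 40),
    effect_rho = c(GLP1a = 0, MCRa = 0.5, SGLT2i = 0.7),
    seed = 31)
  coh <- generate_cohort(cfg)
  pairs <- build_followup_pairs(coh$visits)
  mset <- fit_treatment_models(pairs, reduced_panel()$marker,
                               plsnn_control(ncomp = 2), seed = 8)
  cp <- cross_predict(mset, pairs[pairs$arm == "GLP1a", ])
  # overall t statistic of the mean residual is unremarkable under the null
  t_overall <- cp$overall_mean_residual /
    (sd(cp$per_pair$residual) / sqrt(nrow(cp$per_pair)))
  expect_lt(abs(t_overall), 3)
})
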