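test_that("MDRD eGFR matches hand-computed values and scaling laws", {
  # 175 * 1^-1.154 * 50^-0.203, evaluated independently with a calculator
  expect_equal(compute_egfr_mdrd(1.0, 50, is_female = FALSE, is_black = FALSE),
               79.09466, tolerance = 1e-6)
  male <- compute_egfr_mdrd(1.0, 50)
  expect_equal(compute_egfr_mdrd(1.0, 50, is_female = TRUE), 0.742 * male)
  expect_equal(compute_egfr_mdrd(2.0, 50), male / 2^1.154)
  expect_equal(compute_egfr_mdrd(1.0, 50, is_black = TRUE), 1.212 * male)
  expect_error(compute_egfr_mdrd(0, 50), "creatinine")
  expect_error(compute_egfr_mdrd(1, -4), "age")
})

test_that("annual percent eGFR change is linearly annualized", {
  expect_equal(compute_delta_egfr(60, 60, 1), 0)
  expect_equal(compute_delta_egfr(60, 54, 1), -10)
  expect_equal(compute_delta_egfr(80, 72, 2), -5)  # two-year interval
  expect_error(compute_delta_egfr(0, 60, 1), "baseline")
  expect_error(compute_delta_egfr(60, 60, 0), "interval")
  # sign of the change matches the sign of the eGFR difference
  set.seed(1)
  b <- runif(50, 30, 90); f <- runif(50, 20, 100)
  expect_equal(sign(compute_delta_egfr(b, f, 1)), sign(f - b))
})

test_that("CD/UCD labelling partitions the real line at the stated thresholds", {
  expect_equal(classify_outcome(-4), "CD")
  expect_equal(classify_outcome(-12), "UCD")
  expect_equal(classify_outcome(c(-7.5, -10, -5)),
               c("indeterminate", "indeterminate", "CD"))
  expect_error(classify_outcome(NaN), "finite")
  set.seed(2)
  lab <- classify_outcome(runif(500, -30, 10))
  expect_true(all(lab %in% c("CD", "UCD", "indeterminate")))
  d <- runif(500, -30, 10)
  lab <- classify_outcome(d)
  expect_identical(lab == "CD", d >= -5)
  expect_identical(lab == "UCD", d < -10)
})

test_that("the inclusion window is closed at both ends", {
  v <- data.frame(patient_id = letters[1:5], visit_idx = 0L,
                  egfr = c(29, 30, 60, 90, 91))
  kept <- filter_inclusion(v)
  expect_equal(kept$egfr, c(30, 60, 90))
  log <- attr(kept, "exclusion_log")
  expect_equal(log$n[log$reason == "egfr_below_lower"], 1)
  expect_equal(log$n[log$reason == "egfr_above_upper"], 1)
})

test_that("follow-up pairs enumerate consecutive visit couples", {
  pairs <- build_followup_pairs(toy_visits(), inclusion = NULL)
  # A: 4 visits -> 3 pairs; B: 2 visits -> 1 pair; C: 3 visits but eGFR
  # missing at the last one -> only the first couple survives
  expect_equal(sum(pairs$patient_id == "A"), 3)
  expect_equal(sum(pairs$patient_id == "B"), 1)
  expect_equal(sum(pairs$patient_id == "C"), 1)
  expect_equal(pairs$arm[pairs$patient_id == "B"], "GLP1a")
  expect_equal(pairs$delta_egfr[pairs$pair_id == "B_p0"], -10)
  # baseline markers are carried, not follow-up ones
  expect_equal(pairs$M1[pairs$pair_id == "A_p1"], 2)
  log <- attr(pairs, "pair_log")
  expect_equal(log$n[log$reason == "dropped_missing_egfr"], 1)
})

test_that("pair counts match a brute-force enumeration on random tables", {
  set.seed(42)
  for (rep in 1:10) {
    n_pat <- sample(3:8, 1)
    rows <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
      nv <- sample(1:5, 1)
      data.frame(patient_id = sprintf("P%d", i), visit_idx = seq_len(nv) - 1L,
                 arm = "RASi",
                 egfr = ifelse(runif(nv) < 0.15, NA, runif(nv, 25, 95)))
    }))
    pairs <- build_followup_pairs(rows, inclusion = c(30, 90))
    expected <- 0L
    for (i in seq_len(n_pat)) {
      sub <- rows[rows$patient_id == sprintf("P%d", i), ]
      sub <- sub[order(sub$visit_idx), ]
      if (nrow(sub) < 2) next
      for (j in seq_len(nrow(sub) - 1)) {
        b <- sub$egfr[j]; f <- sub$egfr[j + 1]
        if (!is.na(b) && !is.na(f) && b >= 30 && b <= 90) expected <- expected + 1L
      }
    }
    expect_equal(nrow(pairs), expected)
  }
})

test_that("matrix assembly is complete-case with panel column order", {
  pairs <- fixture_pairs()[1:10, ]
  panel <- c("LEP", "eGFR", "SBP")
  cm <- assemble_matrix(pairs, panel)
  expect_equal(colnames(cm$X), panel)
  expect_equal(nrow(cm$X), 10)
  expect_equal(cm$y, pairs$delta_egfr)

  pairs$LEP[c(2, 7)] <- NA
  expect_message(cm2 <- assemble_matrix(pairs, panel), "2 rows dropped")
  expect_equal(nrow(cm2$X), 8)
  expect_equal(cm2$n_dropped, 2)

  expect_error(assemble_matrix(pairs, c("eGFR", "XYZ")), "XYZ")
})
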