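# Shared fixtures, built once per test run. The default cohort mirrors the
# study arm sizes (277/52/64/104 pairs) and is reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(generator_config(seed = 7))
  }
  .fixtures$cohort
}

fixture_pairs <- function() {
  if (is.null(.fixtures$pairs)) {
    .fixtures$pairs <- build_followup_pairs(fixture_cohort()$visits)
  }
  .fixtures$pairs
}

fixture_model_set <- function() {
  if (is.null(.fixtures$mset)) {
    .fixtures$mset <- fit_treatment_models(fixture_pairs(),
                                           reduced_panel()$marker, seed = 42)
  }
  .fixtures$mset
}

# Truth rows aligned with a pair table.
truth_for <- function(pairs) {
  truth <- fixture_cohort()$truth
  truth[match(pairs$pair_id, truth$pair_id), ]
}

# Hand-built visit table: one row per visit, explicit arm per interval.
toy_visits <- function() {
  data.frame(
    patient_id = c("A", "A", "A", "A", "B", "B", "C", "C", "C"),
    visit_idx = c(0L, 1L, 2L, 3L, 0L, 1L, 0L, 1L, 2L),
    visit_year = 2015L,
    arm = c("RASi", "RASi", "RASi", "RASi", "GLP1a", "GLP1a",
            "RASi", "RASi", "RASi"),
    egfr = c(60, 57, 54, 50, 80, 72, 45, 44, NA),
    M1 = 1:9,
    M2 = seq(0.1, 0.9, by = 0.1),
    stringsAsFactors = FALSE
  )
}
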