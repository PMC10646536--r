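# Synthetic longitudinal DKD cohort generator.
#
# Emulates the structure of an observational diabetic-kidney-disease cohort
# with four treatment arms (RASi alone; RASi + GLP1a / MCRa / SGLT2i added
# after baseline), correlated continuous baseline markers driven by a small
# number of latent factors, and an annual-percent-change eGFR outcome whose
# add-on benefit is concentrated in patients with a poor RASi-only
# prognosis. Ground truth (latents, prognosis, per-drug effects) is emitted
# alongside the visit table so downstream estimators can be validated.

#' Default latent-factor marker model
#'
#' Loadings, noise SDs and affine clinical-scale maps for the nine
#' consensus markers plus \code{n_noise} pure-noise markers. Markers are
#' generated as \code{center + spread * (loadings %*% u + noise)}; the eGFR
#' marker instead uses a bounded map
#' \code{center + spread * tanh(raw / 2)} so baseline eGFR always lies
#' inside the 30-90 inclusion window.
#'
#' @param n_noise Number of uninformative markers appended (default 6).
#' @return Data frame with columns \code{marker}, \code{l1}, \code{l2},
#'   \code{noise_sd}, \code{center}, \code{spread}.
#' @export
default_marker_model <- function(n_noise = 6) {
  core <- data.frame(
    marker = c("eGFR", "DPP4", "ICAM1", "LEP", "AGE", "ADIPOQ", "TOTCHOL",
               "SBP", "SERPINE1"),
    l1 = c(-0.9, 0.8, 0.7, 0.6, 0.4, -0.5, 0.3, 0.5, 0.7),
    l2 = c(0.1, 0.2, -0.3, 0.5, -0.4, 0.6, 0.7, 0.4, 0.3),
    noise_sd = c(0.5, 0.5, 0.5, 0.5, 0.6, 0.5, 0.6, 0.5, 0.5),
    center = c(60, 400, 250, 22, 66, 10, 190, 140, 25),
    spread = c(25, 120, 60, 6, 6, 3, 30, 12, 7),
    stringsAsFactors = FALSE
  )
  if (n_noise > 0) {
    core <- rbind(core, data.frame(
      marker = paste0("NOISE", seq_len(n_noise)),
      l1 = 0, l2 = 0, noise_sd = 1, center = 0, spread = 1,
      stringsAsFactors = FALSE
    ))
  }
  core
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_pairs Named counts of follow-up pairs per arm; defaults mirror
#'   the study arm sizes 277 (RASi), 52 (GLP1a), 64 (MCRa), 104 (SGLT2i).
#' @param n_latent Number of latent factors driving the markers (default 2).
#' @param marker_model Data frame as returned by [default_marker_model()]
#'   (loadings columns \code{l1..l<n_latent>}, \code{noise_sd},
#'   \code{center}, \code{spread}).
#' @param n_noise_markers Pure-noise markers appended by the default model.
#' @param prognosis Parameters (a, b, c) of the true RASi-only prognosis
#'   \code{f(u) = a - b * softplus(c * u1)} in %/yr; defaults span roughly
#'   +5 to -25 %/yr.
#' @param effect_rho Named rescue strengths of the add-on drugs; the true
#'   additive effect is \code{g_X(u) = rho_X * max(0, -(f(u) + 5))}.
#' @param rescue_threshold Prognosis level (%/yr) below which add-on rescue
#'   switches on (default -5, the controlled-disease boundary).
#' @param outcome_noise_sd SD of the outcome noise in %/yr (default 2).
#' @param balance_cd_ucd If TRUE (default), the RASi arm is sampled so that
#'   CD and UCD counts are approximately equal.
#' @param balance_tol Relative tolerance for the CD/UCD imbalance (default
#'   0.1: counts differ by at most 10% of their sum).
#' @param max_attempts Cap on consecutive rejected candidate patients
#'   during rejection sampling (default 1000).
#' @param repeat_fraction Fraction of RASi-arm patients contributing two
#'   consecutive pairs (default 0.3); add-on patients contribute one pair.
#' @param addon_sick_fraction Fraction of add-on patients drawn from the
#'   poor-prognosis region f(u) < rescue_threshold, emulating indication
#'   bias (default 0.5).
#' @param ar_phi AR(1) correlation of the latent factors across a patient's
#'   consecutive visits (default 0.8).
#' @param interval_years Visit spacing (default 1).
#' @param egfr_bounds Inclusion window for baseline eGFR (default 30-90).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return Validated config list of class \code{"dkd_generator_config"}.
#' @export
generator_config <- function(n_pairs = c(RASi = 277, GLP1a = 52, MCRa = 64,
                                         SGLT2i = 104),
                             n_latent = 2,
                             n_noise_markers = 6,
                             marker_model = default_marker_model(n_noise_markers),
                             prognosis = list(a = 5, b = 6, c = 1.5),
                             effect_rho = c(GLP1a = 0.6, MCRa = 0.5, SGLT2i = 0.7),
                             rescue_threshold = -5,
                             outcome_noise_sd = 2,
                             balance_cd_ucd = TRUE,
                             balance_tol = 0.1,
                             max_attempts = 1000,
                             repeat_fraction = 0.3,
                             addon_sick_fraction = 0.5,
                             ar_phi = 0.8,
                             interval_years = 1,
                             egfr_bounds = c(30, 90),
                             seed = 1) {
  cfg <- list(n_pairs = n_pairs, n_latent = n_latent,
              marker_model = marker_model, prognosis = prognosis,
              effect_rho = effect_rho, rescue_threshold = rescue_threshold,
              outcome_noise_sd = outcome_noise_sd,
              balance_cd_ucd = balance_cd_ucd, balance_tol = balance_tol,
              max_attempts = max_attempts, repeat_fraction = repeat_fraction,
              addon_sick_fraction = addon_sick_fraction, ar_phi = ar_phi,
              interval_years = interval_years, egfr_bounds = egfr_bounds,
              seed = seed)
  validate_generator_config(cfg)
  structure(cfg, class = "dkd_generator_config")
}

validate_generator_config <- function(cfg) {
  if (!"RASi" %in% names(cfg$n_pairs)) stop("n_pairs must include a 'RASi' arm")
  if (any(cfg$n_pairs <= 0)) stop("all arm pair counts must be positive")
  if (cfg$outcome_noise_sd < 0) stop("outcome_noise_sd must be >= 0")
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction > 1) {
    stop("repeat_fraction must lie in [0, 1]")
  }
  mm <- cfg$marker_model
  lcols <- paste0("l", seq_len(cfg$n_latent))
  if (!all(c("marker", lcols, "noise_sd", "center", "spread") %in% names(mm))) {
    stop("marker_model lacks required columns for n_latent = ", cfg$n_latent)
  }
  if (anyDuplicated(mm$marker)) stop("marker_model has duplicated marker names")
  addons <- setdiff(names(cfg$n_pairs), "RASi")
  if (!all(addons %in% names(cfg$effect_rho))) {
    stop("effect_rho must name every add-on arm in n_pairs")
  }
  invisible(cfg)
}

# Numerically safe softplus.
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' True RASi-only prognosis function of the generator
#'
#' \code{f(u) = a - b * softplus(c * u1)}: smooth and monotone decreasing in
#' the first latent factor, spanning roughly +5 to -25 %/yr at the default
#' parameters.
#'
#' @param u1 First latent factor value(s).
#' @param prognosis Parameter list (a, b, c) as in [generator_config()].
#' @return True annual eGFR change under RASi alone, %/yr.
#' @export
true_prognosis <- function(u1, prognosis = generator_config()$prognosis) {
  prognosis$a - prognosis$b * softplus(prognosis$c * u1)
}

#' True add-on rescue effect of the generator
#'
#' \code{g_X = rho * max(0, -(f + 5))} at the default threshold: the add-on
#' benefit is proportional to how far the RASi-only prognosis falls below
#' -5 %/yr, so the worse the prognosis, the larger the rescue.
#'
#' @param f_true True RASi-only prognosis values (%/yr).
#' @param rho Rescue strength of the drug.
#' @param threshold Prognosis level below which rescue switches on.
#' @return True additive treatment effect, %/yr (non-negative).
#' @export
true_addon_effect <- function(f_true, rho, threshold = -5) {
  rho * pmax(0, threshold - f_true)
}

# First-latent threshold above which f(u1) < rescue_threshold.
sick_u1_threshold <- function(cfg) {
  pr <- cfg$prognosis
  # f(u1) = thr  <=>  softplus(c u1) = (a - thr) / b
  s <- (pr$a - cfg$rescue_threshold) / pr$b
  log(expm1(s)) / pr$c
}

# Generate one patient's block of visits for a given arm.
# Returns NULL when a baseline eGFR leaves the inclusion window (the block
# is then rejected and redrawn by the caller).
generate_patient_block <- function(cfg, arm, n_pairs_block, sick, patient_id) {
  mm <- cfg$marker_model
  nl <- cfg$n_latent
  L <- as.matrix(mm[, paste0("l", seq_len(nl)), drop = FALSE])
  nv <- n_pairs_block + 1L
  e_row <- match("eGFR", mm$marker)

  U <- matrix(0, nv, nl)
  U[1, ] <- rnorm(nl)
  if (sick) {
    thr <- sick_u1_threshold(cfg)
    U[1, 1] <- qnorm(runif(1, pnorm(thr), 1))
  }
  if (nv > 1) {
    for (v in 2:nv) {
      U[v, ] <- cfg$ar_phi * U[v - 1, ] + sqrt(1 - cfg$ar_phi^2) * rnorm(nl)
    }
  }

  raw <- U %*% t(L) + matrix(rnorm(nv * nrow(mm)), nv) *
    rep(mm$noise_sd, each = nv)                      # visits x markers
  vals <- sweep(sweep(raw, 2, mm$spread, `*`), 2, mm$center, `+`)
  # bounded eGFR map for the entry visit; later visits derive from the outcome
  egfr <- numeric(nv)
  egfr[1] <- mm$center[e_row] + mm$spread[e_row] * tanh(raw[1, e_row] / 2)

  f_true <- true_prognosis(U[seq_len(n_pairs_block), 1], cfg$prognosis)
  g_own <- if (arm == "RASi") {
    rep(0, n_pairs_block)
  } else {
    true_addon_effect(f_true, cfg$effect_rho[[arm]], cfg$rescue_threshold)
  }
  eps <- rnorm(n_pairs_block, 0, cfg$outcome_noise_sd)
  delta <- f_true + g_own + eps
  for (k in seq_len(n_pairs_block)) {
    egfr[k + 1] <- egfr[k] * (1 + delta[k] * cfg$interval_years / 100)
  }
  baselines <- egfr[seq_len(n_pairs_block)]
  if (any(baselines < cfg$egfr_bounds[1] | baselines > cfg$egfr_bounds[2])) {
    return(NULL)
  }
  vals[, e_row] <- egfr

  addons <- intersect(c("GLP1a", "MCRa", "SGLT2i"), names(cfg$effect_rho))
  g_all <- vapply(addons, function(a) {
    true_addon_effect(f_true, cfg$effect_rho[[a]], cfg$rescue_threshold)
  }, numeric(n_pairs_block))
  g_all <- matrix(g_all, nrow = n_pairs_block,
                  dimnames = list(NULL, paste0("g_", addons)))

  visits <- data.frame(
    patient_id = patient_id,
    visit_idx = seq_len(nv) - 1L,
    visit_year = 2015L + seq_len(nv) - 1L,
    arm = arm,
    egfr = egfr,
    stringsAsFactors = FALSE
  )
  visits <- cbind(visits, as.data.frame(vals, optional = TRUE))
  names(visits)[-(1:5)] <- mm$marker

  truth <- data.frame(
    pair_id = sprintf("%s_p%d", patient_id, seq_len(n_pairs_block) - 1L),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(nl)) truth[[paste0("u", j)]] <- U[seq_len(n_pairs_block), j]
  truth$f_true <- f_true
  truth <- cbind(truth, as.data.frame(g_all))

  list(visits = visits, truth = truth,
       labels = classify_outcome(delta))
}

#' Generate a synthetic DKD cohort with ground truth
#'
#' Draws patients arm by arm from the generative model described in
#' [generator_config()]. RASi-arm patients may contribute two consecutive
#' annual pairs (latent factors evolve as an AR(1) across visits); when
#' \code{balance_cd_ucd} is set, candidate RASi patients are accepted
#' greedily under class quotas until the CD and UCD counts are within
#' \code{balance_tol} of each other. Add-on patients contribute one pair,
#' with a configurable fraction drawn from the poor-prognosis region
#' (indication bias). Follow-up eGFR is derived from baseline eGFR and the
#' observed annual change.
#'
#' @param config A [generator_config()] object.
#' @return List of class \code{"dkd_cohort"} with elements \code{visits}
#'   (long-format visit table; columns \code{patient_id}, \code{visit_idx},
#'   \code{visit_year}, \code{arm}, \code{egfr}, one column per marker) and
#'   \code{truth} (one row per pair: \code{pair_id}, latents \code{u*},
#'   \code{f_true}, and the hypothetical per-drug effects \code{g_GLP1a},
#'   \code{g_MCRa}, \code{g_SGLT2i}).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  with_local_seed(config$seed, {
    visits_list <- list()
    truth_list <- list()

    # --- RASi arm, optionally class-balanced -----------------------------
    n_tot <- config$n_pairs[["RASi"]]
    if (config$balance_cd_ucd) {
      ind_cap <- floor(0.10 * n_tot)
      cap <- floor((1 + config$balance_tol) * (n_tot - ind_cap) / 2)
      while (2 * cap + ind_cap < n_tot) cap <- cap + 1L
      caps <- c(CD = cap, UCD = cap, indeterminate = ind_cap)
    } else {
      caps <- c(CD = Inf, UCD = Inf, indeterminate = Inf)
    }
    counts <- c(CD = 0L, UCD = 0L, indeterminate = 0L)
    filled <- 0L
    pid <- 0L
    rejects <- 0L
    while (filled < n_tot) {
      slots <- n_tot - filled
      npb <- if (slots >= 2L && runif(1) < config$repeat_fraction) 2L else 1L
      blk <- generate_patient_block(config, "RASi", npb, sick = FALSE,
                                    patient_id = sprintf("R%04d", pid + 1L))
      add <- if (is.null(blk)) NULL else table(factor(blk$labels, names(counts)))
      ok <- !is.null(blk) && all(counts + add <= caps)
      if (ok) {
        pid <- pid + 1L
        blk$visits$patient_id <- sprintf("R%04d", pid)
        blk$truth$pair_id <- sprintf("R%04d_p%d", pid, seq_len(npb) - 1L)
        visits_list[[length(visits_list) + 1L]] <- blk$visits
        truth_list[[length(truth_list) + 1L]] <- blk$truth
        counts <- counts + as.integer(add)
        filled <- filled + npb
        rejects <- 0L
      } else {
        rejects <- rejects + 1L
        if (rejects > config$max_attempts) {
          stop(sprintf(
            "RASi-arm rejection sampling failed after %d consecutive attempts (CD=%d, UCD=%d, indeterminate=%d)",
            config$max_attempts, counts[["CD"]], counts[["UCD"]],
            counts[["indeterminate"]]), call. = FALSE)
        }
      }
    }

    # --- add-on arms -----------------------------------------------------
    addons <- setdiff(names(config$n_pairs), "RASi")
    prefixes <- c(GLP1a = "G", MCRa = "M", SGLT2i = "S")
    for (arm in addons) {
      prefix <- prefixes[[arm]] %||% substr(arm, 1, 1)
      for (i in seq_len(config$n_pairs[[arm]])) {
        rejects <- 0L
        repeat {
          sick <- runif(1) < config$addon_sick_fraction
          blk <- generate_patient_block(config, arm, 1L, sick = sick,
                                        patient_id = sprintf("%s%04d", prefix, i))
          if (!is.null(blk)) break
          rejects <- rejects + 1L
          if (rejects > config$max_attempts) {
            stop(sprintf("%s-arm rejection sampling failed after %d attempts",
                         arm, config$max_attempts), call. = FALSE)
          }
        }
        visits_list[[length(visits_list) + 1L]] <- blk$visits
        truth_list[[length(truth_list) + 1L]] <- blk$truth
      }
    }

    visits <- do.call(rbind, visits_list)
    truth <- do.call(rbind, truth_list)
    rownames(visits) <- rownames(truth) <- NULL
    structure(list(visits = visits, truth = truth, config = config),
              class = "dkd_cohort")
  })
}

#' @export
print.dkd_cohort <- function(x, ...) {
  pairs_per_arm <- table(x$visits$arm[!duplicated(x$visits$patient_id)])
  cat(sprintf("Synthetic DKD cohort: %d visits, %d patients, %d pairs\n",
              nrow(x$visits), length(unique(x$visits$patient_id)),
              nrow(x$truth)))
  cat("arms (patients):",
      paste(sprintf("%s=%d", names(pairs_per_arm), pairs_per_arm), collapse = ", "),
      "\n")
  invisible(x)
}

#' Ground-truth add-on effect for every generated pair
#'
#' Oracle accessor used to validate benefit estimation: returns the stored
#' generative effect \code{g_X(u)} of an add-on drug for each pair of the
#' truth table, in %/yr.
#'
#' @param truth Truth table from [generate_cohort()] (or a
#'   \code{"dkd_cohort"} object).
#' @param arm One of \code{"GLP1a"}, \code{"MCRa"}, \code{"SGLT2i"}.
#' @return Numeric vector, one value per pair.
#' @export
true_benefit <- function(truth, arm) {
  if (inherits(truth, "dkd_cohort")) truth <- truth$truth
  col <- paste0("g_", arm)
  if (!col %in% names(truth)) {
    stop(sprintf("unknown add-on arm '%s'", arm), call. = FALSE)
  }
  truth[[col]]
}
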