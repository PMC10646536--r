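# The hybrid PLSNN model: a PLS latent projection (collinearity removal +
# dimension reduction) feeding a normalized Gaussian RBF network (smooth
# non-linear regression that extracts structure from small samples). The
# fitted RASi-arm model's prediction is the composite biomarker Delta_R.

#' Hyperparameters of the PLSNN model
#'
#' @param ncomp Number of PLS components; \code{NULL} (default) selects it
#'   by grouped cross-validation over 1..\code{a_max}.
#' @param a_max Upper bound for the component search (default 5).
#' @param cv_folds Folds for the grouped component search (default 5).
#' @param k_centers RBF centers; default \code{min(ceiling(n/3), 25)}.
#' @param width_scale Kernel width as a multiple of the median pairwise
#'   center distance (default 1).
#' @param lambda Ridge penalty on the RBF output weights (default 1e-3).
#' @param include_linear If TRUE (default), the PLS linear prediction is
#'   appended to the latent scores as an extra network input, so the
#'   network starts from the linear fit and models the remainder.
#' @return List of class \code{"plsnn_control"}.
#' @export
plsnn_control <- function(ncomp = NULL, a_max = 5, cv_folds = 5,
                          k_centers = NULL, width_scale = 1, lambda = 1e-3,
                          include_linear = TRUE) {
  structure(list(ncomp = ncomp, a_max = a_max, cv_folds = cv_folds,
                 k_centers = k_centers, width_scale = width_scale,
                 lambda = lambda, include_linear = include_linear),
            class = "plsnn_control")
}

# Network input space: standardized (PLS scores [, linear prediction]).
plsnn_inputs <- function(pls, X, include_linear) {
  Z <- pls_scores(pls, X)
  if (include_linear) Z <- cbind(Z, predict(pls, X))
  unname(Z)
}

#' Fit a PLSNN model on a cohort matrix
#'
#' Standardizes the panel markers, fits PLS (components chosen by grouped
#' cross-validation unless fixed), projects to latent scores, and fits a
#' normalized RBF network on the (standardized) score space. All
#' randomness (CV folds, k-means initialization) flows from \code{seed},
#' and the fit is invariant to the row order of the data.
#'
#' @param cmatrix A \code{"dkd_cohort_matrix"} from [assemble_matrix()].
#' @param control A [plsnn_control()] list.
#' @param seed Integer seed.
#' @param arm Optional arm label stored with the model.
#' @return Object of class \code{"plsnn_model"}.
#' @export
fit_plsnn <- function(cmatrix, control = plsnn_control(), seed = 1, arm = NA) {
  stopifnot(inherits(cmatrix, "dkd_cohort_matrix"))
  X <- cmatrix$X
  y <- cmatrix$y
  n <- nrow(X)
  A <- control$ncomp %||%
    choose_ncomp(X, y, cmatrix$groups, control$a_max, control$cv_folds, seed)
  pls <- fit_pls(X, y, A)
  Z <- plsnn_inputs(pls, X, control$include_linear)
  z_center <- colMeans(Z)
  z_scale <- apply(Z, 2, sd)
  z_scale[z_scale == 0] <- 1
  Zs <- sweep(sweep(Z, 2, z_center, `-`), 2, z_scale, `/`)
  k <- control$k_centers %||% min(ceiling(n / 3), 25)
  if (k > n) {
    stop(sprintf("k_centers = %d exceeds the %d available pairs", k, n),
         call. = FALSE)
  }
  rbf <- fit_normalized_rbf(Zs, y, k, control$width_scale, control$lambda, seed)
  fitted <- rbf_predict(rbf, Zs)
  structure(list(panel = cmatrix$panel, pls = pls, rbf = rbf,
                 z_center = z_center, z_scale = z_scale,
                 include_linear = control$include_linear,
                 control = control, seed = seed, arm = arm,
                 n = n, sigma_resid = sd(y - fitted)),
            class = "plsnn_model")
}

#' Predict the annual eGFR change from a fitted PLSNN model
#'
#' Pure function of the stored parameters: standardize the panel markers,
#' project through the stored PLS fit, and evaluate the normalized RBF
#' network. Applied to the RASi-arm model, the returned value is the
#' composite biomarker Delta_R for that patient.
#'
#' @param model A \code{"plsnn_model"}.
#' @param newdata Data frame or matrix containing every panel marker
#'   (extra columns are ignored), all values finite.
#' @return Predicted annual eGFR change, %/yr.
#' @export
plsnn_predict <- function(model, newdata) {
  stopifnot(inherits(model, "plsnn_model"))
  if (is.data.frame(newdata)) {
    missing_m <- setdiff(model$panel, names(newdata))
    if (length(missing_m)) {
      stop("missing panel marker(s): ", paste(missing_m, collapse = ", "),
           call. = FALSE)
    }
    newdata <- as.matrix(newdata[, model$panel, drop = FALSE])
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(colnames(newdata))) {
      missing_m <- setdiff(model$panel, colnames(newdata))
      if (length(missing_m)) {
        stop("missing panel marker(s): ", paste(missing_m, collapse = ", "),
             call. = FALSE)
      }
      newdata <- newdata[, model$panel, drop = FALSE]
    }
  }
  X <- assert_numeric_matrix(newdata, "newdata")
  Z <- plsnn_inputs(model$pls, X, model$include_linear)
  Zs <- sweep(sweep(Z, 2, model$z_center, `-`), 2, model$z_scale, `/`)
  rbf_predict(model$rbf, Zs)
}

#' @export
predict.plsnn_model <- function(object, newdata, ...) {
  plsnn_predict(object, newdata)
}

#' @export
print.plsnn_model <- function(x, ...) {
  cat(sprintf("PLSNN model (%s arm): n = %d, %d-marker panel, %d PLS component(s), %d RBF centers\n",
              ifelse(is.na(x$arm), "unlabelled", x$arm), x$n,
              length(x$panel), x$pls$ncomp, nrow(x$rbf$centers)))
  cat(sprintf("training residual SD: %.3f %%/yr\n", x$sigma_resid))
  invisible(x)
}
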