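# Plain-text serialization: cohorts as CSV, models as JSON. The JSON writer
# stores numbers at full double precision so that a model round-trips to
# identical predictions and two identical runs produce byte-identical files.

#' Write a synthetic cohort to CSV files
#'
#' Writes \code{visits.csv} and \code{truth.csv} into \code{dir}.
#'
#' @param cohort A \code{"dkd_cohort"} from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dkd_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("visits.csv", "truth.csv"))
  write.csv(cohort$visits, paths[1], row.names = FALSE)
  write.csv(cohort$truth, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing \code{visits.csv} and \code{truth.csv}.
#' @return A list with \code{visits} and \code{truth} data frames.
#' @export
read_cohort <- function(dir) {
  list(visits = read.csv(file.path(dir, "visits.csv"), stringsAsFactors = FALSE),
       truth = read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE))
}

plsnn_to_list <- function(model) {
  list(
    panel = model$panel,
    arm = model$arm,
    n = model$n,
    seed = model$seed,
    include_linear = model$include_linear,
    sigma_resid = model$sigma_resid,
    pls = list(ncomp = model$pls$ncomp,
               W = model$pls$W, P = model$pls$P, q = model$pls$q,
               SS = model$pls$SS, R = model$pls$R, B = model$pls$B,
               center = model$pls$center, scale = model$pls$scale,
               y_center = model$pls$y_center, markers = model$pls$markers),
    z_center = model$z_center,
    z_scale = model$z_scale,
    rbf = list(centers = model$rbf$centers, sigma = model$rbf$sigma,
               lambda = model$rbf$lambda, weights = model$rbf$weights,
               d = model$rbf$d),
    control = unclass(model$control)
  )
}

plsnn_from_list <- function(x) {
  as_mat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    unname(m)
  }
  pls <- structure(list(
    ncomp = x$pls$ncomp,
    W = as_mat(x$pls$W), P = as_mat(x$pls$P),
    q = as.numeric(x$pls$q), SS = as.numeric(x$pls$SS),
    R = as_mat(x$pls$R), B = as_mat(x$pls$B),
    center = setNames(as.numeric(x$pls$center), x$pls$markers),
    scale = setNames(as.numeric(x$pls$scale), x$pls$markers),
    y_center = x$pls$y_center, markers = unlist(x$pls$markers)
  ), class = "pls_fit")
  rbf <- structure(list(centers = as_mat(x$rbf$centers), sigma = x$rbf$sigma,
                        lambda = x$rbf$lambda,
                        weights = as.numeric(x$rbf$weights), d = x$rbf$d),
                   class = "rbf_net")
  structure(list(panel = unlist(x$panel), pls = pls, rbf = rbf,
                 z_center = as.numeric(x$z_center),
                 z_scale = as.numeric(x$z_scale),
                 include_linear = isTRUE(x$include_linear),
                 control = do.call(plsnn_control, x$control[names(x$control) != "ncomp"]),
                 seed = x$seed, arm = x$arm, n = x$n,
                 sigma_resid = x$sigma_resid),
            class = "plsnn_model")
}

#' Serialize a treatment model set (or a single PLSNN model) to JSON
#'
#' @param object A \code{"treatment_model_set"} or \code{"plsnn_model"}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_model_set <- function(object, path) {
  payload <- if (inherits(object, "treatment_model_set")) {
    list(type = "treatment_model_set",
         panel = object$panel, n = as.list(object$n), seed = object$seed,
         models = lapply(object$models, plsnn_to_list))
  } else if (inherits(object, "plsnn_model")) {
    list(type = "plsnn_model", model = plsnn_to_list(object))
  } else {
    stop("object must be a treatment_model_set or plsnn_model", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a model file written by [write_model_set()]
#'
#' @param path JSON file path.
#' @return The deserialized \code{"treatment_model_set"} or
#'   \code{"plsnn_model"}.
#' @export
read_model_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$type, "plsnn_model")) return(plsnn_from_list(x$model))
  models <- lapply(x$models, plsnn_from_list)
  structure(list(models = models, panel = unlist(x$panel),
                 n = unlist(x$n), seed = x$seed),
            class = "treatment_model_set")
}

#' Write a biomarker panel as CSV
#'
#' @param panel A \code{"biomarker_panel"}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
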