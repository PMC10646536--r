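# Partial least squares regression (PLS1, NIPALS) with VIP-based variable
# ranking. PLS projects the standardized predictors onto a small number of
# latent components chosen to maximize covariance with the outcome, which
# makes it robust to the strong collinearity of clinical marker panels; at
# A = rank(X) its predictions coincide with ordinary least squares.

#' Fit a PLS1 regression model
#'
#' Deterministic NIPALS fit for a single continuous outcome. Predictors are
#' standardized internally (mean 0, SD 1) and the outcome is centered;
#' X is deflated after each component, so component scores are mutually
#' orthogonal on the training data.
#'
#' @param X Numeric matrix or data frame of predictors (n x p).
#' @param y Numeric outcome vector of length n.
#' @param ncomp Number of latent components A, 1 <= A <= min(n-1, p). If
#'   the residual covariance vanishes earlier, the fit is truncated (with a
#'   warning) to the attainable number of components.
#' @return Object of class \code{"pls_fit"}: weights \code{W}, loadings
#'   \code{P}, y-loadings \code{q}, per-component explained outcome sum of
#'   squares \code{SS}, projection matrix \code{R} (so scores are
#'   \code{X_std \%*\% R}), coefficients \code{B} in standardized predictor
#'   space, and the standardization statistics.
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- assert_numeric_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop(sprintf("ncomp must lie in [1, min(n-1, p)] = [1, %d]", min(n - 1, p)),
         call. = FALSE)
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0)) {
    stop("zero-variance predictor column(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, sdv, `/`)
  y_mu <- mean(y)

  E <- Xs
  f <- y - y_mu
  W <- P <- matrix(0, p, ncomp)
  q <- SS <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- E %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(E, t_a) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - t_a %*% t(p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
    SS[a] <- q_a^2 * tt
    a_used <- a
  }
  if (a_used == 0L) {
    stop("no covariance between predictors and outcome; PLS fit is degenerate",
         call. = FALSE)
  }
  if (a_used < ncomp) {
    warning(sprintf("PLS truncated at %d component(s); residual covariance vanished",
                    a_used))
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
    SS <- SS[seq_len(a_used)]
  }
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% q
  structure(list(ncomp = a_used, W = W, P = P, q = q, SS = SS, R = R, B = B,
                 center = mu, scale = sdv, y_center = y_mu,
                 markers = colnames(X)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS1 fit: %d predictors, %d component(s)\n",
              length(x$markers), x$ncomp))
  cat("explained outcome SS per component:",
      paste(signif(x$SS, 4), collapse = ", "), "\n")
  invisible(x)
}

# Latent scores for new rows.
pls_scores <- function(fit, X) {
  X <- assert_numeric_matrix(X)
  if (!is.null(colnames(X)) && all(fit$markers %in% colnames(X))) {
    X <- X[, fit$markers, drop = FALSE]
  }
  if (ncol(X) != length(fit$markers)) {
    stop("newdata does not match the fitted predictors", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, fit$center, `-`), 2, fit$scale, `/`)
  Xs %*% fit$R
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- assert_numeric_matrix(newdata)
  if (!is.null(colnames(X)) && all(object$markers %in% colnames(X))) {
    X <- X[, object$markers, drop = FALSE]
  }
  if (ncol(X) != length(object$markers)) {
    stop("newdata does not match the fitted predictors", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, object$center, `-`), 2, object$scale, `/`)
  drop(object$y_center + Xs %*% object$B)
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}}
#' where \eqn{SS_a} is the outcome sum of squares explained by component a.
#' The normalization makes the mean of the squared VIPs equal 1, so markers
#' with VIP > 1 are more informative than average.
#'
#' @param fit A \code{"pls_fit"} object.
#' @return Named vector of VIP scores (all >= 0).
#' @export
vip_scores <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  if (sum(fit$SS) <= 1e-12) {
    stop("degenerate PLS fit: no outcome variance explained", call. = FALSE)
  }
  # W columns already have unit norm from NIPALS
  vip <- sqrt(length(fit$markers) * drop(fit$W^2 %*% fit$SS) / sum(fit$SS))
  names(vip) <- fit$markers
  vip
}

#' Choose the number of PLS components by grouped cross-validation
#'
#' Repeated visits of the same patient are correlated, so folds partition
#' patients (groups), never single pairs. The A with the smallest grouped
#' CV root-mean-squared error is selected; ties go to the smallest A.
#'
#' @param X,y Predictors and outcome as in [fit_pls()].
#' @param groups Grouping labels (patient ids); default one group per row.
#' @param a_max Largest number of components tried (default 5, capped at
#'   min(n-1, p)).
#' @param folds Number of folds (default 5, capped at the number of groups).
#' @param seed Seed for the fold assignment.
#' @return The selected number of components (integer).
#' @export
choose_ncomp <- function(X, y, groups = NULL, a_max = 5, folds = 5, seed = 1) {
  X <- assert_numeric_matrix(X)
  n <- nrow(X)
  groups <- as.character(groups %||% seq_len(n))
  ug <- sort(unique(groups))
  folds <- min(folds, length(ug))
  if (folds < 2) stop("need at least 2 groups for cross-validation", call. = FALSE)
  fold_of <- with_local_seed(seed, sample(rep_len(seq_len(folds), length(ug))))
  names(fold_of) <- ug
  a_max <- min(a_max, ncol(X), n - 1)
  press <- rep(0, a_max)
  for (k in seq_len(folds)) {
    test <- fold_of[groups] == k
    if (!any(test) || sum(!test) < 3) next
    for (a in seq_len(a_max)) {
      fit <- tryCatch(suppressWarnings(fit_pls(X[!test, , drop = FALSE], y[!test], a)),
                      error = function(e) NULL)
      press[a] <- press[a] + if (is.null(fit)) Inf else {
        sum((y[test] - predict(fit, X[test, , drop = FALSE]))^2)
      }
    }
  }
  which.min(press)  # first minimum = smallest A on ties
}

#' Rank candidate markers by PLS importance
#'
#' Fits a PLS model and orders the markers by VIP (descending), breaking
#' ties by absolute Pearson correlation with the outcome and then by name.
#' With a constant outcome all markers are equally (un)informative: every
#' score is 1 and the order is alphabetical.
#'
#' @param X,y Predictors and outcome.
#' @param ncomp Number of components; if \code{NULL} (default), chosen by
#'   [choose_ncomp()].
#' @param groups Patient ids for grouped CV when \code{ncomp} is selected.
#' @param a_max,folds,seed Passed to [choose_ncomp()].
#' @return A panel data frame of class \code{"biomarker_panel"}: columns
#'   \code{rank}, \code{marker}, \code{score}, \code{source}.
#' @export
rank_variables <- function(X, y, ncomp = NULL, groups = NULL, a_max = 5,
                           folds = 5, seed = 1) {
  X <- assert_numeric_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) == 1L || sd(y) == 0) {
    # constant outcome (or single marker): all VIPs are 1 by normalization
    ord <- order(colnames(X))
    return(new_panel(colnames(X)[ord], rep(1, ncol(X)), NA_character_))
  }
  A <- ncomp %||% choose_ncomp(X, y, groups, a_max, folds, seed)
  fit <- fit_pls(X, y, A)
  vip <- vip_scores(fit)
  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[is.na(r)] <- 0
  ord <- order(-vip, -abs(r), colnames(X), method = "radix")
  new_panel(colnames(X)[ord], as.numeric(vip[ord]), NA_character_,
            provenance = sprintf("PLS VIP ranking, %d component(s)", fit$ncomp))
}

new_panel <- function(markers, scores, source, provenance = NULL) {
  structure(data.frame(rank = seq_along(markers), marker = markers,
                       score = scores,
                       source = rep_len(source, length(markers)),
                       stringsAsFactors = FALSE),
            provenance = provenance,
            class = c("biomarker_panel", "data.frame"))
}

#' Merge expert and full-set rankings into a consensus panel
#'
#' Takes the top \code{k_full} markers of the full-set ranking and the top
#' \code{k_expert} of the expert ranking, forms their union, re-fits PLS on
#' the union, re-ranks by VIP and returns the top \code{m} markers. Each
#' surviving marker is tagged with the set it entered through
#' (\code{"expert"} if it appears in the expert ranking, else
#' \code{"extended"}).
#'
#' @param rank_full Ranking of the full candidate set ([rank_variables()]).
#' @param rank_expert Ranking of the expert subset.
#' @param X,y Data over (at least) the union of the two rankings.
#' @param k_full,k_expert How many top markers each ranking contributes
#'   (\code{NULL} = all; defaults 10 and all).
#' @param m Final panel size (default 9).
#' @param ... Passed to [rank_variables()] for the re-ranking fit.
#' @return A \code{"biomarker_panel"} of \code{m} markers.
#' @export
merge_and_rerank <- function(rank_full, rank_expert, X, y, k_full = 10,
                             k_expert = NULL, m = 9, ...) {
  stopifnot(nrow(rank_full) > 0, nrow(rank_expert) > 0, m >= 1)
  k_expert <- k_expert %||% nrow(rank_expert)
  pool <- unique(c(head(rank_full$marker, k_full),
                   head(rank_expert$marker, k_expert)))
  if (m > length(pool)) {
    stop(sprintf("m = %d exceeds the merged pool size %d", m, length(pool)),
         call. = FALSE)
  }
  X <- assert_numeric_matrix(X)
  reranked <- rank_variables(X[, pool, drop = FALSE], y, ...)
  out <- head(reranked, m)
  out$rank <- seq_len(nrow(out))
  out$source <- ifelse(out$marker %in% rank_expert$marker, "expert", "extended")
  attr(out, "provenance") <- sprintf(
    "consensus of top-%d full-set and top-%d expert markers, re-ranked by PLS VIP",
    k_full, k_expert)
  class(out) <- c("biomarker_panel", "data.frame")
  out
}
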