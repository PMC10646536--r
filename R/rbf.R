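# Normalized Gaussian radial-basis-function regression. The normalized
# basis h_i(z) = phi_i(z) / sum_j phi_j(z) forms a partition of unity, so
# predictions are convex combinations of the output weights: the network
# reproduces constants exactly, is bounded by [min w, max w], and tends to
# the nearest center's weight far from the data — well-behaved properties
# for extrapolation on small clinical samples.

#' Fit a normalized radial basis function network
#'
#' Centers are placed by seeded k-means on the inputs (with
#' \code{k_centers = n}, the training points themselves are used, giving an
#' interpolator as the ridge penalty and width shrink). A shared width
#' \code{sigma = width_scale * median pairwise center distance} is used;
#' output weights solve the ridge least-squares problem
#' \code{min ||y - H w||^2 + lambda ||w||^2} on the normalized basis matrix
#' H. The fit is invariant to the row order of the inputs.
#'
#' @param Z Numeric matrix of inputs (n x d), e.g. PLS latent scores.
#' @param y Outcome vector of length n.
#' @param k_centers Number of centers (2 <= ... <= n allowed; 1 gives a
#'   constant model).
#' @param width_scale Multiplier on the median pairwise center distance
#'   (default 1).
#' @param lambda Ridge penalty on the output weights (default 1e-3).
#' @param seed Seed for the k-means initialization.
#' @return Object of class \code{"rbf_net"}: \code{centers}, \code{sigma},
#'   \code{lambda}, \code{weights}.
#' @export
fit_normalized_rbf <- function(Z, y, k_centers, width_scale = 1,
                               lambda = 1e-3, seed = 1) {
  Z <- assert_numeric_matrix(Z)
  y <- as.numeric(y)
  n <- nrow(Z)
  if (length(y) != n) stop("length(y) must equal nrow(Z)", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (k_centers < 1 || k_centers > n) {
    stop("k_centers must lie in [1, n]", call. = FALSE)
  }
  ord <- canonical_row_order(Z)
  Zo <- Z[ord, , drop = FALSE]
  yo <- y[ord]

  n_distinct <- nrow(unique(Zo))
  if (k_centers > 1 && n_distinct == 1) {
    stop("all inputs are identical; cannot place multiple centers", call. = FALSE)
  }
  k <- min(k_centers, n_distinct)
  centers <- if (k == n) {
    Zo
  } else if (k == 1) {
    matrix(colMeans(Zo), 1)
  } else {
    with_local_seed(seed, {
      kmeans(Zo, centers = k, nstart = 5, iter.max = 100)$centers
    })
  }
  centers <- unname(as.matrix(centers))

  sigma <- if (nrow(centers) == 1) {
    1  # a single normalized basis is identically 1; the width is irrelevant
  } else {
    width_scale * median(dist(centers))
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate center configuration: zero median pairwise distance",
         call. = FALSE)
  }

  H <- normalized_basis(Zo, centers, sigma)
  sv <- svd(H)
  d <- sv$d
  shrink <- ifelse(d > max(d) * 1e-12, d / (d^2 + lambda), 0)
  w <- drop(sv$v %*% (shrink * crossprod(sv$u, yo)))

  structure(list(centers = centers, sigma = sigma, lambda = lambda,
                 weights = w, d = ncol(centers)),
            class = "rbf_net")
}

# Normalized Gaussian basis matrix, computed in log space so the partition
# of unity survives far from the centers (no 0/0 underflow).
normalized_basis <- function(Z, centers, sigma) {
  d2 <- outer(rowSums(Z^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(Z)), rowSums(centers^2)) - 2 * Z %*% t(centers)
  d2[d2 < 0] <- 0
  logphi <- -d2 / (2 * sigma^2)
  m <- apply(logphi, 1, max)
  e <- exp(logphi - m)
  e / rowSums(e)
}

#' Predict from a normalized RBF network
#'
#' Returns \code{sum_i w_i h_i(z)} for each input row. Because the h_i form
#' a partition of unity, every prediction lies in
#' \[min(w), max(w)\]; far from all centers the prediction tends to the
#' weight of the nearest center.
#'
#' @param net An \code{"rbf_net"} object.
#' @param z Numeric matrix (rows = inputs) or a single numeric vector.
#' @return Numeric vector of predictions.
#' @export
rbf_predict <- function(net, z) {
  stopifnot(inherits(net, "rbf_net"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  z <- assert_numeric_matrix(z, "z")
  if (ncol(z) != net$d) {
    stop(sprintf("input has %d columns but the network expects %d",
                 ncol(z), net$d), call. = FALSE)
  }
  drop(normalized_basis(z, net$centers, net$sigma) %*% net$weights)
}

#' @export
print.rbf_net <- function(x, ...) {
  cat(sprintf("Normalized RBF network: %d centers in %d dims, sigma = %.4g, lambda = %.3g\n",
              nrow(x$centers), x$d, x$sigma, x$lambda))
  invisible(x)
}
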