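#' Gaussian (RBF) kernel between two feature vectors
#'
#' Evaluates \eqn{k(x, y) = \exp(-\gamma \lVert x - y \rVert^2)}. The kernel
#' maps every pattern onto the unit sphere of the implicit feature space
#' (\eqn{k(x, x) = 1}), which is what makes the hypersphere and hyperplane
#' views of the one-class boundary equivalent.
#'
#' The canonical width parameter throughout the package is `gamma`; the
#' alternative "sigma" spelling common in neuroimaging toolboxes is related
#' by the documented convention \eqn{\gamma = 1 / (2\sigma^2)} (see
#' [sigma_to_gamma()]).
#'
#' @param x,y Numeric vectors of equal length (beta units).
#' @param gamma Positive kernel width parameter.
#' @return A single number in `(0, 1]`; exactly 1 iff `x == y`.
#' @examples
#' rbf_kernel(c(0, 0), c(0, 2), gamma = 0.5) # exp(-2)
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) {
    stop_shape("`x` and `y` must have the same length.")
  }
  assert_scalar_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  d <- x - y
  exp(-gamma * sum(d * d))
}

#' RBF kernel matrix between two sets of patterns
#'
#' Entry `(i, j)` is `rbf_kernel(A[i, ], B[j, ], gamma)`. Squared distances
#' are computed via the expansion
#' \eqn{\lVert x\rVert^2 + \lVert y\rVert^2 - 2 x\cdot y}, clipped at zero,
#' which is stable at the very high feature dimensions of whole-brain voxel
#' patterns.
#'
#' @param A,B Numeric matrices (rows = patterns) with equal column counts.
#'   `B` defaults to `A`, giving the symmetric unit-diagonal training kernel.
#' @inheritParams rbf_kernel
#' @return An `nrow(A)` by `nrow(B)` matrix with entries in `(0, 1]`.
#' @export
kernel_matrix <- function(A, B = A, gamma) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop_shape(sprintf("feature dimension mismatch: %d vs %d columns.",
                       ncol(A), ncol(B)))
  }
  assert_scalar_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  sa <- rowSums(A * A)
  sb <- rowSums(B * B)
  d2 <- outer(sa, sb, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  if (identical(dim(A), dim(B)) && isTRUE(all.equal(A, B, tolerance = 0))) {
    K <- (K + t(K)) / 2
    diag(K) <- 1
  }
  K
}

#' Convert between the sigma and gamma spellings of the RBF width
#'
#' The package's convention is \eqn{k(x,y) = \exp(-\gamma\lVert x-y\rVert^2)}
#' with \eqn{\gamma = 1/(2\sigma^2)}. Both spellings appear in the
#' literature and in toolbox interfaces; all internal math uses gamma.
#'
#' @param sigma,gamma Positive reals.
#' @return The converted width parameter.
#' @export
sigma_to_gamma <- function(sigma) {
  assert_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  1 / (2 * sigma^2)
}

#' @rdname sigma_to_gamma
#' @export
gamma_to_sigma <- function(gamma) {
  assert_scalar_number(gamma, "gamma", lower = 0, strict_lower = TRUE)
  1 / sqrt(2 * gamma)
}
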