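# Independent oracles used across the suite. Each one deliberately avoids
# the package's own code paths.

# Generic convex-QP solve of the one-class dual via kernlab's interior-point
# solver: min 1/2 a'Ka  s.t.  sum(a) = 1, 0 <= a_i <= 1/(nu n).
qp_oracle <- function(K, nu, sigf = 9) {
  n <- nrow(K)
  C <- 1 / (nu * n)
  sol <- kernlab::ipop(c = rep(0, n), H = K, A = matrix(1, 1, n), b = 1,
                       l = rep(0, n), u = rep(C, n), r = 0,
                       sigf = sigf, maxiter = 400)
  alpha <- kernlab::primal(sol)
  list(alpha = alpha, objective = 0.5 * drop(t(alpha) %*% K %*% alpha))
}

# Entry-wise RBF kernel by a naive double loop.
naive_kernel <- function(A, B, gamma) {
  K <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      K[i, j] <- exp(-gamma * sum((A[i, ] - B[j, ])^2))
    }
  }
  K
}

# Textbook Pearson correlation with the two-sided t-transform p-value.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Brute-force pre-image objective minimiser for 2-D instances: dense grid
# followed by derivative-free polish.
preimage_oracle_2d <- function(model) {
  X <- as.matrix(model$training_features)
  sv <- model$support_indices
  Xs <- X[sv, , drop = FALSE]
  as <- model$alphas[sv]
  gamma <- model$gamma
  aKa <- 2 * model$objective_value
  obj <- function(z) {
    kz <- exp(-gamma * colSums((t(Xs) - z)^2))
    1 - 2 * sum(as * kz) + aKa
  }
  lo <- apply(Xs, 2, min) - 1
  hi <- apply(Xs, 2, max) + 1
  gx <- seq(lo[1], hi[1], length.out = 60)
  gy <- seq(lo[2], hi[2], length.out = 60)
  vals <- outer(gx, gy, Vectorize(function(a, b) obj(c(a, b))))
  ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  start <- c(gx[ix[1]], gy[ix[2]])
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(z = fit$par, objective = fit$value)
}

# Small cohorts used by several files.
tiny_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_spec(n_controls = 6, n_patients = 6,
                              grid_shape = c(6, 6, 6), n_regions = 5,
                              seed = seed, ...))
}

control_ids <- function(cohort) {
  cohort$table$subject_id[cohort$table$group == "control"]
}
patient_ids <- function(cohort) {
  cohort$table$subject_id[cohort$table$group == "patient"]
}

subset_features <- function(features, ids) {
  ocboundary:::features_subset(features, ids)
}
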