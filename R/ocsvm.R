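#' Fit a nu-one-class SVM with RBF kernel
#'
#' Solves the one-class dual
#' \deqn{\min_\alpha \tfrac12 \alpha^\top K \alpha \quad
#'       \text{s.t. } 0 \le \alpha_i \le \tfrac{1}{\nu n},\;
#'       \sum_i \alpha_i = 1,}
#' where `K` is the RBF kernel matrix of the training patterns, by
#' sequential minimal optimisation with maximal-violating-pair selection
#' (compiled). The decision function is
#' \eqn{f(x) = \sum_i \alpha_i k(x_i, x) - \rho}: positive inside the
#' learned boundary, negative for outliers. The boundary offset \eqn{\rho}
#' is the mean kernel expansion over margin support vectors
#' (`tol_alpha < alpha_i < 1/(nu n) - tol_alpha`); if no strict-margin
#' vector exists it is the midpoint of the KKT-feasible interval.
#'
#' `nu` upper-bounds the fraction of training outliers and lower-bounds the
#' fraction of support vectors (the nu-property); see
#' [nu_property_report()].
#'
#' @param features Numeric matrix (subjects x features) or `ocb_features`.
#' @param nu Outlier-ratio parameter in `(0, 1]`.
#' @param gamma Positive RBF width.
#' @param tol KKT-violation stopping tolerance of the solver.
#' @param max_iter Maximum number of pairwise dual updates.
#' @param tol_alpha Threshold on `alpha` below which a coefficient counts
#'   as zero when identifying support vectors.
#' @return An object of class `ocsvm_model` with elements `alphas`, `rho`,
#'   `gamma`, `nu`, `support_indices`, `margin_indices`,
#'   `training_features`, `objective_value` and solver diagnostics.
#' @examples
#' x <- matrix(rnorm(20), 10, 2)
#' m <- fit_ocsvm(x, nu = 0.5, gamma = 0.5)
#' tidy(m)
#' @export
fit_ocsvm <- function(features, nu, gamma, tol = 1e-6, max_iter = 10000L,
                      tol_alpha = 1e-8) {
  X <- as.matrix(features)
  if (nrow(X) < 2) {
    abort("need at least 2 training subjects.",
          class = "ocb_insufficient_data_error")
  }
  if (any(!is.finite(X))) {
    abort("training features contain non-finite values.",
          class = "ocb_validation_error")
  }
  assert_scalar_number(nu, "nu", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar_number(gamma, "gamma", lower = 0, strict_lower = TRUE)

  n <- nrow(X)
  K <- kernel_matrix(X, gamma = gamma)
  sol <- .smo_ocsvm(K, nu, tol, as.integer(max_iter))
  if (!sol$converged) {
    warn(sprintf("solver stopped at max_iter = %d with KKT violation %.2e.",
                 max_iter, sol$kkt_violation))
  }
  alpha <- sol$alpha
  g <- sol$grad
  C <- 1 / (nu * n)

  support <- which(alpha > tol_alpha)
  margin <- which(alpha > tol_alpha & alpha < C - tol_alpha)
  rho <- if (length(margin) > 0) {
    mean(g[margin])
  } else {
    at_upper <- which(alpha >= C - tol_alpha)
    at_lower <- which(alpha <= tol_alpha)
    lo <- if (length(at_upper) > 0) max(g[at_upper]) else -Inf
    hi <- if (length(at_lower) > 0) min(g[at_lower]) else Inf
    if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
    else if (is.finite(lo)) lo else hi
  }

  structure(
    list(alphas = alpha, rho = rho, gamma = gamma, nu = nu,
         support_indices = support, margin_indices = margin,
         training_features = features,
         subject_ids = rownames(X) %||% paste0("row", seq_len(n)),
         objective_value = sol$objective,
         iterations = sol$iterations,
         kkt_violation = sol$kkt_violation,
         converged = sol$converged),
    class = "ocsvm_model"
  )
}

#' @export
print.ocsvm_model <- function(x, ...) {
  cat(sprintf(
    "One-class SVM (RBF): n = %d, nu = %g, gamma = %g\n  rho = %.6g, support vectors = %d (margin: %d), objective = %.6g\n",
    length(x$alphas), x$nu, x$gamma, x$rho,
    length(x$support_indices), length(x$margin_indices), x$objective_value))
  invisible(x)
}

#' @describeIn fit_ocsvm One row per training subject: dual coefficient,
#'   support/margin status, training decision value.
#' @param x,object An `ocsvm_model`.
#' @param ... Unused.
#' @method tidy ocsvm_model
#' @export
tidy.ocsvm_model <- function(x, ...) {
  dv <- decision_values(x, x$training_features)
  tibble::tibble(
    subject_id = x$subject_ids,
    alpha = x$alphas,
    support = seq_along(x$alphas) %in% x$support_indices,
    margin = seq_along(x$alphas) %in% x$margin_indices,
    decision_value = dv$decision_value,
    outlier = dv$outlier
  )
}

#' @describeIn fit_ocsvm One-row model summary (nu, gamma, rho, counts,
#'   objective, convergence).
#' @method glance ocsvm_model
#' @export
glance.ocsvm_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$alphas), nu = x$nu, gamma = x$gamma, rho = x$rho,
    n_support = length(x$support_indices),
    n_margin = length(x$margin_indices),
    objective = x$objective_value,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Decision values and outlier flags for test patterns
#'
#' Evaluates \eqn{f(x) = \sum_i \alpha_i k(x_i, x) - \rho} for each test
#' row. The decision threshold is fixed at zero: a subject with a negative
#' decision value lies outside the normality boundary and is flagged an
#' outlier. The magnitude of `f` serves as a signed distance surrogate and
#' degree-of-abnormality measure.
#'
#' @param model An `ocsvm_model`.
#' @param test Numeric matrix of test patterns (rows), feature dimension
#'   matching the training features.
#' @return A tibble (`decision_report`) with columns `subject_id`,
#'   `decision_value`, `outlier`.
#' @export
decision_values <- function(model, test) {
  stopifnot(inherits(model, "ocsvm_model"))
  Xtr <- as.matrix(model$training_features)
  Xte <- if (is.null(dim(test))) matrix(test, nrow = 1) else as.matrix(test)
  if (ncol(Xte) != ncol(Xtr)) {
    stop_shape(sprintf("test feature dimension %d != training dimension %d.",
                       ncol(Xte), ncol(Xtr)))
  }
  Kt <- kernel_matrix(Xte, Xtr, gamma = model$gamma)
  f <- drop(Kt %*% model$alphas) - model$rho
  out <- tibble::tibble(
    subject_id = rownames(Xte) %||% paste0("test", seq_len(nrow(Xte))),
    decision_value = f,
    outlier = f < 0
  )
  class(out) <- c("decision_report", class(out))
  out
}

#' Empirical nu-property fractions of a fitted model
#'
#' Returns the fraction of training subjects lying outside the boundary and
#' the fraction retained as support vectors. For an exact solution the
#' nu-property guarantees `outlier_fraction <= nu <= sv_fraction`
#' (up to 1/n). Margin support vectors sit numerically at decision value
#' zero (within the solver's KKT tolerance), so training points count as
#' outliers only when their decision value falls below `-tol_decision`;
#' the strict below-zero rule of [decision_values()] is unchanged for test
#' subjects.
#'
#' @param model An `ocsvm_model`.
#' @param report Optional training-set decision report; computed from the
#'   model's retained training features if omitted.
#' @param tol_decision Numerical slack under zero for counting a training
#'   point as outside the boundary; defaults to the solver's KKT stopping
#'   tolerance.
#' @return A tibble with columns `nu`, `outlier_fraction`, `sv_fraction`.
#' @export
nu_property_report <- function(model, report = NULL, tol_decision = 1e-6) {
  stopifnot(inherits(model, "ocsvm_model"))
  report <- report %||% decision_values(model, model$training_features)
  tibble::tibble(
    nu = model$nu,
    outlier_fraction = mean(report$decision_value < -tol_decision),
    sv_fraction = length(model$support_indices) / length(model$alphas)
  )
}

#' Serialize / restore a fitted model as JSON
#'
#' The JSON carries the dual coefficients, offset, hyperparameters, subject
#' ids and the training feature matrix, so a restored model reproduces
#' decision values exactly.
#'
#' @param model An `ocsvm_model`.
#' @param path Output (input) file path.
#' @return `write_ocsvm()` returns `path` invisibly; `read_ocsvm()` the
#'   restored model.
#' @export
write_ocsvm <- function(model, path) {
  stopifnot(inherits(model, "ocsvm_model"))
  payload <- list(
    alphas = model$alphas, rho = model$rho, gamma = model$gamma,
    nu = model$nu, subject_ids = model$subject_ids,
    objective_value = model$objective_value,
    training_features = as.matrix(model$training_features)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ocsvm
#' @export
read_ocsvm <- function(path) {
  p <- jsonlite::fromJSON(path)
  X <- as.matrix(p$training_features)
  rownames(X) <- p$subject_ids
  alpha <- as.numeric(p$alphas)
  C <- 1 / (p$nu * length(alpha))
  structure(
    list(alphas = alpha, rho = p$rho, gamma = p$gamma, nu = p$nu,
         support_indices = which(alpha > 1e-8),
         margin_indices = which(alpha > 1e-8 & alpha < C - 1e-8),
         training_features = X, subject_ids = p$subject_ids,
         objective_value = p$objective_value,
         iterations = NA_integer_, kkt_violation = NA_real_,
         converged = TRUE),
    class = "ocsvm_model"
  )
}
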