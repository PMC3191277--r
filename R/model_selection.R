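#' Hyperparameter search grid
#'
#' Defaults follow the reference protocol: `nu` from 0.1 to 0.5 in steps of
#' 0.1 and the RBF `gamma` log-spaced over 1e-7 to 1e-3 (5 points per
#' decade). The two-step search holds `nu` at `initial_nu` while choosing
#' `gamma`.
#'
#' @param nu_values Strictly increasing values in `(0, 1]`.
#' @param gamma_values Strictly increasing positive values.
#' @param initial_nu Value of `nu` used during the `gamma` step.
#' @return A `search_grid` object.
#' @export
search_grid <- function(nu_values = seq(0.1, 0.5, by = 0.1),
                        gamma_values = 10^seq(-7, -3, by = 0.2),
                        initial_nu = 0.1) {
  if (length(nu_values) == 0 || length(gamma_values) == 0) {
    abort("grids must be non-empty.", class = "ocb_config_error")
  }
  if (is.unsorted(nu_values, strictly = TRUE) ||
      is.unsorted(gamma_values, strictly = TRUE)) {
    abort("grid values must be strictly increasing.",
          class = "ocb_config_error")
  }
  if (any(nu_values <= 0 | nu_values > 1) || any(gamma_values <= 0)) {
    abort("nu values must lie in (0, 1] and gamma values must be positive.",
          class = "ocb_config_error")
  }
  assert_scalar_number(initial_nu, "initial_nu", lower = 0, upper = 1,
                       strict_lower = TRUE)
  structure(list(nu_values = as.numeric(nu_values),
                 gamma_values = as.numeric(gamma_values),
                 initial_nu = initial_nu),
            class = "search_grid")
}

squared_distances <- function(X) {
  s <- rowSums(X * X)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

# Leave-one-out accuracy over the training positives at fixed (nu, gamma),
# reusing a precomputed squared-distance matrix.
loo_accuracy_d2 <- function(d2, nu, gamma) {
  n <- nrow(d2)
  K <- exp(-gamma * d2)
  correct <- logical(n)
  for (i in seq_len(n)) {
    Ki <- K[-i, -i, drop = FALSE]
    sol <- .smo_ocsvm(Ki, nu, 1e-6, 10000L)
    rho <- rho_from_solution(sol$alpha, sol$grad, 1 / (nu * (n - 1)))
    f <- sum(K[i, -i] * sol$alpha) - rho
    correct[i] <- f >= 0
  }
  mean(correct)
}

rho_from_solution <- function(alpha, g, C, tol_alpha = 1e-8) {
  margin <- which(alpha > tol_alpha & alpha < C - tol_alpha)
  if (length(margin) > 0) return(mean(g[margin]))
  at_upper <- which(alpha >= C - tol_alpha)
  at_lower <- which(alpha <= tol_alpha)
  lo <- if (length(at_upper) > 0) max(g[at_upper]) else -Inf
  hi <- if (length(at_lower) > 0) min(g[at_lower]) else Inf
  if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
  else if (is.finite(lo)) lo else hi
}

#' Inner-loop validation accuracy at one hyperparameter setting
#'
#' Fits the one-class model on `train` and scores `validation`: the
#' accuracy is the fraction of validation positive-class subjects classified
#' as non-outliers (decision value >= 0). With a single held-out subject —
#' the leave-one-out case — the accuracy is 0 or 1.
#'
#' @param train,validation Numeric matrices of positive-class patterns;
#'   must be disjoint subject sets.
#' @param nu,gamma Hyperparameters of the candidate model.
#' @return Accuracy in `[0, 1]`.
#' @export
inner_score <- function(train, validation, nu, gamma) {
  if (is.null(dim(validation))) validation <- matrix(validation, nrow = 1)
  if (nrow(as.matrix(train)) < 2 || nrow(as.matrix(validation)) < 1) {
    abort("train and validation sets must be non-empty (train >= 2).",
          class = "ocb_validation_error")
  }
  model <- fit_ocsvm(as.matrix(train), nu = nu, gamma = gamma)
  mean(!decision_values(model, validation)$outlier)
}

#' Two-step hyperparameter search on an inner leave-one-out
#'
#' Step 1 holds `nu` at `grid$initial_nu` and picks the `gamma` maximising
#' mean inner leave-one-out accuracy; step 2 holds that `gamma` fixed and
#' picks `nu`. Accuracy ties on `gamma` are broken toward the largest
#' `gamma`: under the convention `gamma = 1/(2 sigma^2)` that is the
#' smallest kernel length-scale `sigma`, the tightest boundary among the
#' tied settings. Ties on `nu` are broken toward the smallest value (the
#' loosest boundary, sacrificing the fewest training subjects).
#'
#' @param train Numeric matrix of positive-class training patterns
#'   (>= 3 rows so an inner leave-one-out is possible).
#' @param grid A [search_grid()].
#' @param mode `"two_step"` (default) or `"joint"` (exhaustive 2-D search,
#'   same tie-breaks, provided for comparison).
#' @return A list with `gamma`, `nu`, and the per-step accuracy tables.
#' @export
two_step_search <- function(train, grid, mode = c("two_step", "joint")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "search_grid"))
  X <- as.matrix(train)
  if (nrow(X) < 3) {
    abort("need >= 3 training subjects for an inner leave-one-out.",
          class = "ocb_validation_error")
  }
  d2 <- squared_distances(X)

  if (mode == "joint") {
    acc <- outer(grid$gamma_values, grid$nu_values,
                 Vectorize(function(g, nu) loo_accuracy_d2(d2, nu, g)))
    best <- max(acc)
    hits <- which(acc == best, arr.ind = TRUE)
    # largest gamma first, then smallest nu
    hits <- hits[order(-hits[, 1], hits[, 2]), , drop = FALSE]
    gamma_star <- grid$gamma_values[hits[1, 1]]
    nu_star <- grid$nu_values[hits[1, 2]]
    return(list(gamma = gamma_star, nu = nu_star,
                joint = tibble::tibble(
                  gamma = rep(grid$gamma_values, times = length(grid$nu_values)),
                  nu = rep(grid$nu_values, each = length(grid$gamma_values)),
                  accuracy = as.vector(acc))))
  }

  acc_gamma <- vapply(grid$gamma_values,
                      function(g) loo_accuracy_d2(d2, grid$initial_nu, g),
                      numeric(1))
  gamma_star <- grid$gamma_values[max(which(acc_gamma == max(acc_gamma)))]
  acc_nu <- vapply(grid$nu_values,
                   function(nu) loo_accuracy_d2(d2, nu, gamma_star),
                   numeric(1))
  nu_star <- grid$nu_values[min(which(acc_nu == max(acc_nu)))]
  list(gamma = gamma_star, nu = nu_star,
       step1 = tibble::tibble(gamma = grid$gamma_values, accuracy = acc_gamma),
       step2 = tibble::tibble(nu = grid$nu_values, accuracy = acc_nu))
}

match_pairs <- function(table, positive_class) {
  negative_class <- setdiff(c("control", "patient"), positive_class)
  pos <- table[table$group == positive_class, , drop = FALSE]
  neg <- table[table$group == negative_class, , drop = FALSE]
  neg_by_pair <- setNames(neg$subject_id, neg$pair_id)
  matched <- neg_by_pair[pos$pair_id]
  if (any(is.na(matched))) {
    abort(sprintf("positive-class subject(s) without a matched partner: %s.",
                  paste(pos$subject_id[is.na(matched)], collapse = ", ")),
          class = "ocb_pairing_error")
  }
  tibble::tibble(positive_id = pos$subject_id,
                 negative_id = unname(matched),
                 pair_id = pos$pair_id)
}

#' Nested leave-one-out cross-validation with matched-pair testing
#'
#' The outer loop holds out one positive-class subject per fold together
#' with its pair-matched negative-class subject; the two-step search runs
#' on the remaining positives (inner leave-one-out), a model is fitted on
#' them with the chosen `(gamma, nu)`, and both held-out subjects are
#' scored. Aggregates are the percentage of held-out positives classified
#' non-outlier (the true-negative ratio when controls are the positive
#' class) and the percentage of held-out negatives classified outlier (the
#' true-positive ratio). Averaged parameters for the final model are the
#' geometric mean of the fold-wise `gamma` (log-spaced grid) and the
#' arithmetic mean of the fold-wise `nu`.
#'
#' Swapping `positive_class` to `"patient"` reruns the identical protocol
#' with the patient group as the modelled class.
#'
#' @param features An `ocb_features` matrix (or matrix with subject-id
#'   rownames) covering all subjects.
#' @param table Cohort table with columns `subject_id`, `group`, `pair_id`.
#' @param grid A [search_grid()].
#' @param positive_class `"control"` (default) or `"patient"`.
#' @param mode Search mode passed to [two_step_search()].
#' @return An object of class `nested_loo`: per-fold tibble plus aggregate
#'   ratios and averaged parameters. See [tidy.nested_loo()],
#'   [glance.nested_loo()].
#' @export
nested_loo <- function(features, table, grid = search_grid(),
                       positive_class = c("control", "patient"),
                       mode = c("two_step", "joint")) {
  positive_class <- match.arg(positive_class)
  mode <- match.arg(mode)
  pairs <- match_pairs(table, positive_class)
  if (nrow(pairs) < 4) {
    abort("need at least 4 matched pairs for a nested leave-one-out.",
          class = "ocb_validation_error")
  }
  missing_rows <- setdiff(c(pairs$positive_id, pairs$negative_id),
                          rownames(features))
  if (length(missing_rows) > 0) {
    abort(sprintf("subjects missing from the feature matrix: %s.",
                  paste(missing_rows, collapse = ", ")),
          class = "ocb_validation_error")
  }

  folds <- purrr::map(seq_len(nrow(pairs)), function(f) {
    held_pos <- pairs$positive_id[f]
    held_neg <- pairs$negative_id[f]
    train_ids <- setdiff(pairs$positive_id, held_pos)
    Xtr <- features_subset(features, train_ids)
    sel <- two_step_search(Xtr, grid, mode = mode)
    model <- fit_ocsvm(Xtr, nu = sel$nu, gamma = sel$gamma)
    rep_pos <- decision_values(model, features_subset(features, held_pos))
    rep_neg <- decision_values(model, features_subset(features, held_neg))
    tibble::tibble(
      fold = f, positive_id = held_pos, negative_id = held_neg,
      gamma = sel$gamma, nu = sel$nu,
      positive_decision = rep_pos$decision_value,
      positive_outlier = rep_pos$outlier,
      negative_decision = rep_neg$decision_value,
      negative_outlier = rep_neg$outlier,
      train_ids = list(train_ids)
    )
  }) |> dplyr::bind_rows()

  structure(
    list(folds = folds,
         positive_class = positive_class,
         grid = grid,
         positive_inlier_pct = 100 * mean(!folds$positive_outlier),
         negative_outlier_pct = 100 * mean(folds$negative_outlier),
         averaged_gamma = exp(mean(log(folds$gamma))),
         averaged_nu = mean(folds$nu)),
    class = "nested_loo"
  )
}

#' @export
print.nested_loo <- function(x, ...) {
  pos <- x$positive_class
  neg <- setdiff(c("control", "patient"), pos)
  cat(sprintf("Nested leave-one-out (%d folds, positive class: %s)\n",
              nrow(x$folds), pos))
  cat(sprintf("  %% %ss detected as non-outlier: %.1f%%\n", pos,
              x$positive_inlier_pct))
  cat(sprintf("  %% %ss detected as outlier:     %.1f%%\n", neg,
              x$negative_outlier_pct))
  cat(sprintf("  averaged parameters: gamma = %.3g, nu = %.3g\n",
              x$averaged_gamma, x$averaged_nu))
  invisible(x)
}

#' Tidy the per-fold results of a nested cross-validation
#'
#' @param x A `nested_loo` object.
#' @param ... Unused.
#' @return Tibble with one row per outer fold: held-out ids, chosen
#'   hyperparameters, decision values and outlier flags.
#' @method tidy nested_loo
#' @export
tidy.nested_loo <- function(x, ...) {
  dplyr::select(x$folds, -"train_ids")
}

#' One-row summary of a nested cross-validation
#'
#' @param x A `nested_loo` object.
#' @param ... Unused.
#' @return Tibble with fold count, aggregate ratios (percent) and averaged
#'   hyperparameters. When controls are the positive class,
#'   `true_negative_pct` is the percentage of controls detected as
#'   non-outlier and `true_positive_pct` the percentage of patients
#'   detected as outlier.
#' @method glance nested_loo
#' @export
glance.nested_loo <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$folds),
    positive_class = x$positive_class,
    true_negative_pct = x$positive_inlier_pct,
    true_positive_pct = x$negative_outlier_pct,
    averaged_gamma = x$averaged_gamma,
    averaged_nu = x$averaged_nu
  )
}

#' Final model refit on every positive-class subject
#'
#' Retrains the one-class model on all positives using the averaged
#' parameters from the nested cross-validation, so that every
#' negative-class subject is scored against the same boundary and their
#' decision values are mutually comparable (as required for severity
#' correlation and the weight maps).
#'
#' @param positives Feature rows of all positive-class subjects.
#' @param cv A `nested_loo` result computed on those positives.
#' @return An `ocsvm_model`.
#' @export
final_model <- function(positives, cv) {
  stopifnot(inherits(cv, "nested_loo"))
  fit_ocsvm(positives, nu = cv$averaged_nu, gamma = cv$averaged_gamma)
}
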