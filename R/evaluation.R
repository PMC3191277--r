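# Outer loop with hyperparameters fixed (no inner search): used for the
# fast permutation null, where the observed run's averaged parameters are
# reused for every permuted relabeling.
outer_folds_fixed <- function(features, pairs, gamma, nu) {
  pos_out <- logical(nrow(pairs))
  neg_out <- logical(nrow(pairs))
  X <- as.matrix(features)
  d2 <- squared_distances(X[match(pairs$positive_id, rownames(X)), ,
                            drop = FALSE])
  K <- exp(-gamma * d2)
  Kneg <- exp(-gamma * cross_distances(
    X[match(pairs$negative_id, rownames(X)), , drop = FALSE],
    X[match(pairs$positive_id, rownames(X)), , drop = FALSE]))
  n <- nrow(pairs)
  for (f in seq_len(n)) {
    Kf <- K[-f, -f, drop = FALSE]
    sol <- .smo_ocsvm(Kf, nu, 1e-6, 10000L)
    rho <- rho_from_solution(sol$alpha, sol$grad, 1 / (nu * (n - 1)))
    pos_out[f] <- (sum(K[f, -f] * sol$alpha) - rho) < 0
    neg_out[f] <- (sum(Kneg[f, -f] * sol$alpha) - rho) < 0
  }
  list(positive_inlier_pct = 100 * mean(!pos_out),
       negative_outlier_pct = 100 * mean(neg_out))
}

cross_distances <- function(A, B) {
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Randomly reassign group labels preserving group sizes, then re-form
# matched pairs: original pairs that still straddle the permuted groups are
# kept; leftover positives and negatives are matched at random.
permute_table <- function(table, positive_class) {
  negative_class <- setdiff(c("control", "patient"), positive_class)
  n_pos <- sum(table$group == positive_class)
  pos_ids <- sample(table$subject_id, n_pos)
  new_group <- ifelse(table$subject_id %in% pos_ids,
                      positive_class, negative_class)
  new_pair <- rep(NA_character_, nrow(table))
  kept <- split(seq_len(nrow(table)), table$pair_id)
  for (pid in names(kept)) {
    ix <- kept[[pid]]
    if (length(ix) == 2 && length(unique(new_group[ix])) == 2) {
      new_pair[ix] <- pid
    }
  }
  free_pos <- which(new_group == positive_class & is.na(new_pair))
  free_neg <- which(new_group == negative_class & is.na(new_pair))
  if (length(free_pos) > 0) {
    free_neg <- sample(free_neg, length(free_neg))
    ids <- sprintf("perm%03d", seq_along(free_pos))
    new_pair[free_pos] <- ids
    new_pair[free_neg] <- ids
  }
  tibble::tibble(subject_id = table$subject_id, group = new_group,
                 pair_id = new_pair)
}

#' Permutation significance test for the cross-validated TP/TN ratios
#'
#' Group labels are randomly reassigned (preserving group sizes)
#' `n_permutations` times and the full matched-pair outer cross-validation
#' is re-run each time. The p-value for the true-positive ratio is the
#' fraction of permutations whose TP ratio is at least the observed one
#' (ties count against the observed statistic — the conservative reading of
#' "higher than"); likewise for the true-negative ratio. By default the
#' estimator is `count / n_permutations`; `plus_one = TRUE` uses the
#' `(count + 1) / (n_permutations + 1)` variant.
#'
#' With `fast_null = TRUE` the permuted runs reuse the observed run's
#' averaged `(gamma, nu)` instead of repeating the two-step search — the
#' search dominates the cost of a full re-run.
#'
#' @inheritParams nested_loo
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed; the test is bit-reproducible given
#'   `(seed, inputs)`.
#' @param fast_null Reuse observed averaged hyperparameters per permutation.
#' @param plus_one Use the `(count + 1)/(B + 1)` p-value estimator.
#' @param observed Optionally, a precomputed `nested_loo` on the real
#'   labels (must match `features`/`table`/`grid`).
#' @return A `permutation_result` object; see [tidy.permutation_result()].
#' @export
permutation_test <- function(features, table, grid = search_grid(),
                             n_permutations = 1000L, seed = 1L,
                             positive_class = c("control", "patient"),
                             fast_null = FALSE, plus_one = FALSE,
                             mode = c("two_step", "joint"),
                             observed = NULL) {
  positive_class <- match.arg(positive_class)
  mode <- match.arg(mode)
  assert_scalar_number(n_permutations, "n_permutations", lower = 1)
  n_pos <- sum(table$group == positive_class)
  if (n_pos * 2 != nrow(table)) {
    abort("permutation test requires equal group sizes (matched pairing is undefined otherwise).",
          class = "ocb_config_error")
  }
  observed <- observed %||% nested_loo(features, table, grid,
                                       positive_class = positive_class,
                                       mode = mode)
  obs_tp <- observed$negative_outlier_pct
  obs_tn <- observed$positive_inlier_pct

  draws <- with_seed(derive_seed(seed, "permutation"), {
    purrr::map(seq_len(n_permutations), function(b) {
      ptab <- permute_table(table, positive_class)
      res <- if (fast_null) {
        outer_folds_fixed(features, match_pairs(ptab, positive_class),
                          gamma = observed$averaged_gamma,
                          nu = observed$averaged_nu)
      } else {
        cv <- nested_loo(features, ptab, grid,
                         positive_class = positive_class, mode = mode)
        list(positive_inlier_pct = cv$positive_inlier_pct,
             negative_outlier_pct = cv$negative_outlier_pct)
      }
      tibble::tibble(permutation = b,
                     tp_pct = res$negative_outlier_pct,
                     tn_pct = res$positive_inlier_pct)
    }) |> dplyr::bind_rows()
  })

  count_tp <- sum(draws$tp_pct >= obs_tp)
  count_tn <- sum(draws$tn_pct >= obs_tn)
  denom <- if (plus_one) n_permutations + 1 else n_permutations
  adj <- if (plus_one) 1L else 0L

  structure(
    list(observed_tp = obs_tp, observed_tn = obs_tn,
         n_permutations = as.integer(n_permutations),
         count_tp_ge = count_tp, count_tn_ge = count_tn,
         p_tp = (count_tp + adj) / denom,
         p_tn = (count_tn + adj) / denom,
         seed = as.integer(seed), fast_null = fast_null,
         plus_one = plus_one, draws = draws,
         observed = observed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%d permutations%s)\n  TP = %.1f%% (p = %.4g)\n  TN = %.1f%% (p = %.4g)\n",
    x$n_permutations, if (x$fast_null) ", fast null" else "",
    x$observed_tp, x$p_tp, x$observed_tn, x$p_tn))
  invisible(x)
}

#' Tidy the permuted-label draws of a permutation test
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble with one row per permutation (`tp_pct`, `tn_pct`).
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) x$draws

#' One-row summary of a permutation test
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble with observed ratios, exceedance counts and p-values.
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    observed_tp = x$observed_tp, observed_tn = x$observed_tn,
    n_permutations = x$n_permutations,
    count_tp_ge = x$count_tp_ge, count_tn_ge = x$count_tn_ge,
    p_tp = x$p_tp, p_tn = x$p_tn, fast_null = x$fast_null
  )
}

#' Pearson correlation between decision values and clinical severity
#'
#' Correlates the signed decision values (distance surrogate to the
#' normality boundary) with the severity score, over all scored patients or
#' a response-defined subset. A negative correlation means more severe
#' subjects lie further outside the boundary. The p-value is the two-sided
#' t transform with `n - 2` degrees of freedom.
#'
#' @param report A `decision_report` (e.g. from scoring all patients
#'   against the final model).
#' @param table Cohort table with `subject_id`, `severity`, `response`.
#' @param subset `"all"`, `"responders"` or `"non-responders"`.
#' @return Tibble with columns `subset`, `n`, `r`, `p_value`.
#' @export
severity_correlation <- function(report, table,
                                 subset = c("all", "responders",
                                            "non-responders")) {
  subset <- match.arg(subset)
  joined <- dplyr::inner_join(report, table, by = "subject_id")
  if (nrow(joined) < nrow(report)) {
    abort("some scored subjects are missing from the cohort table.",
          class = "ocb_validation_error")
  }
  if (subset != "all") {
    keep <- if (subset == "responders") "responder" else "non-responder"
    joined <- joined[joined$response == keep, , drop = FALSE]
  }
  if (nrow(joined) < 3) {
    abort(sprintf("need >= 3 subjects for a correlation (have %d).",
                  nrow(joined)),
          class = "ocb_validation_error")
  }
  if (sd(joined$decision_value) == 0 || sd(joined$severity) == 0) {
    abort("zero variance in decision values or severity: correlation undefined.",
          class = "ocb_degenerate_error")
  }
  ct <- stats::cor.test(joined$decision_value, joined$severity,
                        method = "pearson", alternative = "two.sided")
  tibble::tibble(subset = subset, n = nrow(joined),
                 r = unname(ct$estimate), p_value = ct$p.value)
}

#' Treatment response tabulated by outlier status
#'
#' Splits the scored patients by their outlier flag and reports, within
#' each group, the number and percentage of treatment responders. An empty
#' cell (e.g. no non-outliers) yields an `NA` percentage.
#'
#' @param report A `decision_report` over patients.
#' @param table Cohort table with `subject_id` and `response`.
#' @return Tibble with columns `outlier`, `n`, `n_responders`,
#'   `pct_responders`.
#' @export
subgroup_table <- function(report, table) {
  joined <- dplyr::inner_join(report, table, by = "subject_id")
  bad <- joined$response %in% "not-applicable" | is.na(joined$response)
  if (any(bad)) {
    abort(sprintf("subject(s) without a response label: %s.",
                  paste(joined$subject_id[bad], collapse = ", ")),
          class = "ocb_validation_error")
  }
  tibble::tibble(outlier = c(TRUE, FALSE)) |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(.data$outlier) |>
        dplyr::summarise(n = dplyr::n(),
                         n_responders = sum(.data$response == "responder")),
      by = "outlier") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_responders = dplyr::coalesce(.data$n_responders, 0L),
      pct_responders = ifelse(.data$n > 0, 100 * .data$n_responders / .data$n,
                              NA_real_))
}
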