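#' Plot a decision report
#'
#' Decision values per subject with the zero boundary; subjects below zero
#' are outliers with respect to the trained class.
#'
#' @param object A `decision_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decision_report
#' @export
autoplot.decision_report <- function(object, ...) {
  df <- dplyr::mutate(object,
                      subject_id = factor(.data$subject_id,
                                          levels = .data$subject_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject_id,
                                   y = .data$decision_value,
                                   fill = .data$outlier)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "decision value f(x)",
                  fill = "outlier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot per-fold nested cross-validation outcomes
#'
#' Held-out decision values per fold for the positive-class subject and its
#' matched negative-class partner.
#'
#' @param object A `nested_loo` result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nested_loo
#' @export
autoplot.nested_loo <- function(object, ...) {
  pos <- object$positive_class
  neg <- setdiff(c("control", "patient"), pos)
  df <- tidy(object) |>
    tidyr::pivot_longer(c("positive_decision", "negative_decision"),
                        names_to = "role", values_to = "decision_value") |>
    dplyr::mutate(group = ifelse(.data$role == "positive_decision", pos, neg))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$decision_value,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "outer fold", y = "held-out decision value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null distribution
#'
#' Histogram of the permuted-label true-positive ratios with the observed
#' ratio marked.
#'
#' @param object A `permutation_result`.
#' @param statistic `"tp"` or `"tn"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, statistic = c("tp", "tn"),
                                        ...) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "tp") "tp_pct" else "tn_pct"
  obs <- if (statistic == "tp") object$observed_tp else object$observed_tn
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(binwidth = 100 / max(1, object$n_permutations^0.5),
                            fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs, colour = "red") +
    ggplot2::labs(x = sprintf("permuted %s ratio (%%)", toupper(statistic)),
                  y = "count") +
    ggplot2::theme_minimal()
}

#' Scatter plot of decision values against severity
#'
#' @param report A `decision_report` over patients.
#' @param table Cohort table with `severity` and `response`.
#' @return A ggplot.
#' @export
plot_severity <- function(report, table) {
  df <- dplyr::inner_join(report, table, by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$severity,
                                   y = .data$decision_value,
                                   colour = .data$response)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "severity (HRSD points)", y = "decision value f(x)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of each condition map
#'
#' @param object A `weight_map` (weight or t map).
#' @param slice Axial (third-axis) slice index; default the middle slice.
#' @param ... Unused.
#' @return A ggplot with one facet per condition.
#' @method autoplot weight_map
#' @export
autoplot.weight_map <- function(object, slice = NULL, ...) {
  dims <- dim(object$values[[1]])
  slice <- slice %||% ceiling(dims[3] / 2)
  df <- purrr::imap(object$values, function(v, cond) {
    sl <- v[, , slice]
    tibble::tibble(condition = cond,
                   x = rep(seq_len(dims[1]), times = dims[2]),
                   y = rep(seq_len(dims[2]), each = dims[1]),
                   value = as.vector(sl))
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = names(object$values)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s map (axial slice %d)",
                                  object$statistic, slice),
                  fill = object$statistic) +
    ggplot2::theme_minimal()
}
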