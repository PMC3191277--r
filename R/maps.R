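preimage_objective <- function(z, X, alpha, gamma, aKa) {
  kz <- exp(-gamma * colSums((t(X) - z)^2))
  1 - 2 * sum(alpha * kz) + aKa
}

#' RBF pre-image approximation of the one-class model weight
#'
#' The model weight \eqn{w = \sum_i \alpha_i \Phi(x_i)} lives in the
#' implicit kernel feature space; its approximate pre-image is the
#' input-space point `z` minimising
#' \eqn{\lVert \Phi(z) - \sum_i \alpha_i \Phi(x_i) \rVert^2}, found by the
#' fixed-point iteration
#' \deqn{z \leftarrow \frac{\sum_i \alpha_i e^{-\gamma\lVert z - x_i\rVert^2} x_i}
#'                        {\sum_i \alpha_i e^{-\gamma\lVert z - x_i\rVert^2}}.}
#' Each step is accepted only if it does not increase the objective
#' (otherwise the step is damped by halving); iteration stops when
#' \eqn{\lVert z_{t+1} - z_t \rVert < tol\,(1 + \lVert z_t \rVert)} or at
#' `max_iter`. Because the fixed point is local, the iteration is restarted
#' from the alpha-weighted support-vector mean plus `n_restarts` seeded
#' random perturbations, keeping the best objective. The returned point is
#' the centre of the single Gaussian best capturing the support-vector
#' expansion.
#'
#' @param model An `ocsvm_model`.
#' @param init Optional initial point; default is the alpha-weighted mean
#'   of the support vectors.
#' @param max_iter Maximum fixed-point iterations per start.
#' @param tol Relative convergence tolerance on the iterate.
#' @param n_restarts Number of additional seeded random starts.
#' @param seed Seed for the random restarts.
#' @return A list with `z` (the pre-image vector), and `diagnostics`
#'   (per-start tibble plus `objective`, `grad_norm`, `iterations`,
#'   `converged` and the accepted-step `objective_trace` for the best
#'   start).
#' @export
preimage <- function(model, init = NULL, max_iter = 500L, tol = 1e-10,
                     n_restarts = 5L, seed = 1L) {
  stopifnot(inherits(model, "ocsvm_model"))
  X <- as.matrix(model$training_features)
  sv <- model$support_indices
  alpha <- model$alphas
  gamma <- model$gamma
  Xs <- X[sv, , drop = FALSE]
  as <- alpha[sv]
  aKa <- 2 * model$objective_value
  center <- drop(crossprod(Xs, as)) / sum(as)

  if (!is.null(init) && any(!is.finite(init))) {
    abort("`init` must be finite.", class = "ocb_validation_error")
  }

  run_from <- function(z0) {
    z <- z0
    obj <- preimage_objective(z, Xs, as, gamma, aKa)
    obj_trace <- obj
    iters <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- as * exp(-gamma * colSums((t(Xs) - z)^2))
      if (sum(w) < 1e-300) {
        # all kernel weights underflowed: restart from the weighted SV mean
        z <- center
        obj <- preimage_objective(z, Xs, as, gamma, aKa)
        next
      }
      z_new <- drop(crossprod(Xs, w)) / sum(w)
      obj_new <- preimage_objective(z_new, Xs, as, gamma, aKa)
      t_damp <- 1
      while (obj_new > obj && t_damp > 1e-8) {
        t_damp <- t_damp / 2
        z_try <- z + t_damp * (z_new - z)
        obj_new <- preimage_objective(z_try, Xs, as, gamma, aKa)
        z_new <- z_try
      }
      if (obj_new > obj) { converged <- TRUE; iters <- it; break }
      moved <- sqrt(sum((z_new - z)^2))
      z <- z_new
      obj <- obj_new
      obj_trace <- c(obj_trace, obj)
      iters <- it
      if (moved < tol * (1 + sqrt(sum(z^2)))) { converged <- TRUE; break }
    }
    kz <- exp(-gamma * colSums((t(Xs) - z)^2))
    # d/dz of the objective: 4 gamma sum_i alpha_i k(z, x_i) (z - x_i)
    grad <- 4 * gamma * (sum(as * kz) * z - drop(crossprod(Xs, as * kz)))
    list(z = z, objective = obj, iterations = iters,
         converged = converged, grad_norm = sqrt(sum(grad^2)),
         obj_trace = obj_trace)
  }

  starts <- list(init %||% center)
  if (n_restarts > 0) {
    scale <- pmax(apply(Xs, 2, sd), 1e-8)
    extra <- with_seed(derive_seed(seed, "preimage"), {
      lapply(seq_len(n_restarts), function(i) {
        center + rnorm(ncol(Xs), 0, scale)
      })
    })
    starts <- c(starts, extra)
  }
  runs <- lapply(starts, run_from)
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- runs[[which.min(objs)]]
  if (!best$converged) {
    abort(sprintf("pre-image iteration failed to converge (best objective %.3g, gradient norm %.3g).",
                  best$objective, best$grad_norm),
          class = "ocb_convergence_error")
  }
  diag_tbl <- tibble::tibble(
    start = seq_along(runs),
    objective = objs,
    iterations = vapply(runs, `[[`, numeric(1), "iterations"),
    converged = vapply(runs, `[[`, logical(1), "converged")
  )
  list(z = best$z,
       diagnostics = list(objective = best$objective,
                          grad_norm = best$grad_norm,
                          iterations = best$iterations,
                          converged = best$converged,
                          objective_trace = best$obj_trace,
                          starts = diag_tbl))
}

#' Spatial weight map of a fitted one-class model
#'
#' Computes the pre-image of the model weight and unflattens it through the
#' feature index into one spatial representation per condition: voxel-kind
#' features give 3D volumes (out-of-mask voxels zero); region-kind features
#' give per-region value tables painted onto the atlas. Voxels (or regions)
#' with positive values pull a test pattern toward the non-outlier side of
#' the boundary, negative values toward the outlier side. These maps
#' visualise the decision boundary and must not be read as statistical
#' tests of activation.
#'
#' @param model An `ocsvm_model` fitted on an `ocb_features` matrix.
#' @param mask Logical/0-1 3D array the features were built on.
#' @param atlas Integer-labelled 3D array (required for region features).
#' @param ... Passed to [preimage()].
#' @return A `weight_map` object: list with `values` (named list of 3D
#'   arrays, one per condition), `kind`, `table` (region kind only),
#'   `rescaled`, `convergence`, and the caveat in `note`.
#' @export
weight_map <- function(model, mask, atlas = NULL, ...) {
  feats <- model$training_features
  if (!inherits(feats, "ocb_features")) {
    abort("the model must retain an `ocb_features` training matrix to map.",
          class = "ocb_provenance_error")
  }
  fidx <- feature_index(feats)
  if (nrow(fidx) != ncol(feats)) {
    abort("feature index does not match the training feature columns.",
          class = "ocb_provenance_error")
  }
  pre <- preimage(model, ...)
  build_map(pre$z, feats, mask, atlas, convergence = pre$diagnostics)
}

build_map <- function(values_vec, feats, mask, atlas, convergence = NULL,
                      statistic = "weight") {
  mask <- array(mask != 0, dim(mask))
  fidx <- feature_index(feats)
  kind <- attr(feats, "feature_kind")
  conds <- attr(feats, "condition_order")
  vols <- list()
  tab <- NULL
  if (kind == "voxel") {
    for (cond in conds) {
      sel <- fidx$condition == cond
      v <- array(0, dim(mask))
      v[fidx$voxel_index[sel]] <- values_vec[sel]
      vols[[cond]] <- v
    }
  } else {
    if (is.null(atlas)) {
      abort("region-kind maps need the atlas volume.",
            class = "ocb_provenance_error")
    }
    tab <- dplyr::mutate(fidx, value = values_vec)
    for (cond in conds) {
      sel <- which(fidx$condition == cond)
      v <- array(0, dim(mask))
      for (s in sel) {
        v[atlas == fidx$region[s] & mask] <- values_vec[s]
      }
      vols[[cond]] <- v
    }
  }
  structure(
    list(values = vols, kind = kind, table = tab, rescaled = FALSE,
         statistic = statistic, convergence = convergence,
         note = paste("Weight maps visualise the decision boundary;",
                      "they are not statistical tests of activation.")),
    class = "weight_map"
  )
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<%s %s map: %d condition(s)%s>\n", x$kind, x$statistic,
              length(x$values), if (x$rescaled) ", rescaled to [-1, 1]" else ""))
  invisible(x)
}

#' Rescale a map so the absolute maximum is +/- 1
#'
#' Divides every value by the maximum absolute value, per condition map, so
#' the colour scale runs from -1 to +1 with signs preserved. Idempotent.
#'
#' @param map A `weight_map`.
#' @return The rescaled `weight_map` (`rescaled = TRUE`).
#' @export
rescale_map <- function(map) {
  stopifnot(inherits(map, "weight_map"))
  for (cond in names(map$values)) {
    m <- max(abs(map$values[[cond]]))
    if (m == 0) {
      abort(sprintf("condition '%s' map is all zero: cannot rescale.", cond),
            class = "ocb_rescale_error")
    }
    map$values[[cond]] <- map$values[[cond]] / m
  }
  if (!is.null(map$table)) {
    map$table <- map$table |>
      dplyr::group_by(.data$condition) |>
      dplyr::mutate(value = .data$value / max(abs(.data$value))) |>
      dplyr::ungroup()
  }
  map$rescaled <- TRUE
  map
}

#' One-sample t-map of the positive class
#'
#' For every feature (voxel or region, per condition) the one-sample
#' t-statistic \eqn{t = \bar x / (s / \sqrt n)} against a zero mean, with
#' `n - 1` degrees of freedom — the standard second-level univariate
#' statistic to set beside the multivariate weight map. Features with zero
#' sample variance are reported as `t = 0` and flagged; maps are
#' unthresholded.
#'
#' @param features An `ocb_features` matrix of the positive class
#'   (`n >= 2` rows).
#' @param mask Logical/0-1 3D array.
#' @param atlas Atlas volume (region-kind features).
#' @return A `weight_map`-shaped object with `statistic = "t"`, plus `df`
#'   and a `degenerate` logical vector marking zero-variance features.
#' @export
one_sample_tmap <- function(features, mask, atlas = NULL) {
  stopifnot(inherits(features, "ocb_features"))
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 2) {
    abort("need >= 2 subjects for a one-sample t-map.",
          class = "ocb_insufficient_data_error")
  }
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  degenerate <- s == 0
  tval <- ifelse(degenerate, 0, mu / (s / sqrt(n)))
  map <- build_map(tval, features, mask, atlas, statistic = "t")
  map$df <- n - 1L
  map$degenerate <- degenerate
  map
}

#' Write a map's condition volumes as NIfTI files
#'
#' @param map A `weight_map`.
#' @param directory Output directory.
#' @param prefix File-name prefix.
#' @return Tibble of written files (invisibly).
#' @export
write_map <- function(map, directory, prefix = map$statistic) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::imap_chr(map$values, function(v, cond) {
    f <- file.path(directory, sprintf("%s_%s.nii.gz", prefix, cond))
    RNifti::writeNifti(RNifti::asNifti(v), f, datatype = "double")
    f
  })
  if (!is.null(map$table)) {
    tf <- file.path(directory, sprintf("%s_regions.tsv", prefix))
    utils::write.table(as.data.frame(map$table), tf, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, regions = tf)
  }
  invisible(tibble::tibble(condition = names(files), file = unname(files)))
}
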