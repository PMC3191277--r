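new_feature_matrix <- function(values, kind, condition_order, feature_index,
                               subject_ids) {
  if (any(!is.finite(values))) {
    abort("feature matrix contains non-finite values.",
          class = "ocb_validation_error")
  }
  rownames(values) <- subject_ids
  structure(values,
            feature_kind = kind,
            condition_order = condition_order,
            feature_index = feature_index,
            class = c("ocb_features", "matrix", "array"))
}

#' @export
print.ocb_features <- function(x, ...) {
  cat(sprintf("<%s feature matrix: %d subjects x %d features, conditions: %s>\n",
              attr(x, "feature_kind"), nrow(x), ncol(x),
              paste(attr(x, "condition_order"), collapse = ", ")))
  invisible(x)
}

#' Feature provenance table
#'
#' Per-column provenance of a feature matrix: the voxel coordinate (and
#' linear index) or atlas region label each column came from, together with
#' its condition.
#'
#' @param features An `ocb_features` matrix.
#' @return A tibble with one row per feature column.
#' @export
feature_index <- function(features) {
  stopifnot(inherits(features, "ocb_features"))
  attr(features, "feature_index")
}

check_volumes <- function(volumes, mask, condition_order) {
  for (sid in names(volumes)) {
    missing <- setdiff(condition_order, names(volumes[[sid]]))
    if (length(missing) > 0) {
      abort(sprintf("subject '%s' is missing condition(s): %s.",
                    sid, paste(missing, collapse = ", ")),
            class = "ocb_missing_data_error")
    }
    for (cond in condition_order) {
      v <- volumes[[sid]][[cond]]
      if (!identical(dim(v), dim(mask))) {
        stop_shape(sprintf(
          "volume grid %s for subject '%s' condition '%s' does not match mask grid %s.",
          paste(dim(v), collapse = "x"), sid, cond,
          paste(dim(mask), collapse = "x")))
      }
    }
  }
}

#' Voxel-based feature vectors from condition-wise beta volumes
#'
#' For each subject, in-mask voxel values of the first condition, then the
#' second, and so on, are concatenated into a single pattern vector — the
#' whole-brain multivoxel representation the one-class analysis operates on.
#' Voxels are taken in ascending linear (array, x-fastest) index order; the
#' order is fixed and recorded in the feature index so spatial maps can be
#' reconstructed exactly.
#'
#' No feature scaling is applied by default: the RBF kernel is evaluated on
#' raw beta values. Optional z-scoring (per feature, across subjects) is
#' available behind `standardize`.
#'
#' @param volumes Named list: `volumes[[subject_id]][[condition]]` is a 3D
#'   array on the mask's grid.
#' @param mask Logical (or 0/1) 3D array.
#' @param condition_order Character vector of conditions, concatenated in
#'   this order. Defaults to the conditions of the first subject.
#' @param standardize If `TRUE`, z-score each feature across subjects.
#' @return An `ocb_features` matrix (subjects x voxels*conditions).
#' @export
voxel_features <- function(volumes, mask, condition_order = NULL,
                           standardize = FALSE) {
  mask <- array(mask != 0, dim(mask))
  condition_order <- condition_order %||% names(volumes[[1]])
  check_volumes(volumes, mask, condition_order)
  idx <- which(mask)
  coords <- arrayInd(idx, dim(mask))
  values <- do.call(rbind, lapply(volumes, function(vols) {
    unlist(lapply(condition_order, function(cond) vols[[cond]][idx]),
           use.names = FALSE)
  }))
  fidx <- tidyr::crossing(condition = factor(condition_order,
                                             levels = condition_order),
                          pos = seq_along(idx)) |>
    dplyr::arrange(.data$condition, .data$pos) |>
    dplyr::mutate(condition = as.character(.data$condition),
                  voxel_index = idx[.data$pos],
                  x = coords[.data$pos, 1],
                  y = coords[.data$pos, 2],
                  z = coords[.data$pos, 3]) |>
    dplyr::select(-"pos")
  if (standardize) values <- standardize_columns(values)
  new_feature_matrix(values, "voxel", condition_order, fidx, names(volumes))
}

#' Atlas-region feature vectors from condition-wise beta volumes
#'
#' Per subject, per condition and per atlas region, the arithmetic mean of
#' the in-mask voxel values carrying that region label; conditions are then
#' concatenated in `condition_order`. Regions are intersected with the mask;
#' a region with no in-mask voxels raises an error by default or is dropped
#' with a warning.
#'
#' @inheritParams voxel_features
#' @param atlas Integer-labelled 3D array; 0 = background.
#' @param empty_regions Either `"error"` (default) or `"drop"`.
#' @return An `ocb_features` matrix (subjects x regions*conditions).
#' @export
region_features <- function(volumes, atlas, mask, condition_order = NULL,
                            empty_regions = c("error", "drop"),
                            standardize = FALSE) {
  empty_regions <- match.arg(empty_regions)
  mask <- array(mask != 0, dim(mask))
  if (!identical(dim(atlas), dim(mask))) {
    stop_shape("atlas grid does not match mask grid.")
  }
  condition_order <- condition_order %||% names(volumes[[1]])
  check_volumes(volumes, mask, condition_order)
  labels <- setdiff(sort(unique(as.vector(atlas))), 0L)
  region_idx <- lapply(labels, function(l) which(atlas == l & mask))
  empty <- lengths(region_idx) == 0
  if (any(empty)) {
    if (empty_regions == "error") {
      abort(sprintf("region label(s) with no in-mask voxels: %s.",
                    paste(labels[empty], collapse = ", ")),
            class = "ocb_validation_error")
    }
    warn(sprintf("dropping empty region label(s): %s.",
                 paste(labels[empty], collapse = ", ")))
    labels <- labels[!empty]
    region_idx <- region_idx[!empty]
  }
  values <- do.call(rbind, lapply(volumes, function(vols) {
    unlist(lapply(condition_order, function(cond) {
      vapply(region_idx, function(ix) mean(vols[[cond]][ix]), numeric(1))
    }), use.names = FALSE)
  }))
  fidx <- tidyr::crossing(condition = factor(condition_order,
                                             levels = condition_order),
                          region = labels) |>
    dplyr::arrange(.data$condition, .data$region) |>
    dplyr::mutate(condition = as.character(.data$condition))
  if (standardize) values <- standardize_columns(values)
  new_feature_matrix(values, "region", condition_order, fidx, names(volumes))
}

standardize_columns <- function(values) {
  mu <- colMeans(values)
  s <- apply(values, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(values, 2, mu, "-"), 2, s, "/")
}

#' Row subsetting of a feature matrix
#'
#' Selecting whole rows (subjects) keeps the feature metadata (kind,
#' condition order, feature index) intact, so downstream mapping still
#' works; selecting columns returns a plain matrix, since a column subset
#' no longer matches the recorded feature index.
#'
#' @param x An `ocb_features` matrix.
#' @param i Row indices or subject ids.
#' @param j Column indices (drops the feature metadata).
#' @param ... Ignored.
#' @param drop Ignored for row subsetting; passed on for column subsetting.
#' @return An `ocb_features` matrix (rows only) or a plain matrix.
#' @export
`[.ocb_features` <- function(x, i, j, ..., drop) {
  if (nargs() == 2L) return(unclass(x)[i]) # linear indexing
  if (missing(j)) {
    if (missing(i)) return(x)
    return(features_subset(x, i))
  }
  if (missing(i)) {
    if (missing(drop)) unclass(x)[, j] else unclass(x)[, j, drop = drop]
  } else {
    if (missing(drop)) unclass(x)[i, j] else unclass(x)[i, j, drop = drop]
  }
}

# subset rows (by index or subject id), keeping feature metadata
features_subset <- function(features, rows) {
  if (is.character(rows)) rows <- match(rows, rownames(features))
  new_feature_matrix(unclass(features)[rows, , drop = FALSE],
                     attr(features, "feature_kind"),
                     attr(features, "condition_order"),
                     attr(features, "feature_index"),
                     rownames(features)[rows])
}
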