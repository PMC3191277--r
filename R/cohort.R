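#' Specify a synthetic cohort
#'
#' A `cohort_spec` fixes every parameter of the synthetic generator, which
#' emulates the statistical structure a normality-boundary analysis assumes:
#' healthy controls share one activation pattern per condition plus voxelwise
#' Gaussian noise; patients carry the same pattern plus a deviation pattern
#' whose amplitude scales linearly with clinical severity; severity (HRSD
#' points) is drawn uniformly over `severity_range` with truncated Gaussian
#' noise; treatment response is derived from a simulated post-treatment score
#' against `response_threshold`; and each control is pair-matched to a
#' patient via a shared `pair_id` (standing in for age/sex matching).
#'
#' The defaults describe the reference study conditions: 19 controls and 19
#' patients, a 12x12x12 grid with an ellipsoidal brain mask, 3 task
#' conditions (low/medium/high stimulus intensity), a 20-region parcellation,
#' a shared activation pattern of SD 3 beta units with voxel noise of SD
#' 0.5 and 10% per-subject amplitude variability, a sparse deviation pattern on
#' ~10% of in-mask voxels scaled by 0.2 beta units per HRSD point (so the
#' planted severity coupling dominates the noise at this grid size),
#' severity uniform on 18-25 HRSD points (acute-episode inclusion range),
#' and response defined as a post-treatment score below 10.
#'
#' @param n_controls,n_patients Positive integers.
#' @param grid_shape Integer vector of 3 axis lengths (each >= 2).
#' @param n_conditions Positive integer; 3 conditions are named
#'   `low`, `medium`, `high`, otherwise `cond1 ...`.
#' @param n_regions Positive integer, at most the number of in-mask voxels.
#' @param noise_sd Non-negative voxel noise SD (beta units).
#' @param pattern_sd SD of the shared baseline activation pattern across
#'   voxels (beta units). The pattern must be appreciably stronger than the
#'   voxel noise for subject-level amplitude differences to shape the
#'   boundary, as they do in smoothed group-space coefficient images.
#' @param amplitude_sd SD of the per-subject multiplicative amplitude on
#'   the shared baseline pattern (mean 1). Individual differences in
#'   overall response amplitude are what make some subjects lie nearer the
#'   centre of the normal distribution than others; with iid voxel noise
#'   alone every held-out subject would be equally (and maximally) atypical.
#' @param deviation_scale Non-negative deviation amplitude per severity
#'   point (beta units / HRSD point).
#' @param severity_range Interval (length-2 non-negative numeric) of patient
#'   severity scores (HRSD points).
#' @param severity_noise_sd Non-negative SD of severity noise (HRSD points).
#' @param response_threshold Post-treatment score (HRSD points) below which
#'   a patient counts as a treatment responder.
#' @param seed Integer root seed; every random draw flows from it.
#' @return A validated `cohort_spec` object.
#' @examples
#' spec <- cohort_spec(n_controls = 4, n_patients = 4, grid_shape = c(6, 6, 6))
#' @export
cohort_spec <- function(n_controls = 19L,
                        n_patients = 19L,
                        grid_shape = c(12L, 12L, 12L),
                        n_conditions = 3L,
                        n_regions = 20L,
                        noise_sd = 0.5,
                        pattern_sd = 3,
                        amplitude_sd = 0.1,
                        deviation_scale = 0.2,
                        severity_range = c(18, 25),
                        severity_noise_sd = 1,
                        response_threshold = 10,
                        seed = 1L) {
  assert_scalar_number(n_controls, "n_controls", lower = 0)
  assert_scalar_number(n_patients, "n_patients", lower = 0)
  if (length(grid_shape) != 3L || any(grid_shape < 2)) {
    abort("`grid_shape` must be three axis lengths, each >= 2.",
          class = "ocb_spec_error")
  }
  assert_scalar_number(n_conditions, "n_conditions", lower = 1)
  assert_scalar_number(n_regions, "n_regions", lower = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(pattern_sd, "pattern_sd", lower = 0)
  assert_scalar_number(amplitude_sd, "amplitude_sd", lower = 0)
  assert_scalar_number(deviation_scale, "deviation_scale", lower = 0)
  if (length(severity_range) != 2L || any(severity_range < 0) ||
      severity_range[1] > severity_range[2]) {
    abort("`severity_range` must be a non-negative interval.",
          class = "ocb_spec_error")
  }
  assert_scalar_number(severity_noise_sd, "severity_noise_sd", lower = 0)
  assert_scalar_number(response_threshold, "response_threshold")
  assert_scalar_number(seed, "seed")

  spec <- list(
    n_controls = as.integer(n_controls),
    n_patients = as.integer(n_patients),
    grid_shape = as.integer(grid_shape),
    n_conditions = as.integer(n_conditions),
    n_regions = as.integer(n_regions),
    noise_sd = noise_sd,
    pattern_sd = pattern_sd,
    amplitude_sd = amplitude_sd,
    deviation_scale = deviation_scale,
    severity_range = as.numeric(severity_range),
    severity_noise_sd = severity_noise_sd,
    response_threshold = response_threshold,
    seed = as.integer(seed)
  )
  mask <- ellipsoid_mask(spec$grid_shape)
  n_inmask <- sum(mask)
  if (spec$n_regions > n_inmask) {
    abort(sprintf("n_regions = %d exceeds the %d in-mask voxels.",
                  spec$n_regions, n_inmask),
          class = "ocb_spec_error")
  }
  structure(spec, class = "cohort_spec")
}

condition_names <- function(n) {
  if (n == 3L) c("low", "medium", "high") else paste0("cond", seq_len(n))
}

# Ellipsoid inscribed in the grid: crude brain-like mask with background.
ellipsoid_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  ax <- pmax(grid_shape / 2 - 0.5, 1)
  i <- slice.index(array(0, grid_shape), 1)
  j <- slice.index(array(0, grid_shape), 2)
  k <- slice.index(array(0, grid_shape), 3)
  r2 <- ((i - ctr[1]) / ax[1])^2 + ((j - ctr[2]) / ax[2])^2 +
    ((k - ctr[3]) / ax[3])^2
  array(r2 <= 1, grid_shape)
}

# Contiguous near-equal blocks of in-mask voxels (ascending linear index),
# label 0 = background.
block_atlas <- function(mask, n_regions) {
  idx <- which(mask)
  sizes <- rep(length(idx) %/% n_regions, n_regions)
  extra <- length(idx) %% n_regions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  atlas <- array(0L, dim(mask))
  atlas[idx] <- rep(seq_len(n_regions), times = sizes)
  atlas
}

#' Simulate a synthetic control/patient cohort
#'
#' Generates per-subject per-condition 3D "beta" volumes, a binary brain
#' mask, an integer-labelled atlas partitioning the in-mask voxels into
#' contiguous regions, and a subject metadata table. Each subject expresses
#' the shared baseline pattern at an individual amplitude
#' `a_s ~ N(1, amplitude_sd^2)` plus iid voxel noise; patient volumes add
#' `severity * deviation_scale * D(condition)` where `D` is a fixed sparse
#' deviation pattern (~10% of in-mask voxels, signs +/-1). Low-deviation
#' patients receive a larger simulated treatment effect, producing the
#' two-subgroup responder structure the analysis looks for.
#'
#' All randomness derives from `spec$seed`: the same spec yields
#' bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `ocs_cohort`: a list with `volumes` (named
#'   list of subjects, each a named list of condition arrays), `mask`
#'   (logical array), `atlas` (integer array, 0 = background), `table`
#'   (tibble with columns `subject_id`, `group`, `pair_id`, `severity`,
#'   `response`), and the generating `spec`.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_controls = 3, n_patients = 3,
#'                                   grid_shape = c(6, 6, 6), n_regions = 4))
#' co$table
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mask <- ellipsoid_mask(spec$grid_shape)
  atlas <- block_atlas(mask, spec$n_regions)
  idx <- which(mask)
  n_vox <- length(idx)
  conds <- condition_names(spec$n_conditions)
  nc <- spec$n_controls
  np <- spec$n_patients
  n_pairs <- min(nc, np)

  out <- with_seed(derive_seed(spec$seed, "cohort"), {
    baseline <- matrix(rnorm(n_vox * spec$n_conditions, 0, spec$pattern_sd),
                       n_vox, spec$n_conditions)
    support <- sort(sample.int(n_vox, max(1L, round(0.1 * n_vox))))
    deviation <- matrix(0, n_vox, spec$n_conditions)
    deviation[support, ] <- sample(c(-1, 1),
                                   length(support) * spec$n_conditions,
                                   replace = TRUE)

    sev_ctrl <- pmax(0, rnorm(nc, mean = 0.3, sd = 0.7))
    sev_pat <- pmax(0, runif(np, spec$severity_range[1],
                             spec$severity_range[2]) +
                      rnorm(np, 0, spec$severity_noise_sd))

    # Two-subgroup treatment effect: low-severity (hence low-deviation)
    # patients get the larger simulated benefit and tend to respond.
    if (np > 0) {
      low <- sev_pat <= median(sev_pat)
      effect <- ifelse(low, 16, 8) + rnorm(np, 0, 2)
      post <- sev_pat - effect
      response_pat <- ifelse(post < spec$response_threshold,
                             "responder", "non-responder")
    } else {
      response_pat <- character(0)
    }
    amplitude <- rnorm(nc + np, mean = 1, sd = spec$amplitude_sd)

    ids <- c(sprintf("ctrl%02d", seq_len(nc)), sprintf("pat%02d", seq_len(np)))
    groups <- c(rep("control", nc), rep("patient", np))
    severity <- c(sev_ctrl, sev_pat)
    pair_of <- function(i, n) {
      ifelse(i <= n_pairs, sprintf("pair%02d", i), sprintf("solo%s%02d",
                                                           n, i))
    }
    pair_id <- c(
      if (nc > 0) pair_of(seq_len(nc), "c") else character(0),
      if (np > 0) ifelse(seq_len(np) <= n_pairs,
                         sprintf("pair%02d", seq_len(np)),
                         NA_character_) else character(0)
    )

    volumes <- vector("list", nc + np)
    names(volumes) <- ids
    for (s in seq_len(nc + np)) {
      dev_amp <- if (groups[s] == "patient") {
        severity[s] * spec$deviation_scale
      } else 0
      vols <- vector("list", spec$n_conditions)
      names(vols) <- conds
      for (cix in seq_len(spec$n_conditions)) {
        v <- array(0, spec$grid_shape)
        v[idx] <- amplitude[s] * baseline[, cix] +
          dev_amp * deviation[, cix] + rnorm(n_vox, 0, spec$noise_sd)
        vols[[cix]] <- v
      }
      volumes[[s]] <- vols
    }

    table <- tibble::tibble(
      subject_id = ids,
      group = groups,
      pair_id = pair_id,
      severity = severity,
      response = c(rep("not-applicable", nc), response_pat)
    )
    list(volumes = volumes, table = table,
         patterns = list(baseline = baseline, deviation = deviation,
                         support = support))
  })

  structure(
    list(volumes = out$volumes, mask = mask, atlas = atlas,
         table = out$table, spec = spec, patterns = out$patterns),
    class = "ocs_cohort"
  )
}

#' @export
print.ocs_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d controls + %d patients, grid %s, %d conditions, %d regions\n",
    x$spec$n_controls, x$spec$n_patients,
    paste(x$spec$grid_shape, collapse = "x"),
    x$spec$n_conditions, x$spec$n_regions))
  print(x$table, n = 6)
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus a TSV table
#'
#' Volumes, mask and atlas are written as NIfTI-1 (double precision, exact
#' round trip), the subject table as TSV, and a JSON manifest listing every
#' file. [read_cohort()] on the same directory reproduces the cohort.
#'
#' @param cohort An `ocs_cohort` (or a compatible list).
#' @param directory Output directory, created if needed.
#' @return A tibble manifest with columns `file`, `kind`, `subject_id`,
#'   `condition`; also written as `manifest.json`.
#' @export
write_fixtures <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    abort(sprintf("cannot create directory '%s'.", directory),
          class = "ocb_io_error")
  }
  rows <- list()
  for (sid in names(cohort$volumes)) {
    for (cond in names(cohort$volumes[[sid]])) {
      f <- file.path(directory, sprintf("%s_%s.nii.gz", sid, cond))
      RNifti::writeNifti(RNifti::asNifti(cohort$volumes[[sid]][[cond]]),
                         f, datatype = "double")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        file = basename(f), kind = "volume", subject_id = sid,
        condition = cond)
    }
  }
  mask_f <- file.path(directory, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(cohort$mask),
                                           dim(cohort$mask))),
                     mask_f, datatype = "int32")
  atlas_f <- file.path(directory, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(cohort$atlas),
                                           dim(cohort$atlas))),
                     atlas_f, datatype = "int32")
  table_f <- file.path(directory, "cohort.tsv")
  utils::write.table(as.data.frame(cohort$table), table_f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    file = "mask.nii.gz", kind = "mask", subject_id = NA, condition = NA)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    file = "atlas.nii.gz", kind = "atlas", subject_id = NA, condition = NA)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    file = "cohort.tsv", kind = "table", subject_id = NA, condition = NA)
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       dataframe = "rows", na = "null")
  manifest
}

#' Read a cohort directory written by [write_fixtures()]
#'
#' Validates the loaded cohort: all volumes must share one grid, subject ids
#' must be unique, every patient `pair_id` must resolve to a control, and
#' every atlas label must intersect the mask.
#'
#' @param directory Directory containing `manifest.json`.
#' @return An `ocs_cohort`-shaped list (without a generating `spec`).
#' @export
read_cohort <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) {
    abort(sprintf("no manifest.json under '%s'.", directory),
          class = "ocb_io_error")
  }
  manifest <- tibble::as_tibble(jsonlite::fromJSON(mf))
  read_vol <- function(f) as.array(RNifti::readNifti(file.path(directory, f)))

  mask_row <- manifest$file[manifest$kind == "mask"]
  atlas_row <- manifest$file[manifest$kind == "atlas"]
  table_row <- manifest$file[manifest$kind == "table"]
  mask <- array(read_vol(mask_row) != 0, dim(read_vol(mask_row)))
  atlas <- array(as.integer(read_vol(atlas_row)), dim(mask))
  table <- tibble::as_tibble(utils::read.delim(
    file.path(directory, table_row), sep = "\t",
    colClasses = c(subject_id = "character", group = "character",
                   pair_id = "character", severity = "numeric",
                   response = "character")))

  vol_rows <- manifest[manifest$kind == "volume", , drop = FALSE]
  volumes <- list()
  for (r in seq_len(nrow(vol_rows))) {
    v <- read_vol(vol_rows$file[r])
    if (!identical(dim(v), dim(mask))) {
      stop_shape(sprintf("volume '%s' grid %s does not match mask grid %s.",
                         vol_rows$file[r], paste(dim(v), collapse = "x"),
                         paste(dim(mask), collapse = "x")))
    }
    volumes[[vol_rows$subject_id[r]]][[vol_rows$condition[r]]] <- v
  }

  if (anyDuplicated(table$subject_id)) {
    abort("duplicate subject ids in cohort table.",
          class = "ocb_validation_error")
  }
  pat <- table[table$group == "patient", , drop = FALSE]
  ctl <- table[table$group == "control", , drop = FALSE]
  if (nrow(pat) > 0) {
    missing_pair <- is.na(pat$pair_id) | !(pat$pair_id %in% ctl$pair_id)
    if (any(missing_pair)) {
      abort(sprintf("patients without a matched control: %s.",
                    paste(pat$subject_id[missing_pair], collapse = ", ")),
            class = "ocb_pairing_error")
    }
  }
  labs <- setdiff(sort(unique(as.vector(atlas))), 0L)
  dangling <- labs[vapply(labs, function(l) !any(atlas == l & mask), logical(1))]
  if (length(dangling) > 0) {
    abort(sprintf("atlas labels with no in-mask voxels: %s.",
                  paste(dangling, collapse = ", ")),
          class = "ocb_validation_error")
  }
  structure(list(volumes = volumes, mask = mask, atlas = atlas,
                 table = table, spec = NULL),
            class = "ocs_cohort")
}
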