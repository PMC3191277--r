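fit_small <- function(X, nu, gamma) fit_ocsvm(X, nu = nu, gamma = gamma)

test_that("a single dominant support vector is its own pre-image", {
  # two far-separated points at tiny nu: the solution can concentrate
  X <- rbind(c(0, 0), c(10, 10))
  m <- fit_small(X, nu = 0.5, gamma = 0.5)
  # construct the single-SV case directly
  m$alphas <- c(1, 0)
  m$support_indices <- 1L
  m$objective_value <- 0.5
  pre <- preimage(m, n_restarts = 0)
  expect_identical(pre$z, X[1, ])
})

test_that("a symmetric equal-weight pair started at the midpoint stays there", {
  X <- rbind(c(2, 0), c(-2, 0))
  m <- fit_small(X, nu = 1, gamma = 0.1)
  expect_equal(m$alphas, c(0.5, 0.5))
  pre <- preimage(m, init = c(0, 0), n_restarts = 0)
  expect_equal(pre$z, c(0, 0))
  expect_true(pre$diagnostics$converged)
})

test_that("the pre-image objective matches a brute-force 2-D minimiser", {
  set.seed(31)
  for (rep in 1:3) {
    X <- matrix(rnorm(5 * 2), 5, 2)
    m <- fit_small(X, nu = 0.6, gamma = 0.8)
    pre <- preimage(m, n_restarts = 5, seed = rep)
    or <- preimage_oracle_2d(m)
    expect_lt(pre$diagnostics$objective, or$objective + 1e-6)
  }
})

test_that("accepted pre-image iterations never increase the objective", {
  set.seed(32)
  X <- matrix(rnorm(8 * 3), 8, 3)
  m <- fit_small(X, nu = 0.5, gamma = 0.6)
  pre <- preimage(m, n_restarts = 3, seed = 2)
  trace <- pre$diagnostics$objective_trace
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("voxel weight maps unflatten and re-flatten losslessly with zero background", {
  co <- tiny_cohort(seed = 33)
  fv <- voxel_features(co$volumes, co$mask)
  m <- fit_ocsvm(subset_features(fv, control_ids(co)), nu = 0.5, gamma = 1e-5)
  wm <- weight_map(m, co$mask, seed = 1)
  expect_equal(names(wm$values), c("low", "medium", "high"))
  pre <- preimage(m, seed = 1)
  fidx <- feature_index(fv)
  reflat <- unlist(lapply(c("low", "medium", "high"), function(cond) {
    wm$values[[cond]][fidx$voxel_index[fidx$condition == cond]]
  }))
  expect_equal(unname(reflat), unname(pre$z))
  for (cond in names(wm$values)) {
    expect_true(all(wm$values[[cond]][!co$mask] == 0))
  }
})

test_that("region weight maps paint piecewise-constant volumes", {
  co <- tiny_cohort(seed = 34)
  fr <- region_features(co$volumes, co$atlas, co$mask)
  m <- fit_ocsvm(subset_features(fr, control_ids(co)), nu = 0.5, gamma = 1e-3)
  wm <- weight_map(m, co$mask, co$atlas, seed = 1)
  expect_equal(length(wm$values), 3)
  v <- wm$values$low
  for (r in 1:5) {
    vals <- unique(v[co$atlas == r & co$mask])
    expect_equal(length(vals), 1)
  }
  expect_false(is.null(wm$table))
  expect_equal(nrow(wm$table), 15)
})

test_that("rescaling divides by the absolute maximum, preserves signs, and is idempotent", {
  co <- tiny_cohort(seed = 35)
  fv <- voxel_features(co$volumes, co$mask)
  m <- fit_ocsvm(subset_features(fv, control_ids(co)), nu = 0.5, gamma = 1e-5)
  wm <- weight_map(m, co$mask, seed = 1)
  rs <- rescale_map(wm)
  for (cond in names(rs$values)) {
    expect_identical(max(abs(rs$values[[cond]])), 1)
    raw <- wm$values[[cond]]
    expect_equal(rs$values[[cond]], raw / max(abs(raw)))
  }
  rs2 <- rescale_map(rs)
  expect_equal(rs2$values, rs$values)
  # a negative absolute maximum maps to -1
  neg <- wm
  neg$values <- list(low = array(c(-4, 2, 0), c(3, 1, 1)))
  out <- rescale_map(neg)
  expect_equal(as.numeric(out$values$low), c(-1, 0.5, 0))
  zero <- wm
  zero$values <- list(low = array(0, c(2, 2, 1)))
  expect_error(rescale_map(zero), class = "ocb_rescale_error")
})

test_that("one-sample t-maps match the closed form and an independent t-test", {
  mask <- array(TRUE, c(2, 1, 1))
  vols <- list(s1 = list(low = array(c(1, 5), c(2, 1, 1))),
               s2 = list(low = array(c(2, 5), c(2, 1, 1))),
               s3 = list(low = array(c(3, 5), c(2, 1, 1))))
  fm <- voxel_features(vols, mask, "low")
  tm <- one_sample_tmap(fm, mask)
  expect_equal(tm$values$low[1, 1, 1], 3.4641, tolerance = 1e-4)
  expect_equal(tm$df, 2L)
  # constant feature (sd = 0) reports t = 0 with the degeneracy flag
  expect_equal(tm$values$low[2, 1, 1], 0)
  expect_identical(tm$degenerate, c(FALSE, TRUE))

  set.seed(36)
  co <- tiny_cohort(seed = 36)
  fv <- voxel_features(co$volumes, co$mask)
  ctl <- subset_features(fv, control_ids(co))
  tm2 <- one_sample_tmap(ctl, co$mask)
  X <- as.matrix(ctl)
  for (j in c(1, 17, 40)) {
    tt <- stats::t.test(X[, j], mu = 0)
    fidx <- feature_index(ctl)[j, ]
    expect_equal(tm2$values[[fidx$condition]][fidx$voxel_index],
                 unname(tt$statistic), tolerance = 1e-12)
  }
})

test_that("antisymmetric samples give a zero t-statistic", {
  mask <- array(TRUE, c(1, 1, 1))
  vols <- list(s1 = list(low = array(-3, c(1, 1, 1))),
               s2 = list(low = array(3, c(1, 1, 1))))
  tm <- one_sample_tmap(voxel_features(vols, mask, "low"), mask)
  expect_equal(tm$values$low[1, 1, 1], 0)
})

test_that("map files are written per condition and region tables alongside", {
  co <- tiny_cohort(seed = 37)
  fr <- region_features(co$volumes, co$atlas, co$mask)
  m <- fit_ocsvm(subset_features(fr, control_ids(co)), nu = 0.5, gamma = 1e-3)
  wm <- weight_map(m, co$mask, co$atlas, seed = 1)
  dir <- withr::local_tempdir()
  files <- write_map(wm, dir, prefix = "w")
  expect_true(all(file.exists(files$file)))
  v <- as.array(RNifti::readNifti(files$file[files$condition == "low"]))
  expect_equal(as.numeric(v), as.numeric(wm$values$low))
})
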