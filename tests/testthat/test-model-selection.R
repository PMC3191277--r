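test_that("inner_score reflects boundary membership at leave-one-out granularity", {
  set.seed(1)
  train <- matrix(rnorm(8 * 2), 8, 2)
  near <- train[1, , drop = FALSE]
  far <- matrix(rep(1e3, 2), 1, 2)
  expect_equal(inner_score(train, near, nu = 0.1, gamma = 1e-4), 1)
  expect_equal(inner_score(train, far, nu = 0.1, gamma = 1), 0)
  one <- inner_score(train[-1, ], train[1, , drop = FALSE], 0.2, 0.01)
  expect_true(one %in% c(0, 1))
})

test_that("a singleton grid is returned unchanged", {
  set.seed(2)
  X <- matrix(rnorm(5 * 2), 5, 2)
  g <- search_grid(nu_values = 0.3, gamma_values = 1e-4, initial_nu = 0.3)
  sel <- two_step_search(X, g)
  expect_equal(sel$gamma, 1e-4)
  expect_equal(sel$nu, 0.3)
})

test_that("accuracy ties resolve to the largest gamma (smallest sigma) and smallest nu", {
  # identical training points: every candidate scores perfectly
  X <- matrix(1, 4, 3) + 0
  g <- search_grid(nu_values = c(0.1, 0.3, 0.5),
                   gamma_values = c(1e-6, 1e-4, 1e-2))
  sel <- two_step_search(X, g)
  expect_equal(sel$gamma, 1e-2)
  expect_equal(sel$nu, 0.1)
  expect_true(all(sel$step1$accuracy == sel$step1$accuracy[1]))
})

test_that("two_step_search agrees with an exhaustive re-evaluation via inner_score", {
  set.seed(3)
  X <- matrix(rnorm(8 * 3, sd = 2), 8, 3)
  grid <- search_grid(nu_values = c(0.2, 0.4),
                      gamma_values = c(1e-3, 1e-2, 1e-1), initial_nu = 0.2)
  sel <- two_step_search(X, grid)
  loo <- function(nu, gamma) {
    mean(vapply(seq_len(nrow(X)), function(i) {
      inner_score(X[-i, , drop = FALSE], X[i, , drop = FALSE], nu, gamma)
    }, numeric(1)))
  }
  acc1 <- vapply(grid$gamma_values, function(g) loo(grid$initial_nu, g),
                 numeric(1))
  g_star <- grid$gamma_values[max(which(acc1 == max(acc1)))]
  acc2 <- vapply(grid$nu_values, function(nu) loo(nu, g_star), numeric(1))
  nu_star <- grid$nu_values[min(which(acc2 == max(acc2)))]
  expect_equal(sel$gamma, g_star)
  expect_equal(sel$nu, nu_star)
  expect_equal(sel$step1$accuracy, acc1)
  expect_equal(sel$step2$accuracy, acc2)
})

test_that("invalid grids are rejected", {
  expect_error(search_grid(nu_values = numeric(0)), class = "ocb_config_error")
  expect_error(search_grid(nu_values = c(0.3, 0.2)), class = "ocb_config_error")
  expect_error(search_grid(gamma_values = c(-1, 1)), class = "ocb_config_error")
})

test_that("the outer loop makes one fold per pair and never leaks the held-out subjects", {
  co <- tiny_cohort(seed = 11)
  fv <- voxel_features(co$volumes, co$mask)
  grid <- search_grid(nu_values = c(0.1, 0.3),
                      gamma_values = 10^seq(-6, -4, by = 1))
  cv <- nested_loo(fv, co$table, grid)
  expect_equal(nrow(cv$folds), 6)
  for (f in seq_len(nrow(cv$folds))) {
    train_ids <- cv$folds$train_ids[[f]]
    expect_false(cv$folds$positive_id[f] %in% train_ids)
    expect_false(cv$folds$negative_id[f] %in% train_ids)
    expect_equal(length(train_ids), 5)
  }
  # matched pairing respected
  tab <- co$table
  for (f in seq_len(nrow(cv$folds))) {
    p <- tab$pair_id[tab$subject_id == cv$folds$positive_id[f]]
    q <- tab$pair_id[tab$subject_id == cv$folds$negative_id[f]]
    expect_identical(p, q)
  }
})

test_that("averaged parameters are the geometric (gamma) and arithmetic (nu) fold means", {
  co <- tiny_cohort(seed = 12)
  fv <- voxel_features(co$volumes, co$mask)
  grid <- search_grid(nu_values = c(0.1, 0.3),
                      gamma_values = 10^seq(-6, -4, by = 1))
  cv <- nested_loo(fv, co$table, grid)
  expect_equal(cv$averaged_gamma, exp(mean(log(cv$folds$gamma))))
  expect_equal(cv$averaged_nu, mean(cv$folds$nu))
  # the stated averaging rule on a log-spaced pair
  expect_equal(exp(mean(log(c(1e-5, 1e-7)))), 1e-6, tolerance = 1e-12)
})

test_that("the final model is fit on all positives with exactly the averaged parameters", {
  co <- tiny_cohort(seed = 13)
  fv <- voxel_features(co$volumes, co$mask)
  grid <- search_grid(nu_values = c(0.2, 0.4),
                      gamma_values = 10^seq(-6, -4, by = 1))
  cv <- nested_loo(fv, co$table, grid)
  fm <- final_model(subset_features(fv, control_ids(co)), cv)
  expect_equal(fm$gamma, cv$averaged_gamma)
  expect_equal(fm$nu, cv$averaged_nu)
  expect_equal(length(fm$alphas), 6)
  # deterministic: refitting reproduces decision values exactly
  fm2 <- final_model(subset_features(fv, control_ids(co)), cv)
  pat <- subset_features(fv, patient_ids(co))
  expect_identical(decision_values(fm, pat), decision_values(fm2, pat))
})

test_that("swapping the positive class reruns the identical protocol on patients", {
  co <- tiny_cohort(seed = 14)
  fv <- voxel_features(co$volumes, co$mask)
  grid <- search_grid(nu_values = c(0.1, 0.3),
                      gamma_values = 10^seq(-6, -4, by = 1))
  cv <- nested_loo(fv, co$table, grid, positive_class = "patient")
  expect_equal(nrow(cv$folds), 6)
  expect_true(all(cv$folds$positive_id %in% patient_ids(co)))
  expect_true(all(cv$folds$negative_id %in% control_ids(co)))
  gl <- glance(cv)
  expect_identical(gl$positive_class, "patient")
})

test_that("unmatched positives raise a pairing error", {
  co <- tiny_cohort(seed = 15)
  tab <- co$table
  tab$pair_id[tab$group == "patient"][2] <- NA
  fv <- voxel_features(co$volumes, co$mask)
  expect_error(nested_loo(fv, tab, search_grid()),
               class = "ocb_pairing_error")
})
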