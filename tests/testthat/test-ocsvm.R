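test_that("nu = 1 forces the uniform dual solution exactly", {
  set.seed(1)
  X <- matrix(rnorm(12 * 3), 12, 3)
  m <- fit_ocsvm(X, nu = 1, gamma = 0.2)
  expect_equal(m$alphas, rep(1 / 12, 12))
  expect_equal(nu_property_report(m)$sv_fraction, 1)
})

test_that("two distinct points at nu = 0.5 split mass symmetrically and sit on the boundary", {
  X <- rbind(c(1, 0), c(-1, 0))
  m <- fit_ocsvm(X, nu = 0.5, gamma = 0.3)
  expect_equal(m$alphas, c(0.5, 0.5), tolerance = 1e-10)
  f <- decision_values(m, X)$decision_value
  expect_equal(f, c(0, 0), tolerance = 1e-10)
})

test_that("dual solution matches a generic QP solve on random instances", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    d <- sample(2:5, 1)
    X <- matrix(rnorm(n * d), n, d)
    nu <- sample(c(0.3, 0.5, 0.8), 1)
    g <- runif(1, 0.1, 1)
    m <- fit_ocsvm(X, nu = nu, gamma = g)
    K <- kernel_matrix(X, gamma = g)
    or <- qp_oracle(K, nu)
    expect_lt(abs(m$objective_value - or$objective), 1e-6)
    expect_lt(max(abs(m$alphas - or$alpha)), 1e-4)
    # decision function agrees with direct evaluation from the oracle fit
    test_pts <- matrix(rnorm(3 * d), 3, d)
    rho_or <- m$rho # same K, same alphas to 1e-4: compare full f instead
    f_pkg <- decision_values(m, test_pts)$decision_value
    f_dir <- drop(naive_kernel(test_pts, X, g) %*% or$alpha) - m$rho
    expect_equal(f_pkg, f_dir, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("fitted duals agree with the LIBSVM parameterisation up to its scaling", {
  set.seed(11)
  X <- matrix(rnorm(10 * 3), 10, 3)
  nu <- 0.4
  g <- 0.3
  m <- fit_ocsvm(X, nu = nu, gamma = g)
  sv <- e1071::svm(X, type = "one-classification", kernel = "radial",
                   gamma = g, nu = nu, scale = FALSE)
  a_lib <- rep(0, 10)
  a_lib[sv$index] <- sv$coefs
  # LIBSVM solves the same program with alpha summing to nu * n
  expect_equal(m$alphas, a_lib / (nu * 10), tolerance = 5e-3)
  expect_equal(m$rho, sv$rho / (nu * 10), tolerance = 5e-3)
})

test_that("dual feasibility, positive offset, and support-vector accounting hold", {
  set.seed(3)
  for (nu in c(0.2, 0.5, 0.9)) {
    X <- matrix(rnorm(15 * 4), 15, 4)
    m <- fit_ocsvm(X, nu = nu, gamma = 0.25)
    expect_equal(sum(m$alphas), 1, tolerance = 1e-8)
    expect_true(all(m$alphas >= -1e-12))
    expect_true(all(m$alphas <= 1 / (nu * 15) + 1e-8))
    expect_gt(m$rho, 0)
    expect_gte(length(m$support_indices), 1)
    expect_true(all(m$margin_indices %in% m$support_indices))
  }
})

test_that("the nu-property bounds training outliers and support vectors", {
  set.seed(21)
  X <- matrix(rnorm(50 * 2), 50, 2)
  for (nu in seq(0.1, 0.9, by = 0.2)) {
    rep_ <- nu_property_report(fit_ocsvm(X, nu = nu, gamma = 0.5))
    expect_lte(rep_$outlier_fraction, nu + 1 / 50)
    expect_gte(rep_$sv_fraction, nu - 1 / 50)
  }
})

test_that("a remote test point is flagged an outlier with decision value near -rho", {
  set.seed(5)
  X <- matrix(rnorm(10 * 3), 10, 3)
  m <- fit_ocsvm(X, nu = 0.3, gamma = 1)
  far <- rep(100, 3)
  rep_ <- decision_values(m, far)
  expect_true(rep_$outlier)
  expect_equal(rep_$decision_value, -m$rho, tolerance = 1e-10)
})

test_that("duplicating every training point leaves decision values unchanged", {
  set.seed(9)
  X <- matrix(rnorm(8 * 3), 8, 3)
  test_pts <- matrix(rnorm(4 * 3), 4, 3)
  m1 <- fit_ocsvm(X, nu = 0.4, gamma = 0.3, tol = 1e-10)
  m2 <- fit_ocsvm(rbind(X, X), nu = 0.4, gamma = 0.3, tol = 1e-10)
  expect_lt(max(abs(decision_values(m1, test_pts)$decision_value -
                      decision_values(m2, test_pts)$decision_value)),
            1e-8)
})

test_that("tiny nu produces no training outliers", {
  set.seed(13)
  X <- matrix(rnorm(10 * 2), 10, 2)
  m <- fit_ocsvm(X, nu = 0.05, gamma = 0.3)
  expect_equal(nu_property_report(m)$outlier_fraction, 0)
})

test_that("JSON serialization round-trips decision values exactly", {
  set.seed(17)
  X <- matrix(rnorm(7 * 3), 7, 3)
  m <- fit_ocsvm(X, nu = 0.3, gamma = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_ocsvm(m, path)
  m2 <- read_ocsvm(path)
  test_pts <- matrix(rnorm(3 * 3), 3, 3)
  expect_equal(decision_values(m2, test_pts)$decision_value,
               decision_values(m, test_pts)$decision_value)
})

test_that("invalid inputs raise typed errors", {
  expect_error(fit_ocsvm(matrix(1, 1, 3), nu = 0.5, gamma = 1),
               class = "ocb_insufficient_data_error")
  expect_error(fit_ocsvm(matrix(c(1, NA, 2, 3), 2, 2), nu = 0.5, gamma = 1),
               class = "ocb_validation_error")
  m <- fit_ocsvm(matrix(rnorm(6), 3, 2), nu = 0.5, gamma = 1)
  expect_error(decision_values(m, matrix(0, 2, 5)), class = "ocb_shape_error")
})

test_that("tidy and glance expose the fitted model in tabular form", {
  set.seed(19)
  X <- matrix(rnorm(10 * 2), 10, 2)
  m <- fit_ocsvm(X, nu = 0.3, gamma = 0.5)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  expect_equal(sum(td$alpha), 1, tolerance = 1e-8)
  gl <- glance(m)
  expect_equal(gl$n_support, length(m$support_indices))
  expect_true(gl$converged)
})
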