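small_grid <- function() {
  search_grid(nu_values = c(0.1, 0.3), gamma_values = 10^seq(-6, -4, by = 1))
}

make_report <- function(ids, f) {
  out <- tibble::tibble(subject_id = ids, decision_value = f, outlier = f < 0)
  class(out) <- c("decision_report", class(out))
  out
}

test_that("permuted labels preserve group sizes and re-form valid pairs", {
  co <- tiny_cohort(seed = 21)
  set.seed(1)
  for (i in 1:20) {
    ptab <- ocboundary:::permute_table(co$table, "control")
    expect_equal(sum(ptab$group == "control"), 6)
    expect_equal(sum(ptab$group == "patient"), 6)
    by_pair <- split(ptab$group, ptab$pair_id)
    expect_true(all(vapply(by_pair, function(g) {
      length(g) == 2 && setequal(g, c("control", "patient"))
    }, logical(1))))
  }
})

test_that("permutation p-values follow the stated counting rule and are reproducible", {
  co <- tiny_cohort(seed = 22)
  fv <- voxel_features(co$volumes, co$mask)
  pt <- permutation_test(fv, co$table, small_grid(), n_permutations = 30,
                         seed = 5, fast_null = TRUE)
  expect_equal(pt$p_tp, sum(pt$draws$tp_pct >= pt$observed_tp) / 30)
  expect_equal(pt$p_tn, sum(pt$draws$tn_pct >= pt$observed_tn) / 30)
  expect_equal(pt$count_tp_ge / pt$n_permutations, pt$p_tp)
  # count/B rule at the granularity reported in practice
  expect_equal(48 / 1000, 0.048)
  pt2 <- permutation_test(fv, co$table, small_grid(), n_permutations = 30,
                          seed = 5, fast_null = TRUE)
  expect_identical(pt$draws, pt2$draws)
  expect_identical(pt$p_tp, pt2$p_tp)
  pt3 <- permutation_test(fv, co$table, small_grid(), n_permutations = 30,
                          seed = 6, fast_null = TRUE)
  expect_false(identical(pt$draws, pt3$draws))
})

test_that("the plus-one estimator and the full-search null are available", {
  co <- tiny_cohort(seed = 23)
  fv <- voxel_features(co$volumes, co$mask)
  pt <- permutation_test(fv, co$table, small_grid(), n_permutations = 9,
                         seed = 2, fast_null = FALSE, plus_one = TRUE)
  expect_equal(pt$p_tp, (pt$count_tp_ge + 1) / 10)
  expect_true(all(pt$draws$tp_pct >= 0 & pt$draws$tp_pct <= 100))
})

test_that("unequal group sizes are rejected for permutation", {
  co <- simulate_cohort(cohort_spec(n_controls = 5, n_patients = 4,
                                    grid_shape = c(6, 6, 6), n_regions = 4,
                                    seed = 2))
  fv <- voxel_features(co$volumes, co$mask)
  expect_error(permutation_test(fv, co$table, small_grid(), 5, 1),
               class = "ocb_config_error")
})

test_that("severity correlation recovers exact anticorrelation and matches a textbook oracle", {
  tab <- tibble::tibble(subject_id = sprintf("p%02d", 1:10),
                        group = "patient",
                        severity = seq(12, 30, by = 2),
                        response = rep(c("responder", "non-responder"), 5))
  rep_ <- make_report(tab$subject_id, -tab$severity)
  sc <- severity_correlation(rep_, tab, "all")
  expect_equal(sc$r, -1)
  expect_equal(sc$n, 10)

  set.seed(9)
  f <- rnorm(10)
  rep2 <- make_report(tab$subject_id, f)
  sc2 <- severity_correlation(rep2, tab, "all")
  or <- pearson_oracle(f, tab$severity)
  expect_equal(sc2$r, or$r, tolerance = 1e-12)
  expect_equal(sc2$p_value, or$p, tolerance = 1e-12)

  sub <- severity_correlation(rep2, tab, "responders")
  expect_equal(sub$n, 5)
  or_sub <- pearson_oracle(f[tab$response == "responder"],
                           tab$severity[tab$response == "responder"])
  expect_equal(sub$r, or_sub$r, tolerance = 1e-12)
})

test_that("degenerate severity inputs raise typed errors", {
  tab <- tibble::tibble(subject_id = c("a", "b", "c"), group = "patient",
                        severity = c(20, 20, 20), response = "responder")
  rep_ <- make_report(tab$subject_id, c(-1, 0, 1))
  expect_error(severity_correlation(rep_, tab, "all"),
               class = "ocb_degenerate_error")
  expect_error(severity_correlation(make_report(c("a", "b"), c(1, 2)),
                                    tab[1:2, ], "all"),
               class = "ocb_validation_error")
})

test_that("the response-by-outlier table counts responders per subgroup", {
  ids <- sprintf("p%d", 1:8)
  # outliers: N N N R ; non-outliers: R R R N
  tab <- tibble::tibble(
    subject_id = ids, group = "patient", severity = 20,
    response = c("non-responder", "non-responder", "non-responder",
                 "responder", "responder", "responder", "responder",
                 "non-responder"))
  rep_ <- make_report(ids, c(-1, -2, -3, -4, 1, 2, 3, 4))
  st <- subgroup_table(rep_, tab)
  expect_equal(st$pct_responders[st$outlier], 25)
  expect_equal(st$pct_responders[!st$outlier], 75)
  expect_equal(st$n, c(4L, 4L))
})

test_that("empty outlier cells are reported as missing, not zero", {
  ids <- sprintf("p%d", 1:4)
  tab <- tibble::tibble(subject_id = ids, group = "patient", severity = 20,
                        response = c("responder", "responder",
                                     "non-responder", "responder"))
  all_out <- subgroup_table(make_report(ids, rep(-1, 4)), tab)
  expect_equal(all_out$n[!all_out$outlier], 0L)
  expect_true(is.na(all_out$pct_responders[!all_out$outlier]))
  none_out <- subgroup_table(make_report(ids, rep(1, 4)), tab)
  expect_true(is.na(none_out$pct_responders[none_out$outlier]))
  # patients without response labels are refused
  tab_bad <- tab
  tab_bad$response[1] <- "not-applicable"
  expect_error(subgroup_table(make_report(ids, rep(1, 4)), tab_bad),
               class = "ocb_validation_error")
})
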