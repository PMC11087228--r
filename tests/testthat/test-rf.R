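coded_features <- function(n = 128, k = 7) design_matrix(full_factorial(k))

test_that("forest fits are deterministic under a seed", {
  X <- coded_features()
  y <- 0.1 + 0.05 * X[, 2] + rnorm(128, 0, 0.01)
  cfg <- ml_run_config(seed = 5)
  r1 <- rf_fit_and_score(X, y, cfg, n_estimators = 25L)
  r2 <- rf_fit_and_score(X, y, cfg, n_estimators = 25L)
  expect_identical(r1$cv_r2, r2$cv_r2)
  expect_identical(predict(r1$model, X), predict(r2$model, X))
  r3 <- rf_fit_and_score(X, y, ml_run_config(seed = 6), n_estimators = 25L)
  expect_false(identical(r1$cv_r2, r3$cv_r2))
})

test_that("a forest learns a one-factor step function", {
  X <- coded_features()
  y <- as.numeric(X[, "C3H"] == 1)  # response = one feature exactly
  res <- rf_fit_and_score(X, y, ml_run_config(seed = 1), n_estimators = 50L)
  expect_gt(res$cv_r2, 0.9)
})

test_that("degenerate and no-CV modes are handled", {
  X <- coded_features(16, 4)[1:16, 1:4]
  res <- rf_fit_and_score(X, rep(2, 16), ml_run_config(seed = 1),
                          n_estimators = 10L)
  expect_true(res$degenerate)
  expect_lte(res$cv_r2, 0)

  y <- 1 + 0.1 * X[, 1] + rnorm(16, 0, 0.01)
  nocv <- rf_fit_and_score(X, y, ml_run_config(folds = NULL, seed = 1),
                           n_estimators = 25L)
  expect_null(nocv$fold_r2)
  expect_gt(nocv$cv_r2, 0.5)  # training fit
  expect_error(rf_fit_and_score(X[1:5, ], y[1:5],
                                ml_run_config(folds = 10, seed = 1)),
               "fewer observations")
})

test_that("the default grid is the published one, deduplicated on expansion", {
  g <- default_rf_grid()
  expect_equal(prod(lengths(g)), 81)  # 3*3*3*3 as printed
  cells <- expand.grid(lapply(g, function(v) v[!duplicated(v)]))
  expect_equal(nrow(cells), 54)  # duplicate 200 estimators collapse
  expect_setequal(unique(cells$n_estimators), c(100L, 200L))
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  X <- coded_features(8, 3)[1:8, 1:3]
  set.seed(2)
  y <- 0.5 + 0.2 * X[, 1] + rnorm(8, 0, 0.02)
  one <- rf_grid_search(X, y, grid = list(n_estimators = 10L,
                                          max_depth = NA_integer_,
                                          min_samples_split = 2L,
                                          min_samples_leaf = 1L), seed = 3)
  expect_equal(one$best$n_estimators, 10L)
  expect_equal(nrow(one$scores), 1L)

  # two identical cells -> first in grid order wins
  two <- rf_grid_search(X, y, grid = list(n_estimators = c(10L, 10L),
                                          max_depth = c(NA_integer_, NA_integer_),
                                          min_samples_split = 2L,
                                          min_samples_leaf = 1L), seed = 3)
  expect_equal(nrow(two$scores), 1L)  # dedup collapses them outright
})

test_that("top-k frequencies respect the R2 filter and tie rules", {
  lib <- shipped_library()
  truth_model <- lib$truth  # numeric predictions = ground truth
  reps <- list(list(model = truth_model, cv_r2 = 0.95))
  f <- top_k_frequency(reps, lib, k = 2, r2_filter = 0.6)
  expect_equal(nrow(f), 2L)
  expect_equal(f$frequency, c(1, 1))
  opt_codes <- apply(true_optima(lib), 1, function(r)
    paste(ifelse(r > 0, "+", "-"), collapse = ""))
  expect_setequal(f$strain, opt_codes)

  # failing repeats contribute nothing
  reps2 <- list(list(model = truth_model, cv_r2 = 0.95),
                list(model = rev(truth_model), cv_r2 = 0.1))
  f2 <- top_k_frequency(reps2, lib, k = 2, r2_filter = 0.6)
  expect_equal(attr(f2, "n_filtered"), 1L)
  expect_equal(attr(f2, "n_repeats"), 1L)
  expect_equal(f2$frequency, c(1, 1))
  f_none <- top_k_frequency(list(list(model = truth_model, cv_r2 = 0.2)),
                            lib, k = 2, r2_filter = 0.6)
  expect_equal(nrow(f_none), 0L)
  expect_equal(attr(f_none, "n_filtered"), 1L)
})

test_that("linear pipeline beats the forest at recovering the optima", {
  # scaled-down mirror of the published comparison: 20 seeded repeats of the
  # 16-run design at 20% noise; frequency mass on the true optimal pair
  lib <- shipped_library()
  opt_codes <- apply(true_optima(lib), 1, function(r)
    paste(ifelse(r > 0, "+", "-"), collapse = ""))
  d <- catalog_design("IV")
  idx <- match(apply(design_matrix(d), 1, paste, collapse = ","),
               apply(lib$strains, 1, paste, collapse = ","))
  lin_sets <- list(); rf_reps <- list()
  set.seed(30)
  for (i in 1:20) {
    y <- lib$truth[idx] * (1 + matrix(rnorm(48, 0, 0.2), 16, 3))
    fit <- fit_ols(build_model_matrix(d), y)
    lin_sets[[i]] <- candidate_optima(significant_effects(fit, 0.05),
                                      colnames(lib$strains))
    Xr <- design_matrix(d)[rep(1:16, 3), ]
    rf <- rf_fit_and_score(Xr, as.numeric(y), ml_run_config(seed = 100 + i),
                           n_estimators = 30L)
    rf_reps[[i]] <- list(model = rf$model, cv_r2 = rf$cv_r2)
  }
  lin_freq <- selection_frequency(lin_sets, colnames(lib$strains))
  rf_freq <- top_k_frequency(rf_reps, lib, k = 2, r2_filter = 0.6)
  mass <- function(f) sum(f$frequency[f$strain %in% opt_codes])
  expect_gt(mass(lin_freq), mass(rf_freq))
})
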