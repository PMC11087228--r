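test_that("model matrix has deterministic terms and products", {
  mm <- build_model_matrix(full_factorial(7))
  expect_equal(ncol(mm), 29L)  # 1 + 7 + 21
  mm2 <- build_model_matrix(matrix(c(-1, 1, -1, -1), 2, 2,
                                   dimnames = list(NULL, c("A", "B"))))
  expect_equal(unname(mm2[, "A:B"]), c(1, -1))
  # full factorial: all columns mutually orthogonal
  g <- crossprod(build_model_matrix(full_factorial(4)))
  expect_equal(g - diag(diag(g)), matrix(0, ncol(g), ncol(g)),
               ignore_attr = TRUE)
})

test_that("OLS interpolates noiseless truth exactly", {
  d <- full_factorial(2, c("F1", "F2"))
  y <- effect_truth(d, 2, c(F1 = 3, F2 = -1))
  fit <- fit_ols(build_model_matrix(d, include_2fi = FALSE), y)
  expect_equal(unname(fit$coefficients),
               c(2, 3, -1), tolerance = 1e-12)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-12)
})

test_that("OLS matches the normal-equation oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    X <- cbind(1, matrix(rnorm(20 * 4), 20, 4))
    colnames(X) <- c("(Intercept)", paste0("F", 1:4))
    y <- rnorm(20)
    fit <- fit_ols(X, y)
    oracle <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$coefficients), as.numeric(oracle),
                 tolerance = 1e-10)
  }
})

test_that("standard errors and p-values match lm", {
  set.seed(7)
  d <- catalog_design("IV")
  y <- effect_truth(d, 0.05, stats::setNames(runif(7, -0.01, 0.01),
                                             d$factor_names))
  y <- cbind(y, y, y) * (1 + matrix(rnorm(48, 0, 0.2), 16, 3))
  mm <- build_model_matrix(d, include_2fi = FALSE)
  fit <- fit_ols(mm, y)
  df <- data.frame(y = as.numeric(y), mm[rep(1:16, 3), -1])
  lfit <- summary(stats::lm(y ~ ., data = df))$coefficients
  expect_equal(unname(fit$coefficients), unname(lfit[, 1]), tolerance = 1e-9)
  expect_equal(unname(fit$std_errors), unname(lfit[, 2]), tolerance = 1e-9)
  expect_equal(unname(fit$p_values), unname(lfit[, 4]), tolerance = 1e-9)
})

test_that("aliased columns are dropped onto retained class representatives", {
  d <- catalog_design("IV")
  mm <- build_model_matrix(d)
  y <- rnorm(16)
  fit <- fit_ols(mm, y)
  # rank of the 16-run ME+2FI matrix: intercept + 7 ME + 7 2FI classes + 1
  expect_equal(length(fit$terms), 15L)
  expect_equal(length(fit$dropped_terms), 14L)
  a <- alias_structure(d)
  # each dropped 2FI points at the earliest retained member of its class
  for (nm in names(fit$dropped_terms)) {
    rep_ <- fit$dropped_terms[[nm]]
    if (is.na(rep_)) next
    cls <- NULL
    for (cl in a$alias_classes) if (nm %in% cl) cls <- cl
    expect_true(rep_ %in% cls)
  }
  # mirrors lm's aliased-NA behaviour: same retained set
  df <- data.frame(y = y, mm[, -1])
  lfit <- stats::lm(y ~ ., data = df)
  expect_equal(sum(!is.na(stats::coef(lfit))), length(fit$terms))
})

test_that("replicates stack into residual degrees of freedom", {
  d <- catalog_design("III")  # saturated: 8 runs, 8 ME-model terms
  y1 <- effect_truth(d, 1, stats::setNames(rep(0.1, 7), d$factor_names))
  mm <- build_model_matrix(d, include_2fi = FALSE)
  fit1 <- fit_ols(mm, y1)
  expect_equal(fit1$residual_df, 0L)
  expect_true(all(is.na(fit1$p_values)))
  expect_error(significant_effects(fit1), "unavailable")
  fit3 <- fit_ols(mm, cbind(y1, y1 * 1.01, y1 * 0.99))
  expect_equal(fit3$residual_df, 16L)
  expect_false(anyNA(fit3$p_values))
})

test_that("noiseless effect recovery matches the word algebra", {
  me <- c(TAL = 0, C3H = 0.031, COMT = -0.004, FCS = -0.03,
          CCOAOMT = -0.002, DCS = 0.008, CURS = 0.001)
  fi <- c("C3H:FCS" = -0.012, "COMT:CURS" = 0.003, "C3H:COMT" = -0.005)
  d64 <- catalog_design("V")
  y64 <- effect_truth(d64, 0.05, me, fi)
  f64 <- fit_ols(build_model_matrix(d64), y64)
  expect_equal(f64$coefficients[names(me)], me, tolerance = 1e-10)
  for (nm in names(fi)) {
    expect_equal(unname(f64$coefficients[nm]), unname(fi[nm]),
                 tolerance = 1e-10)
  }
  other_fi <- setdiff(grep(":", f64$terms, value = TRUE), names(fi))
  expect_equal(max(abs(f64$coefficients[other_fi])), 0, tolerance = 1e-10)

  # 16-run: MEs exact; each retained 2FI accumulates its alias class
  d16 <- catalog_design("IV")
  y16 <- effect_truth(d16, 0.05, me, fi)
  f16 <- fit_ols(build_model_matrix(d16), y16)
  expect_equal(f16$coefficients[names(me)], me, tolerance = 1e-10)
  a <- alias_structure(d16)
  for (cl in Filter(function(cl) any(grepl(":", cl)), a$alias_classes)) {
    retained <- intersect(f16$terms, cl)
    if (!length(retained)) next
    m16 <- build_model_matrix(d16)
    expected <- sum(vapply(intersect(names(fi), cl), function(nm) {
      sgn <- sum(m16[, retained] * m16[, nm]) / nrow(m16)  # +/-1 within class
      sgn * fi[[nm]]
    }, numeric(1)))
    expect_equal(unname(f16$coefficients[retained]), expected,
                 tolerance = 1e-10)
  }
})

test_that("significance report obeys threshold semantics", {
  d <- catalog_design("V")
  set.seed(5)
  me <- c(TAL = 0, C3H = 0.03, COMT = -0.004, FCS = -0.03,
          CCOAOMT = -0.002, DCS = 0.008, CURS = 0.004)
  y <- effect_truth(d, 0.05, me)
  y <- cbind(y, y, y) * (1 + matrix(rnorm(64 * 3, 0, 0.05), 64, 3))
  fit <- fit_ols(build_model_matrix(d, include_2fi = FALSE), y)
  rep99 <- significant_effects(fit, alpha = 0.999999)
  expect_setequal(names(rep99$signs), d$factor_names)  # all testable MEs in
  expect_equal(rep99$signs[["FCS"]], -1)
  expect_equal(rep99$signs[["C3H"]], 1)
  tiny <- significant_effects(fit, alpha = 1e-12)
  expect_true(all(fit$p_values[tiny$significant_terms] < 1e-12))
})

test_that("main-effect predictions ignore interaction coefficients", {
  d <- catalog_design("IV")
  me <- stats::setNames(c(0, 0.02, -0.01, -0.02, 0, 0.01, 0.005),
                        d$factor_names)
  y <- effect_truth(d, 0.05, me)
  fit <- fit_ols(build_model_matrix(d), y)
  full <- full_factorial(7)
  pred <- predict_main_effects(fit, full)
  expect_equal(pred, effect_truth(full, 0.05, me), tolerance = 1e-9)
  # perturbing 2FI coefficients leaves predictions unchanged
  fit2 <- fit
  fis <- grep(":", fit2$terms, value = TRUE)
  fit2$coefficients[fis] <- fit2$coefficients[fis] + 99
  expect_equal(predict_main_effects(fit2, full), pred)
  # flipping one factor changes the prediction by exactly 2 * ME
  s1 <- design_matrix(full)[1, , drop = FALSE]
  s2 <- s1; s2[1, "C3H"] <- -s2[1, "C3H"]
  expect_equal(abs(predict_main_effects(fit, s1) -
                     predict_main_effects(fit, s2)),
               2 * abs(me[["C3H"]]), tolerance = 1e-9)
})

test_that("coefficient of determination matches hand computations", {
  expect_equal(coefficient_of_determination(c(1, 2, 3), c(1, 2, 3)), 1)
  truth <- c(1, 2, 3, 4)
  expect_equal(coefficient_of_determination(rep(mean(truth), 4), truth), 0)
  expect_equal(coefficient_of_determination(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_lt(coefficient_of_determination(c(9, 9, 9), c(1, 2, 3)), 0)
})

test_that("best subset recovers a single active factor at every size", {
  d <- full_factorial(4)
  y <- effect_truth(d, 1, c(F2 = 0.5))
  mm <- build_model_matrix(d, include_2fi = FALSE)
  for (k in 1:3) {
    bs <- best_subset(mm, y, max_terms = k)
    expect_true("F2" %in% attr(bs, "selected_terms"))
    expect_equal(unname(bs$coefficients[["F2"]]), 0.5, tolerance = 1e-10)
  }
  bs0 <- best_subset(mm, y, max_terms = 0)
  expect_equal(attr(bs0, "selected_terms"), character(0))
  expect_equal(unname(bs0$coefficients[["(Intercept)"]]), mean(y))
  expect_error(best_subset(build_model_matrix(d), y, max_terms = 9), "at most")
})

test_that("type-I error of a null factor is calibrated", {
  # truth does not depend on TAL; reject at alpha = 0.05 under 20% noise
  d <- catalog_design("IV")
  me <- stats::setNames(c(0, 0.03, -0.005, -0.03, -0.002, 0.008, 0.005),
                        d$factor_names)
  y0 <- effect_truth(d, 0.05, me)
  mm <- build_model_matrix(d, include_2fi = FALSE)
  n_rep <- 400L
  set.seed(11)
  rejections <- sum(vapply(seq_len(n_rep), function(i) {
    y <- cbind(y0, y0, y0) * (1 + matrix(rnorm(48, 0, 0.2), 16, 3))
    fit_ols(mm, y)$p_values[["TAL"]] < 0.05
  }, logical(1)))
  band <- qbinom(c(0.005, 0.995), n_rep, 0.05)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})
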