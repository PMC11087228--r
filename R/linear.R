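#' Build the effect model matrix
#'
#' Columns for the intercept, each coded main effect and (optionally) each
#' two-factor interaction, in the deterministic order of [effect_terms()].
#' Interaction columns are elementwise products of their parent main-effect
#' columns.
#'
#' @param design A `doe_design` (or coded matrix).
#' @param include_2fi Include two-factor interaction columns?
#' @return Numeric matrix with `1 + k (+ k(k-1)/2)` named columns.
#' @export
build_model_matrix <- function(design, include_2fi = TRUE) {
  m <- design_matrix(design)
  if (is.null(colnames(m))) colnames(m) <- default_factor_names(ncol(m))
  effect_columns(m, include_2fi)
}

#' Ordinary least squares with alias-aware column dropping
#'
#' Fits the effect model by OLS. Replicate observations are stacked: a
#' response matrix with one row per run and one column per replicate expands
#' the model matrix rows accordingly, so replicates contribute residual
#' degrees of freedom. Rank deficiency (aliased terms) is resolved by a
#' deterministic scan in term order: a column numerically inside the span of
#' the already-retained columns is dropped, and the earliest retained member
#' of its alias class represents it — mirroring the `NA` behaviour of R's
#' `lm` for aliased coefficients.
#'
#' @param model_matrix From [build_model_matrix()].
#' @param response Numeric vector (one value per run) or matrix
#'   (runs x replicates).
#' @param drop_tol Relative tolerance for declaring a column spanned.
#' @return An object of class `linear_fit`: coefficients, std_errors,
#'   p_values (per retained term), `dropped_terms` (named character vector:
#'   dropped term -> retained representative, NA if no single representative),
#'   `residual_df`, `r_squared_train`, `fitted`, `residuals`.
#' @export
fit_ols <- function(model_matrix, response, drop_tol = 1e-8) {
  X <- as.matrix(model_matrix)
  y <- as.matrix(response)
  if (nrow(y) != nrow(X)) stop("response rows must match model matrix rows")
  n_reps <- ncol(y)
  if (n_reps > 1L) {
    X <- X[rep(seq_len(nrow(X)), times = n_reps), , drop = FALSE]
  }
  yv <- as.numeric(y)

  # deterministic greedy scan for a linearly independent column set
  keep <- integer(0)
  Q <- matrix(0, nrow(X), 0)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    r <- if (ncol(Q)) v - Q %*% crossprod(Q, v) else v
    if (sqrt(sum(r^2)) > drop_tol * max(sqrt(sum(v^2)), 1)) {
      keep <- c(keep, j)
      Q <- cbind(Q, r / sqrt(sum(r^2)))
    }
  }
  if (length(keep) == 0L) stop("model matrix has no usable columns")
  dropped <- setdiff(seq_len(ncol(X)), keep)

  # representative of each dropped term: earliest retained column identical
  # up to sign, if one exists
  rep_of <- character(length(dropped))
  if (length(dropped)) {
    cs <- column_cosine(X[, c(keep, dropped), drop = FALSE])
    for (i in seq_along(dropped)) {
      hit <- which(abs(abs(cs[seq_along(keep), length(keep) + i]) - 1) < 1e-8)
      rep_of[i] <- if (length(hit)) colnames(X)[keep[hit[1]]] else NA_character_
    }
    names(rep_of) <- colnames(X)[dropped]
  }

  Xk <- X[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xk, yv)
  coefs <- fit$coefficients
  res <- fit$residuals
  df <- length(yv) - length(keep)
  rss <- sum(res^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtX_inv <- chol2inv(chol(crossprod(Xk)))
  se <- if (df > 0) sqrt(diag(XtX_inv) * sigma2) else rep(NA_real_, length(keep))
  tval <- coefs / se
  pval <- if (df > 0) 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
          else rep(NA_real_, length(keep))
  tss <- sum((yv - mean(yv))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  structure(list(coefficients = stats::setNames(coefs, colnames(Xk)),
                 std_errors = stats::setNames(se, colnames(Xk)),
                 p_values = stats::setNames(pval, colnames(Xk)),
                 dropped_terms = rep_of,
                 residual_df = df,
                 r_squared_train = r2,
                 fitted = fit$fitted.values,
                 residuals = res,
                 terms = colnames(Xk)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear effect fit:", length(x$coefficients), "terms, residual df",
      x$residual_df, "\n")
  tab <- fit_table(x)
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}

#' ANOVA-style coefficient table
#'
#' @param fit A [fit_ols()] result.
#' @return data.frame with term, estimate, std_error, p_value and, for
#'   aliased (dropped) terms, their retained representative.
#' @export
fit_table <- function(fit) {
  tab <- data.frame(term = fit$terms,
                    estimate = as.numeric(fit$coefficients),
                    std_error = as.numeric(fit$std_errors),
                    p_value = as.numeric(fit$p_values),
                    alias_of = NA_character_)
  if (length(fit$dropped_terms)) {
    tab <- rbind(tab, data.frame(term = names(fit$dropped_terms),
                                 estimate = NA_real_, std_error = NA_real_,
                                 p_value = NA_real_,
                                 alias_of = unname(fit$dropped_terms)))
  }
  tab
}

#' Significant terms at a threshold
#'
#' @param fit A [fit_ols()] result with available p-values.
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `significance_report`: `alpha`,
#'   `significant_terms`, and `signs` (+1/-1) of the significant main
#'   effects.
#' @export
significant_effects <- function(fit, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (all(is.na(fit$p_values))) {
    stop("p-values unavailable (saturated fit with zero residual df)")
  }
  sig <- fit$terms[!is.na(fit$p_values) & fit$p_values < alpha]
  me <- sig[!grepl(":", sig) & sig != "(Intercept)"]
  structure(list(alpha = alpha,
                 significant_terms = sig,
                 signs = stats::setNames(sign(fit$coefficients[me]), me)),
            class = "significance_report")
}

#' Main-effect-only predictions
#'
#' Predicts the response of coded strains from the intercept and main-effect
#' coefficients alone; interaction coefficients are excluded by definition
#' (they cannot be attributed in low-resolution designs).
#'
#' @param fit A [fit_ols()] result.
#' @param strains Coded matrix (or `doe_design`), columns named as the fit's
#'   main-effect terms.
#' @return Numeric vector of predictions, one per strain.
#' @export
predict_main_effects <- function(fit, strains) {
  m <- design_matrix(strains)
  me <- fit$terms[!grepl(":", fit$terms) & fit$terms != "(Intercept)"]
  beta0 <- if ("(Intercept)" %in% fit$terms)
    fit$coefficients[["(Intercept)"]] else 0
  as.numeric(beta0 + m[, me, drop = FALSE] %*% fit$coefficients[me])
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of predictions against a reference; can be negative
#' when predictions are worse than the reference mean.
#'
#' @param predicted,truth Equal-length numeric vectors.
#' @return Scalar R-squared.
#' @export
coefficient_of_determination <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 2)
  1 - sum((truth - predicted)^2) / sum((truth - mean(truth))^2)
}

#' Exhaustive best-subset regression
#'
#' Evaluates every subset of the non-intercept terms up to `max_terms`
#' (intercept always included) and returns the fit maximizing adjusted
#' R-squared, with the full search log. Used as the probe for what partially
#' aliased screening designs can still reveal.
#'
#' @param model_matrix From [build_model_matrix()].
#' @param response As in [fit_ols()].
#' @param max_terms Largest subset size (enumeration budget: at most 2e5
#'   subsets, and `max_terms` at most 8).
#' @param criterion Only `"adj_r_squared"` is implemented.
#' @return A `linear_fit` for the winning subset, with attributes
#'   `search_log` (data.frame: subset, size, criterion value) and
#'   `selected_terms`.
#' @export
best_subset <- function(model_matrix, response, max_terms,
                        criterion = "adj_r_squared") {
  criterion <- match.arg(criterion)
  if (max_terms > 8) stop("max_terms must be at most 8 (exhaustive search)")
  X <- as.matrix(model_matrix)
  has_int <- "(Intercept)" %in% colnames(X)
  cand <- setdiff(colnames(X), "(Intercept)")
  n_subsets <- sum(choose(length(cand), 0:max_terms))
  if (n_subsets > 2e5) {
    stop("subset enumeration budget exceeded (", n_subsets,
         " subsets); reduce max_terms")
  }
  y <- as.matrix(response)
  n_reps <- ncol(y)

  best <- NULL; best_score <- -Inf
  log_subset <- character(0); log_size <- integer(0); log_score <- numeric(0)
  for (size in 0:max_terms) {
    sets <- if (size == 0) list(character(0)) else
      utils::combn(cand, size, simplify = FALSE)
    for (s in sets) {
      cols <- c(if (has_int) "(Intercept)", s)
      f <- fit_ols(X[, cols, drop = FALSE], y)
      n <- nrow(X) * n_reps
      p_used <- length(f$terms)
      score <- if (f$residual_df > 0)
        1 - (1 - f$r_squared_train) * (n - 1) / f$residual_df else -Inf
      log_subset <- c(log_subset, paste(s, collapse = "+"))
      log_size <- c(log_size, size)
      log_score <- c(log_score, score)
      if (score > best_score + 1e-12) {  # strict improvement: first-wins ties
        best_score <- score
        best <- f
        attr(best, "selected_terms") <- s
      }
    }
  }
  attr(best, "search_log") <- data.frame(subset = log_subset, size = log_size,
                                         adj_r_squared = log_score)
  best
}
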