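#' Campaign configuration
#'
#' Describes a full comparison campaign: which designs to run, at which noise
#' levels, how many factor-to-column permutations, which missing-row
#' scenarios, and the matched random baselines. Every stochastic component
#' derives its seed from `seed`.
#'
#' @param designs Character vector of design cells: any of `"FF"` (full
#'   factorial), `"V"`, `"IV"`, `"III"`, `"PB"` (see [catalog_design()]).
#' @param noise_levels Relative noise levels (sigma of the multiplicative
#'   Gaussian error).
#' @param n_reps Replicates per strain.
#' @param n_permutations Permutations of the factor-to-column assignment per
#'   design cell; `NULL` enumerates all `k!` (the published setting; minutes
#'   of runtime), an integer samples that many with the campaign seed.
#' @param missing_rows Named list: design name -> vector of missing-strain
#'   counts (default: the published scenarios for "V" and "IV").
#' @param n_missing_permutations Random permutations per missing-row scenario.
#' @param random_baselines Match every design cell with random sampling of
#'   the same size and repeat count?
#' @param alpha ANOVA significance threshold.
#' @param seed Campaign master seed.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(designs = c("V", "IV", "III", "PB"),
                            noise_levels = c(0.05, 0.20),
                            n_reps = 3L,
                            n_permutations = NULL,
                            missing_rows = list(V = c(1, 2, 5, 10),
                                                IV = c(1, 2, 3, 5)),
                            n_missing_permutations = 100L,
                            random_baselines = TRUE,
                            alpha = 0.05,
                            seed = 1L) {
  stopifnot(all(designs %in% c("FF", "V", "IV", "III", "PB")),
            all(noise_levels >= 0), n_reps >= 1, alpha > 0, alpha < 1)
  missing_rows <- missing_rows[intersect(names(missing_rows), designs)]
  structure(list(designs = designs, noise_levels = noise_levels,
                 n_reps = as.integer(n_reps),
                 n_permutations = n_permutations,
                 missing_rows = missing_rows,
                 n_missing_permutations = as.integer(n_missing_permutations),
                 random_baselines = isTRUE(random_baselines),
                 alpha = alpha, seed = as.integer(seed)),
            class = "campaign_config")
}

campaign_design <- function(name) {
  if (name == "FF") full_factorial(7, PATHWAY_ENZYMES) else catalog_design(name)
}

# Derive a stream of per-repeat seeds below 2^31 from the master seed.
derive_seeds <- function(seed, n, stream) {
  with_seed(seed + stream, sample.int(.Machine$integer.max - 1L, n))
}

# Select the full-library rows matching a design's runs (by coded string).
match_runs <- function(design, library) {
  idx <- match(strain_codes(design_matrix(design)),
               strain_codes(library$strains))
  if (anyNA(idx)) stop("design contains runs outside the library")
  idx
}

# One analysis repeat: select -> add noise -> fit -> significance ->
# candidates -> ME-only R2 on the full factorial.
analyse_selection <- function(design, library, sigma, n_reps, alpha, seed) {
  idx <- match_runs(design, library)
  truth <- library$truth[idx]
  eps <- with_seed(seed, matrix(stats::rnorm(length(idx) * n_reps, 0, sigma),
                                length(idx), n_reps))
  y <- truth * (1 + eps)
  mm <- build_model_matrix(design_matrix(design))
  fit <- fit_ols(mm, y)
  rep_report <- significant_effects(fit, alpha)
  cand <- candidate_optima(rep_report, colnames(library$strains))
  pred <- predict_main_effects(fit, library$strains)
  list(significant_me = names(rep_report$signs),
       signs = rep_report$signs,
       coefficients = fit$coefficients[intersect(names(fit$coefficients),
                                                 colnames(library$strains))],
       r2 = coefficient_of_determination(pred, library$truth),
       candidates = cand)
}

aggregate_cell <- function(repeats, factor_names) {
  n <- length(repeats)
  sig_freq <- vapply(factor_names, function(f)
    100 * mean(vapply(repeats, function(r) f %in% r$significant_me,
                      logical(1))), numeric(1))
  coef_mat <- t(vapply(repeats, function(r) {
    out <- stats::setNames(rep(NA_real_, length(factor_names)), factor_names)
    out[names(r$coefficients)] <- r$coefficients
    out
  }, numeric(length(factor_names))))
  r2 <- vapply(repeats, `[[`, numeric(1), "r2")
  list(n_repeats = n,
       me_significance_pct = sig_freq,
       coef_mean = colMeans(coef_mat, na.rm = TRUE),
       coef_sd = apply(coef_mat, 2, stats::sd, na.rm = TRUE),
       r2_mean = mean(r2), r2_sd = stats::sd(r2),
       selection = selection_frequency(lapply(repeats, `[[`, "candidates"),
                                       factor_names))
}

#' Run a design-comparison campaign
#'
#' Simulates the noiseless full factorial library once, then for every
#' configured design cell and noise level repeats the analysis pipeline
#' (select runs, draw fresh replicates, fit the ME+2FI model, test
#' significance, derive candidate optima, score ME-only predictions on the
#' full library) over permutations of the factor-to-column assignment, plus
#' matched random baselines and missing-row scenarios. Fully deterministic
#' given the model and the config seed.
#'
#' @param model A [pathway_model()]; ignored when `library` is supplied.
#' @param config A [campaign_config()].
#' @param library Optional precomputed noiseless full factorial
#'   [simulate_library()] result.
#' @return An object of class `campaign_result`: list with `cells` (named
#'   `design.noise`; each holds `n_repeats`, `me_significance_pct`,
#'   `coef_mean`, `coef_sd`, `r2_mean`, `r2_sd` and the strain `selection`
#'   frequency table), `truth_optima`, `library`, `config`.
#' @export
run_campaign <- function(model = build_default_model(),
                         config = campaign_config(), library = NULL) {
  if (is.null(library)) library <- simulate_library(model, full_factorial(7))
  factor_names <- colnames(library$strains)
  k <- length(factor_names)
  cells <- list()
  stream <- 0L

  run_cell <- function(design_of_repeat, n_repeats, sigma) {
    stream <<- stream + 1L
    seeds <- derive_seeds(config$seed, n_repeats, stream)
    reps <- lapply(seq_len(n_repeats), function(i)
      analyse_selection(design_of_repeat(i), library, sigma, config$n_reps,
                        config$alpha, seeds[i]))
    cell <- aggregate_cell(reps, factor_names)
    cell$seeds <- seeds  # traceability: one noise seed per repeat
    cell
  }

  for (name in config$designs) {
    base <- campaign_design(name)
    perms <- if (name == "FF") list(seq_len(k)) else if
      (is.null(config$n_permutations)) all_permutations(k) else {
        stream <- stream + 1L
        with_seed(config$seed + stream,
                  replicate(config$n_permutations, sample.int(k),
                            simplify = FALSE))
      }
    for (sigma in config$noise_levels) {
      cells[[paste(name, sigma, sep = ".")]] <-
        run_cell(function(i) permute_columns(base, perms[[i]]),
                 length(perms), sigma)
      if (config$random_baselines && name != "FF") {
        stream <- stream + 1L
        sub_seeds <- derive_seeds(config$seed, length(perms), stream)
        cells[[paste0("random", nrow(base$matrix), ".", sigma)]] <-
          run_cell(function(i) random_subset(k, nrow(base$matrix),
                                             sub_seeds[i], factor_names),
                   length(perms), sigma)
      }
    }
    for (n_miss in config$missing_rows[[name]]) {
      stream <- stream + 1L
      mperm_seeds <- derive_seeds(config$seed, config$n_missing_permutations,
                                  stream)
      for (sigma in config$noise_levels) {
        cells[[paste(name, "miss", n_miss, sigma, sep = ".")]] <-
          run_cell(function(i) {
            p <- with_seed(mperm_seeds[i], sample.int(k))
            drop_rows(permute_columns(base, p), n_miss, mperm_seeds[i] + 1L)
          }, config$n_missing_permutations, sigma)
      }
    }
  }

  structure(list(cells = cells, truth_optima = true_optima(library),
                 library = library, config = config),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat("Campaign:", length(x$cells), "cells over",
      nrow(x$library$strains), "ground-truth strains\n")
  print(summarize_me_frequencies(x), digits = 3)
  invisible(x)
}

#' Main-effect significance frequency table
#'
#' One row per campaign cell, one column per enzyme, cells the percentage of
#' repeats in which the enzyme's main effect was significant.
#'
#' @param result A [run_campaign()] result.
#' @return data.frame with columns `cell`, `n_repeats`, then one per factor.
#' @export
summarize_me_frequencies <- function(result) {
  factor_names <- colnames(result$library$strains)
  rows <- lapply(names(result$cells), function(nm) {
    cell <- result$cells[[nm]]
    cbind(data.frame(cell = nm, n_repeats = cell$n_repeats),
          as.data.frame(as.list(cell$me_significance_pct)))
  })
  do.call(rbind, rows)
}

#' Two-stage sequential experiment plan
#'
#' Implements the follow-up strategy: after a screening stage fixes the
#' dominant factors at the signs of their coefficients, the second stage is a
#' full factorial over the remaining free factors (equivalently, the highest
#' resolution fraction available for them) with the fixed factors held
#' constant.
#'
#' @param stage1 The screening-stage `doe_design`.
#' @param fixed_factors Named vector of +1/-1 signs for the factors fixed
#'   after stage 1 (may be empty).
#' @return List: `stage2` (a `doe_design` over all k factors with fixed
#'   columns constant), `total_experiments` (stage-1 runs + stage-2 runs).
#' @export
#' @examples
#' plan <- sequential_plan(catalog_design("IV"),
#'                         c(C3H = 1, FCS = -1, COMT = -1))
#' plan$total_experiments  # 32
sequential_plan <- function(stage1, fixed_factors = numeric()) {
  factor_names <- colnames(design_matrix(stage1))
  if (!all(names(fixed_factors) %in% factor_names)) {
    stop("fixed_factors must name factors of stage1")
  }
  stopifnot(all(fixed_factors %in% c(-1, 1)))
  free <- setdiff(factor_names, names(fixed_factors))
  n2 <- 2^length(free)
  m <- matrix(NA_real_, n2, length(factor_names),
              dimnames = list(NULL, factor_names))
  for (f in names(fixed_factors)) m[, f] <- fixed_factors[[f]]
  if (length(free)) {
    m[, free] <- design_matrix(full_factorial(length(free), free))
  }
  stage2 <- new_design(m, factor_names,
                       list(type = "derived", parent = "sequential_stage2",
                            fixed = fixed_factors))
  list(stage2 = stage2,
       total_experiments = nrow(design_matrix(stage1)) + n2)
}
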