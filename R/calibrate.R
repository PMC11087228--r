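#' Calibration properties of a parameter set
#'
#' The three structural properties the shipped model must satisfy, evaluated
#' on the noiseless full factorial library:
#' \describe{
#'   \item{(a) optimal pair}{the tied argmax strains are exactly the pair
#'     combining high C3H, DCS and CURS with low FCS, COMT and CCOAOMT, with
#'     TAL at either level;}
#'   \item{(b) TAL silent}{the full-factorial ME+2FI fit gives TAL's main
#'     effect a p-value above `alpha`, while the other six main effects are
#'     below it;}
#'   \item{(c) C3H dominant}{C3H has the largest absolute main effect.}
#' }
#'
#' @param model A [pathway_model()].
#' @param alpha Significance threshold.
#' @param library Optional precomputed noiseless full factorial library.
#' @return List with logical `optimal_pair`, `tal_insignificant`,
#'   `c3h_largest`, overall `ok`, and supporting `details`.
#' @export
calibration_properties <- function(model, alpha = 0.05, library = NULL) {
  if (is.null(library)) {
    library <- simulate_library(model, full_factorial(7))
  }
  optima <- true_optima(library)
  target <- expected_optimal_pair()
  pair_ok <- setequal(strain_codes(optima), strain_codes(target))

  fit <- fit_ols(build_model_matrix(library$strains), library$truth)
  p <- fit$p_values[PATHWAY_ENZYMES]
  tal_ok <- !is.na(p[["TAL"]]) && p[["TAL"]] > alpha &&
    all(p[setdiff(PATHWAY_ENZYMES, "TAL")] < alpha)
  me <- abs(fit$coefficients[PATHWAY_ENZYMES])
  c3h_ok <- names(which.max(me)) == "C3H"

  list(optimal_pair = pair_ok, tal_insignificant = tal_ok,
       c3h_largest = c3h_ok, ok = pair_ok && tal_ok && c3h_ok,
       details = list(optima = optima, main_effect_p = p,
                      main_effects = fit$coefficients[PATHWAY_ENZYMES],
                      fit = fit, library = library))
}

#' The qualitative optimal strain pair
#'
#' High C3H, DCS and CURS; low FCS, COMT and CCOAOMT; TAL at either level.
#' Columns in canonical enzyme order.
#'
#' @return A 2 x 7 coded matrix.
#' @export
expected_optimal_pair <- function() {
  m <- rbind(c(-1, 1, -1, -1, -1, 1, 1),
             c( 1, 1, -1, -1, -1, 1, 1))
  colnames(m) <- PATHWAY_ENZYMES
  m
}

#' Calibrate default kinetic parameters
#'
#' Log-uniform random search over kinetic parameter ranges, accepting the
#' first parameter set whose noiseless full factorial library satisfies the
#' three [calibration_properties()]. Zero-width ranges pin a parameter to its
#' centre, so a degenerate search specification around a known-good set
#' returns it unchanged.
#'
#' @param ranges Named list of `c(lo, hi)` ranges (any subset of the names in
#'   [default_kinetic_parameters()]); parameters not listed stay at their
#'   shipped value.
#' @param n_trials Search budget.
#' @param seed Integer seed.
#' @param alpha Significance threshold for property (b).
#' @return A calibrated [pathway_model()]; `$metadata` records the seed, the
#'   accepted trial index and the sampled parameters.
#' @export
calibrate_default_parameters <- function(ranges = list(), n_trials = 50L,
                                         seed = 1L, alpha = 0.05) {
  base <- default_kinetic_parameters()
  if (!all(names(ranges) %in% names(base))) {
    stop("unknown parameter(s) in ranges: ",
         paste(setdiff(names(ranges), names(base)), collapse = ", "))
  }
  if (!all(vapply(ranges, function(r) length(r) == 2 && all(r > 0) &&
                    r[1] <= r[2], logical(1)))) {
    stop("each range must be c(lo, hi) with 0 < lo <= hi")
  }
  fails <- c(optimal_pair = 0L, tal_insignificant = 0L, c3h_largest = 0L)
  for (trial in seq_len(n_trials)) {
    p <- base
    if (length(ranges)) {
      draw <- with_seed(seed + trial - 1L, vapply(ranges, function(r) {
        exp(stats::runif(1, log(r[1]), log(r[2])))
      }, numeric(1)))
      p[names(ranges)] <- draw
    }
    model <- build_default_model(p)
    props <- calibration_properties(model, alpha)
    if (props$ok) {
      model$metadata$parameter_source <- "calibrated"
      model$metadata$calibration_seed <- as.integer(seed)
      model$metadata$calibration_trial <- trial
      model$metadata$sampled_parameters <-
        if (length(ranges)) p[names(ranges)] else numeric(0)
      return(model)
    }
    for (nm in names(fails)) if (!props[[nm]]) fails[nm] <- fails[nm] + 1L
    if (length(ranges) == 0L) break  # nothing to vary
  }
  stop("calibration search budget exhausted after ", n_trials,
       " trial(s); failure counts: ",
       paste(names(fails), fails, sep = " = ", collapse = ", "))
}
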