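#' Instantaneous flux of one reaction
#'
#' Pure-R evaluation of the four rate laws, used for documentation, small
#' calculations and as an independent check of the compiled right-hand side.
#' Fluxes are proportional to the enzyme concentration and vanish when any
#' substrate or the enzyme is absent.
#'
#' @param reaction A [reaction()].
#' @param state Named numeric vector of species concentrations (mM).
#' @param enzyme_conc Enzyme concentration (mM).
#' @return Flux in mM/h.
#' @export
reaction_flux <- function(reaction, state, enzyme_conc) {
  if (any(state < 0) || enzyme_conc < 0) {
    stop("concentrations must be non-negative")
  }
  subs <- names(reaction$substrates)
  s1 <- state[[subs[1]]]
  switch(reaction$rate_law,
    michaelis_menten = {
      km <- reaction$params$Km[[subs[1]]]
      reaction$params$kcat * enzyme_conc * s1 / (km + s1)
    },
    mass_action = reaction$params$k * enzyme_conc * s1,
    mm_competitive = {
      pool <- reaction$competitor_pool
      denom <- 1 + sum(state[names(pool)] / pool)
      km <- reaction$params$Km[[subs[1]]]
      reaction$params$kcat * enzyme_conc * (s1 / km) / denom
    },
    mm_bisubstrate_competitive = {
      pool <- reaction$competitor_pool
      denom <- 1 + sum(state[names(pool)] / pool)
      s2 <- state[[subs[2]]]
      km1 <- reaction$params$Km[[subs[1]]]
      km2 <- reaction$params$Km[[subs[2]]]
      reaction$params$kcat * enzyme_conc * (s1 / km1) * (s2 / km2) / denom^2
    })
}

#' Time derivative of the pathway state
#'
#' R-level wrapper around the compiled right-hand side; mainly useful for
#' testing and for inspecting fluxes at a given state.
#'
#' @param model A [pathway_model()].
#' @param state Named numeric vector over `model$species`.
#' @param enzyme_conc Named numeric vector of enzyme concentrations (mM).
#' @return Named vector of d(concentration)/dt (mM/h).
#' @export
pathway_rhs <- function(model, state, enzyme_conc) {
  e <- model$encoding
  dy <- pathway_rhs_cpp(as.numeric(state[model$species]),
                        e$r_type, e$r_enz, e$r_sub1, e$r_sub2,
                        e$r_k, e$r_km1, e$r_km2,
                        e$pool_start, e$pool_sp, e$pool_km, e$stoich,
                        as.numeric(enzyme_conc[model$enzymes]))
  stats::setNames(dy, model$species)
}

#' Simulate one strain
#'
#' Integrates the batch ODE system from the model's initial state to its
#' horizon for a strain given by coded enzyme levels, and reports the
#' curcumin end-point concentration, the package's response variable.
#'
#' @param model A [pathway_model()].
#' @param strain Numeric vector of 7 coded levels in \{-1, +1\}, ordered as
#'   `model$enzymes`.
#' @param enzyme_conc Optional named vector of absolute enzyme concentrations
#'   overriding the coded levels (test hook; e.g. an enzyme at 0).
#' @param n_report Number of equally spaced report times (including 0).
#' @return A list with `trajectory` (data.frame: time plus one column per
#'   species), `cur_endpoint` (mM) and `endpoint` (named vector, full state at
#'   the horizon).
#' @export
#' @examples
#' m <- build_default_model()
#' s <- simulate_strain(m, rep(1, 7))
#' s$cur_endpoint
simulate_strain <- function(model, strain = NULL, enzyme_conc = NULL,
                            n_report = 51) {
  if (is.null(enzyme_conc)) {
    enzyme_conc <- decode_levels(model, strain)
  } else {
    stopifnot(setequal(names(enzyme_conc), model$enzymes), all(enzyme_conc >= 0))
    enzyme_conc <- enzyme_conc[model$enzymes]
  }
  e <- model$encoding
  times <- seq(0, model$sim_horizon, length.out = max(2L, n_report))
  res <- tryCatch(
    pathway_ode_cpp(as.numeric(model$initial_state), times,
                    e$r_type, e$r_enz, e$r_sub1, e$r_sub2,
                    e$r_k, e$r_km1, e$r_km2,
                    e$pool_start, e$pool_sp, e$pool_km, e$stoich,
                    as.numeric(enzyme_conc), model$rtol, model$atol,
                    max_steps = 1e6),
    error = function(err) {
      stop("pathway ODE integration failed (enzymes: ",
           paste(signif(enzyme_conc, 3), collapse = ", "), "): ",
           conditionMessage(err), call. = FALSE)
    })
  # Depleted species can undershoot zero by a few multiples of atol (the
  # integrator preserves the linear carbon invariant exactly, so the
  # internal state is left untouched); reported concentrations are
  # projected to zero, larger negatives abort.
  yout <- res$y
  if (any(yout < -1e3 * model$atol)) {
    stop("integration produced concentrations below -1000*atol; ",
         "tighten tolerances")
  }
  yout[yout < 0] <- 0
  traj <- as.data.frame(yout)
  names(traj) <- model$species
  traj <- cbind(time = times, traj)
  list(trajectory = traj,
       cur_endpoint = traj$CUR[nrow(traj)],
       endpoint = stats::setNames(as.numeric(yout[nrow(yout), ]),
                                  model$species))
}

#' Noise specification
#'
#' Replicates are generated as `truth * (1 + eps)` with
#' `eps ~ Normal(0, sigma^2)`, independent across strains and replicates:
#' multiplicative relative Gaussian noise. Negative draws are kept (no
#' truncation) to preserve the Gaussian error model assumed by OLS.
#'
#' @param sigma Relative standard deviation (e.g. 0.05 or 0.20).
#' @param n_reps Number of replicates per strain.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.20, n_reps = 3L) {
  stopifnot(sigma >= 0, n_reps >= 1)
  structure(list(sigma = sigma, n_reps = as.integer(n_reps),
                 distribution = "gaussian"),
            class = "noise_spec")
}

#' Simulate a strain library (noiseless)
#'
#' Runs [simulate_strain()] for every row of a design and collects the
#' noiseless curcumin end points ("truth"). Replicate columns are initialised
#' to the truth; add measurement error with [add_noise()].
#'
#' @param model A [pathway_model()].
#' @param design A [full_factorial()]-style design with 7 coded columns.
#' @return An object of class `strain_library`: list with `strains` (coded
#'   matrix), `truth` (numeric vector, mM), `replicates` (matrix), `noise`
#'   ([noise_spec()] with sigma 0), `seed` (NA until noise is added).
#' @export
simulate_library <- function(model, design) {
  m <- design_matrix(design)
  if (ncol(m) != 7L) stop("design must have 7 factors")
  truth <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    truth[i] <- tryCatch(
      simulate_strain(model, m[i, ], n_report = 2L)$cur_endpoint,
      error = function(err) {
        stop("simulation failed at design row ", i, ": ",
             conditionMessage(err), call. = FALSE)
      })
  }
  structure(list(strains = m, truth = truth,
                 replicates = matrix(truth, nrow(m), 1L),
                 noise = noise_spec(0, 1L), seed = NA_integer_),
            class = "strain_library")
}

#' @export
print.strain_library <- function(x, ...) {
  cat("Strain library:", nrow(x$strains), "strains,",
      ncol(x$replicates), "replicate(s), sigma =", x$noise$sigma, "\n")
  cat("  truth range:", signif(min(x$truth), 3), "-",
      signif(max(x$truth), 3), "mM\n")
  invisible(x)
}

#' Add replicate measurement noise to a library
#'
#' @param library A [simulate_library()] result.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; the replicate matrix is reproducible given the
#'   seed.
#' @return The library with `replicates` replaced by an
#'   `n_strains x n_reps` matrix of noisy responses; `truth` is unchanged.
#' @export
add_noise <- function(library, noise, seed) {
  stopifnot(inherits(library, "strain_library"), inherits(noise, "noise_spec"))
  n <- length(library$truth)
  eps <- with_seed(seed, matrix(stats::rnorm(n * noise$n_reps, 0, noise$sigma),
                                n, noise$n_reps))
  library$replicates <- library$truth * (1 + eps)
  library$noise <- noise
  library$seed <- as.integer(seed)
  library
}

# Run code under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Carbon-unit balance of a trajectory
#'
#' Cinnamate-unit weighted sum of all species: monomeric intermediates count
#' once, the three condensation products twice. Constant over time for the
#' closed batch system.
#'
#' @param trajectory The `trajectory` data.frame from [simulate_strain()].
#' @return Numeric vector, one total per report time (mM cinnamate units).
#' @export
carbon_balance <- function(trajectory) {
  as.numeric(as.matrix(trajectory[, names(CARBON_WEIGHTS)]) %*% CARBON_WEIGHTS)
}
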