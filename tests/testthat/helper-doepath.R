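# Shared fixtures. The shipped full factorial library is expensive enough
# (128 ODE integrations, ~1 s) to build once per test run.
.fixtures <- new.env(parent = emptyenv())

shipped_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_default_model()
  .fixtures$model
}

shipped_library <- function() {
  if (is.null(.fixtures$library)) {
    .fixtures$library <- simulate_library(shipped_model(), full_factorial(7))
  }
  .fixtures$library
}

# Noiseless response generated from a known effect model (intercept, main
# effects, optional 2FIs) on a coded design: the recovery oracle.
effect_truth <- function(design, beta0, me, fi = NULL) {
  m <- design_matrix(design)
  y <- rep(beta0, nrow(m)) + as.numeric(m[, names(me), drop = FALSE] %*% me)
  if (!is.null(fi)) {
    for (nm in names(fi)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      y <- y + fi[[nm]] * m[, pair[1]] * m[, pair[2]]
    }
  }
  y
}

# Single-reaction toy model: one Michaelis-Menten conversion TYR -> CUA by
# TAL; used against the scalar RK4 oracle.
toy_mm_model <- function(kcat = 12, km = 0.3, tyr0 = 0.4, horizon = 5) {
  pathway_model(
    list(reaction("TAL", c(TYR = 1), c(CUA = 1), "TAL", "michaelis_menten",
                  list(kcat = kcat, Km = list(TYR = km)))),
    default_enzyme_conc = stats::setNames(rep(0.01, 7),
                                          c("TAL", "C3H", "COMT", "FCS",
                                            "CCOAOMT", "DCS", "CURS")),
    initial_state = c(TYR = tyr0),
    sim_horizon = horizon)
}

# Dense fixed-step RK4 on the scalar MM equation dS/dt = -Vmax S / (Km + S):
# the independent integration oracle.
rk4_mm_endpoint <- function(vmax, km, s0, t_end, n_steps = 200000) {
  h <- t_end / n_steps
  f <- function(s) -vmax * s / (km + s)
  s <- s0
  for (i in seq_len(n_steps)) {
    k1 <- f(s); k2 <- f(s + h / 2 * k1); k3 <- f(s + h / 2 * k2)
    k4 <- f(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}
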