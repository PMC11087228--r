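test_that("the default network reproduces the pathway topology", {
  m <- shipped_model()
  expect_length(m$species, 12L)
  expect_length(m$enzymes, 7L)
  rl <- vapply(m$reactions, function(r) r$rate_law, character(1))
  enz <- vapply(m$reactions, function(r) r$enzyme, character(1))
  expect_equal(enz[rl == "mass_action"], "C3H")
  promiscuous <- unique(enz[vapply(m$reactions, function(r)
    length(r$competitor_pool) > 0, logical(1))])
  expect_setequal(promiscuous, c("FCS", "DCS", "CURS"))
  expect_equal(sum(enz == "FCS"), 3L)
  expect_equal(sum(enz == "CURS"), 4L)
  # DMC arises from both mixed condensations
  dmc <- Filter(function(r) "DMC" %in% names(r$products), m$reactions)
  expect_length(dmc, 2L)
})

test_that("reaction fluxes follow their rate laws", {
  r_mm <- reaction("x", c(TYR = 1), c(CUA = 1), "TAL", "michaelis_menten",
                   list(kcat = 200, Km = list(TYR = 0.3)))
  # half saturation: flux = kcat * E / 2
  expect_equal(reaction_flux(r_mm, c(TYR = 0.3), 0.01), 1)
  expect_equal(reaction_flux(r_mm, c(TYR = 0.3), 0), 0)
  expect_equal(reaction_flux(r_mm, c(TYR = 0), 0.01), 0)
  expect_error(reaction_flux(r_mm, c(TYR = -1), 0.01), "non-negative")

  # competitive MM with competitors at zero equals plain MM
  pool <- c(CUA = 0.5, CAA = 0.05, FEA = 8)
  r_comp <- reaction("y", c(CUA = 1), c(CUCOA = 1), "FCS", "mm_competitive",
                     list(kcat = 60, Km = list(CUA = 0.5)),
                     competitor_pool = pool)
  st <- c(CUA = 0.2, CAA = 0, FEA = 0)
  expect_equal(reaction_flux(r_comp, st, 0.01),
               60 * 0.01 * 0.2 / (0.5 + 0.2))
  # flux scales linearly in enzyme concentration
  expect_equal(reaction_flux(r_comp, st, 0.02),
               2 * reaction_flux(r_comp, st, 0.01))

  r_ma <- reaction("z", c(CUA = 1), c(CAA = 1), "C3H", "mass_action",
                   list(k = 40))
  expect_equal(reaction_flux(r_ma, c(CUA = 0.1), 0.01), 40 * 0.01 * 0.1)
})

test_that("compiled and R rate evaluations agree", {
  m <- shipped_model()
  set.seed(3)
  state <- stats::setNames(runif(12, 0, 0.3), m$species)
  ec <- decode_levels(m, c(1, -1, 1, -1, 1, -1, 1))
  dy <- pathway_rhs(m, state, ec)
  # independent route: accumulate reaction_flux through the stoichiometry
  manual <- stats::setNames(numeric(12), m$species)
  for (r in m$reactions) {
    v <- reaction_flux(r, state, ec[[r$enzyme]])
    manual[names(r$substrates)] <- manual[names(r$substrates)] - r$substrates * v
    manual[names(r$products)] <- manual[names(r$products)] + r$products * v
  }
  expect_equal(dy, manual, tolerance = 1e-12)
  # doubling one enzyme doubles exactly its reactions' fluxes
  ec2 <- ec; ec2[["DCS"]] <- 2 * ec2[["DCS"]]
  delta <- pathway_rhs(m, state, ec2) - dy
  dcs_flux <- stats::setNames(numeric(12), m$species)
  for (r in Filter(function(r) r$enzyme == "DCS", m$reactions)) {
    v <- reaction_flux(r, state, ec[[r$enzyme]])
    dcs_flux[names(r$substrates)] <- dcs_flux[names(r$substrates)] - v
    dcs_flux[names(r$products)] <- dcs_flux[names(r$products)] + v
  }
  expect_equal(delta, dcs_flux, tolerance = 1e-12)
})

test_that("the integrator matches a dense RK4 oracle on the scalar MM system", {
  toy <- toy_mm_model(kcat = 12, km = 0.3, tyr0 = 0.4, horizon = 5)
  s <- simulate_strain(toy, rep(-1, 7))
  # enzyme at default 0.01 -> Vmax = 0.12
  oracle_tyr <- rk4_mm_endpoint(vmax = 0.12, km = 0.3, s0 = 0.4, t_end = 5)
  expect_equal(s$endpoint[["TYR"]], oracle_tyr, tolerance = 1e-8)
  expect_equal(s$endpoint[["CUA"]], 0.4 - oracle_tyr, tolerance = 1e-8)
})

test_that("strain simulation honours conservation and positivity", {
  m <- shipped_model()
  set.seed(42)
  for (strain in list(rep(-1, 7), rep(1, 7),
                      sample(c(-1, 1), 7, replace = TRUE))) {
    s <- simulate_strain(m, strain, n_report = 21)
    traj <- s$trajectory
    expect_true(all(as.matrix(traj[-1]) >= 0))
    # conserved exactly inside the integrator; the zero-projection of
    # depleted species distorts reported totals by at most ~100 * atol
    cb <- carbon_balance(traj)
    expect_equal(cb, rep(cb[1], length(cb)), tolerance = 100 * m$atol)
    # end products never decrease
    for (sp in c("BDC", "DMC", "CUR")) expect_true(all(diff(traj[[sp]]) >= -1e-9))
    expect_gte(s$cur_endpoint, 0)
  }
})

test_that("an absent first enzyme yields zero curcumin", {
  m <- shipped_model()
  ec <- decode_levels(m, rep(1, 7))
  ec[["TAL"]] <- 0
  s <- simulate_strain(m, enzyme_conc = ec)
  expect_equal(s$cur_endpoint, 0, tolerance = 1e-12)
  expect_equal(s$endpoint[["TYR"]], m$initial_state[["TYR"]])
})

test_that("library simulation is deterministic row-wise", {
  m <- shipped_model()
  d <- structure(list(
    matrix = rbind(c(-1, 1, -1, -1, -1, 1, 1), c(-1, 1, -1, -1, -1, 1, 1)),
    factor_names = m$enzymes, provenance = list(type = "manual"), n = 7L),
    class = "doe_design")
  lib <- simulate_library(m, d)
  expect_equal(lib$truth[1], lib$truth[2])
  lib16 <- simulate_library(m, catalog_design("IV"))
  expect_length(lib16$truth, 16L)
  full <- shipped_library()
  expect_length(full$truth, 128L)
  expect_true(all(full$truth >= 0))
})

test_that("noise is multiplicative, unbiased and seeded", {
  lib <- simulate_library(shipped_model(), catalog_design("III"))
  l0 <- add_noise(lib, noise_spec(0, 3), seed = 1)
  expect_equal(l0$replicates, matrix(lib$truth, 8, 3), ignore_attr = TRUE)

  l1 <- add_noise(lib, noise_spec(0.2, 3), seed = 9)
  l2 <- add_noise(lib, noise_spec(0.2, 3), seed = 9)
  expect_identical(l1$replicates, l2$replicates)
  expect_identical(l1$truth, lib$truth)
  expect_false(identical(l1$replicates,
                         add_noise(lib, noise_spec(0.2, 3), seed = 10)$replicates))

  # law of large numbers on one strain
  one <- lib; one$truth <- lib$truth[1]; one$strains <- lib$strains[1, , drop = FALSE]
  one$replicates <- matrix(one$truth, 1, 1)
  big <- add_noise(one, noise_spec(0.2, 100000L), seed = 4)
  draws <- as.numeric(big$replicates)
  se <- 0.2 * one$truth / sqrt(length(draws))
  expect_lt(abs(mean(draws) - one$truth), 3 * se)
  expect_lt(abs(stats::sd(draws) / one$truth - 0.2), 0.02 * 0.2)
})

test_that("calibration search validates ranges and degenerate specs", {
  # zero-width ranges around shipped defaults return them unchanged
  m <- calibrate_default_parameters(ranges = list(), n_trials = 1, seed = 1)
  expect_s3_class(m, "pathway_model")
  expect_equal(m$metadata$calibration_trial, 1L)
  expect_error(calibrate_default_parameters(ranges = list(bogus = c(1, 2))),
               "unknown parameter")
  expect_error(calibrate_default_parameters(ranges = list(TAL.kcat = c(2, 1))),
               "lo <= hi")
  # an impossible region fails with per-property diagnostics
  expect_error(
    calibrate_default_parameters(ranges = list(C3H.k = c(1e-4, 2e-4)),
                                 n_trials = 2, seed = 1),
    "budget exhausted")
})
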