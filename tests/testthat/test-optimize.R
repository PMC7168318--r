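settings <- solver_settings()

test_that("pFBA solves a linear chain exactly", {
  m <- toy_chain_model(bound = 2)
  s <- solve_pfba(m, settings)
  expect_equal(s$status, "optimal")
  expect_equal(unname(s$objective_value), 2)
  expect_equal(unname(s$fluxes), rep(2, 3))
  expect_equal(s$growth_rate_per_day, 48)
  # steady state
  expect_lt(max(abs(stoich_matrix(m) %*% s$fluxes)), 1e-6)
})

test_that("pFBA routes flux through the shorter of two equal-yield pathways", {
  m <- parallel_routes_model(bound = 2)
  s <- solve_pfba(m, settings)
  expect_equal(unname(s$objective_value), 2)
  expect_equal(unname(s$fluxes[["R1"]]), 2)
  expect_equal(unname(s$fluxes[["R2a"]]), 0)
  # oracle: enumerate vertices of the growth-fixed polytope, compare L1
  l1_opt <- vertex_min_l1_at(m, 2)
  expect_equal(s$l1_norm, l1_opt, tolerance = 1e-8)
})

test_that("pFBA growth equals exhaustive vertex enumeration on small networks", {
  for (seed in 1:10) {
    m <- random_small_model(seed, n_extra = 4)   # 7 reactions
    s <- solve_pfba(m, settings)
    vmax <- vertex_max_growth(m)
    expect_equal(unname(s$objective_value), vmax, tolerance = 1e-7,
                 info = paste("seed", seed))
    # step 2 never lowers the step-1 optimum
    expect_equal(unname(s$fluxes[[m$objective]]), vmax, tolerance = 1e-6)
    # steady-state residual
    expect_lt(max(abs(stoich_matrix(m) %*% s$fluxes)), 1e-6)
    # pFBA L1 <= plain FBA L1
    f <- solve_fba(m, settings)
    expect_lte(s$l1_norm, sum(abs(f$fluxes)) + 1e-8)
  }
})

test_that("solver statuses cover infeasible and unbounded models", {
  m <- toy_chain_model()
  m_inf <- set_bounds(m, "EX_A", 0, 0)
  m_inf <- set_bounds(m_inf, "BIO", 1, 2)     # forced flux, no source
  expect_equal(solve_fba(m_inf, settings)$status, "infeasible")
  m_unb <- set_bounds(m, c("EX_A", "R1", "BIO"), upper = Inf)
  expect_equal(solve_fba(m_unb, settings)$status, "unbounded")
})

test_that("MOMA distance is zero iff the reference stays feasible", {
  m <- parallel_routes_model()
  ref <- solve_pfba(m, settings)
  # identical model: distance 0, fluxes equal the reference
  s0 <- solve_moma(m, ref, settings)
  expect_equal(s0$moma_distance, 0, tolerance = 1e-9)
  expect_equal(s0$fluxes, ref$fluxes, tolerance = 1e-6)
  # deletion of a zero-flux reaction: distance 0, growth unchanged
  s1 <- solve_moma(knockout_reactions(m, "R2a"), ref, settings)
  expect_equal(s1$moma_distance, 0, tolerance = 1e-9)
  expect_equal(s1$objective_value, ref$objective_value, tolerance = 1e-9)
  # deleting the active route: MOMA growth <= re-optimised growth
  mdel <- knockout_reactions(m, "R1")
  smoma <- solve_moma(mdel, ref, settings)
  sfba <- solve_pfba(mdel, settings)
  expect_lte(smoma$objective_value, sfba$objective_value + 1e-9)
  expect_gt(smoma$moma_distance, 0)
  # infeasible modified model
  m_inf <- set_bounds(knockout_reactions(m, "EX_A"), "BIO", 1, 2)
  expect_equal(solve_moma(m_inf, ref, settings)$status, "infeasible")
})

test_that("active_set applies the two detection limits", {
  m <- toy_chain_model()
  s <- solve_pfba(m, settings)
  expect_setequal(active_set(s, settings), c("EX_A", "R1", "BIO"))
  z <- robustfba:::new_flux_solution(
    setNames(c(1e-8, 1e-8, 1e-8), m$reactions$id), "optimal", "BIO", "fba",
    settings)
  # 1e-8 is above the generic limit (1e-9) but below the objective's (1e-6)
  expect_setequal(active_set(z, settings), c("EX_A", "R1"))
  zero <- robustfba:::new_flux_solution(
    setNames(numeric(3), m$reactions$id), "optimal", "BIO", "fba", settings)
  expect_length(active_set(zero, settings), 0)
  bad <- robustfba:::new_flux_solution(setNames(numeric(3), m$reactions$id),
                                       "infeasible", "BIO", "fba", settings)
  expect_error(active_set(bad, settings), "optimal")
})

test_that("energy-from-nothing QC passes clean models and fails a planted ATP cycle", {
  g <- generate_model(synth_config(seed = 2, composition = "compact"),
                      qc = FALSE)
  rep_ok <- qc_energy_from_nothing(g$model, settings)
  expect_true(rep_ok$pass)
  bad <- atp_cycle_fault_model()
  rep_bad <- qc_energy_from_nothing(bad, settings)
  expect_false(rep_bad$pass)
  # the offending loop is named
  expect_true("GEN" %in% unlist(rep_bad$carriers))
})

test_that("leak test passes clean models and localises a stoichiometric error", {
  g <- generate_model(synth_config(seed = 2, composition = "compact"),
                      qc = FALSE)
  expect_true(qc_leak_test(g$model, settings)$pass)
  bad <- duplication_leak_model()
  rep_bad <- qc_leak_test(bad, settings)
  expect_false(rep_bad$pass)
  expect_true("B_c" %in% rep_bad$leaky$metabolite)
})

test_that("bioenergetic scenarios relocate ATP production at constant growth", {
  g <- generate_model(synth_config(seed = 1, composition = "compact"))
  m <- g$model
  s_ctl <- solve_pfba(m, settings)
  m1 <- bioenergetics_scenario(m, "no_redox_exchange")
  s1 <- solve_pfba(m1, settings)
  m2 <- bioenergetics_scenario(m, "psi_coupled")
  s2 <- solve_pfba(m2, settings)
  # scenario 1: extra ATP from cyclic PSI, none from mitochondria
  expect_gt(s1$fluxes[["CEF"]], 1e-6)
  expect_equal(unname(s1$fluxes[["RESP"]]), 0, tolerance = 1e-9)
  # scenario 2: mitochondrial ATP, AOX silent
  expect_gt(s2$fluxes[["RESP"]], 1e-6)
  expect_equal(unname(s2$fluxes[["AOX"]]), 0, tolerance = 1e-9)
  # growth is unaffected by where the balancing ATP is made
  expect_equal(s1$objective_value, s_ctl$objective_value, tolerance = 1e-8)
  expect_equal(s2$objective_value, s_ctl$objective_value, tolerance = 1e-8)
  # toggle back restores the original bounds
  m_back <- bioenergetics_scenario(m1, "control")
  i <- match(c("SHUTTLE_EXPORT", "AOX"), m$reactions$id)
  j <- match(c("SHUTTLE_EXPORT", "AOX"), m_back$reactions$id)
  expect_equal(m_back$reactions$lower_bound[j], m$reactions$lower_bound[i])
  expect_equal(m_back$reactions$upper_bound[j], m$reactions$upper_bound[i])
})

test_that("growth is nondecreasing in the carbon-uptake bound", {
  g <- generate_model(synth_config(seed = 4, composition = "compact"),
                      qc = FALSE)
  mu <- vapply(seq(0.6, 1.4, length.out = 7), function(f) {
    m <- set_bounds(g$model, "EX_hco3", 0, f * 0.78)
    solve_fba(m, settings)$objective_value
  }, numeric(1))
  expect_true(all(diff(mu) >= -1e-9))
})
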