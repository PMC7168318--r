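test_that("parameter set construction and perturbation behave", {
  p <- composition_params()
  expect_length(p, 69)
  expect_equal(p[["cn"]], 5.7)
  expect_equal(p[["np"]], 10)
  expect_equal(p[["ps"]], 0.78)
  expect_equal(p[["totalprot"]], 0.46)
  expect_equal(p[["glucose"]], 0)
  expect_error(composition_params(c(bogus = 1)), "unknown parameters")
  expect_error(composition_params(c(totalprot = -1)), "positive")
  expect_error(composition_params(c(gcprop = 100)), "gcprop")

  # identity, single-field change, inverse
  expect_equal(perturb_params(p, setNames(rep(1, 69), names(p))), p)
  p2 <- perturb_params(p, c(ps = 1.4))
  expect_equal(p2[["ps"]], 0.78 * 1.4)
  expect_equal(p2[names(p2) != "ps"], p[names(p) != "ps"])
  p3 <- perturb_params(p2, c(ps = 1 / 1.4))
  expect_equal(p3[["ps"]], p[["ps"]], tolerance = 1e-12)
  expect_error(perturb_params(p, c(nope = 2)), "unknown parameters")
})

test_that("DNA and RNA base composition follows the GC proportion", {
  bs <- build_biomass(composition_params(c(gcprop = 40)))
  molefrac <- function(coefs) coefs / sum(coefs)
  dna <- molefrac(bs$components$dna)
  expect_equal(unname(dna[c("dgmp", "dcmp")]), c(0.2, 0.2), tolerance = 1e-12)
  expect_equal(unname(dna[c("damp", "dtmp")]), c(0.3, 0.3), tolerance = 1e-12)
  rna <- molefrac(bs$components$rna)
  expect_equal(unname(rna[["gmp"]] + rna[["cmp"]]), 0.4, tolerance = 1e-12)
})

test_that("equal masses of two equal-weight amino acids give equal coefficients", {
  vals <- setNames(rep(1e-9, 20), robustfba:::amino_acid_ids)
  vals[c("ala", "gly")] <- 0.04
  p <- composition_params(vals)
  M <- default_monomer_masses()
  M[c("ala", "gly")] <- 100
  bs <- build_biomass(p, M)
  prot <- bs$components$protein
  expect_equal(unname(prot[["ala"]]), unname(prot[["gly"]]), tolerance = 1e-9)
  # the two dominate and together make up ~1 g
  expect_equal(sum(prot * M[names(prot)]) / 1000, 1, tolerance = 1e-9)
  expect_equal(unname(prot[["ala"]]) * 100 / 1000, 0.5, tolerance = 1e-6)
})

test_that("component totals are renormalised over their printed sum", {
  bs <- build_biomass(composition_params())
  totals <- c(0.46, 0.31, 0.21, 0.0022, 0.018, 0.016)
  expect_equal(bs$raw_total, sum(totals), tolerance = 1e-12)
  expect_equal(unname(bs$fractions),
               unname(totals / sum(totals)), tolerance = 1e-12)
  expect_equal(sum(bs$fractions), 1, tolerance = 1e-12)
})

test_that("every component equation consumes exactly 1 g of monomers", {
  M <- default_monomer_masses()
  for (seed in 1:5) {
    p <- generate_params(seed, scale = 0.3)
    bs <- build_biomass(p)
    for (nm in names(bs$components)) {
      grams <- sum(bs$components[[nm]] * M[names(bs$components[[nm]])]) / 1000
      expect_equal(grams, 1, tolerance = 1e-6,
                   info = paste("seed", seed, nm))
    }
  }
})

test_that("scaling one monomer leaves the other components' equations unchanged", {
  p <- composition_params()
  bs <- build_biomass(p)
  bs2 <- build_biomass(perturb_params(p, c(ala = 1.7)))
  expect_false(isTRUE(all.equal(bs$components$protein, bs2$components$protein)))
  for (nm in c("carbohydrate", "lipid", "dna", "rna", "pigment"))
    expect_equal(bs2$components[[nm]], bs$components[[nm]], info = nm)
})

test_that("uptake constraints follow the C:N and N:P cascade", {
  g <- generate_model(synth_config(seed = 1, composition = "compact"),
                      qc = FALSE)
  p <- composition_params()
  m <- apply_uptake_constraints(g$model, p)
  ub <- setNames(m$reactions$upper_bound, m$reactions$id)
  expect_equal(unname(ub[["EX_hco3"]]), 0.78)
  expect_equal(unname(ub[["EX_no3"]]), 0.78 / 5.7, tolerance = 1e-12)
  expect_equal(unname(ub[["EX_po4"]]), 0.78 / 5.7 / 10, tolerance = 1e-12)
  # doubling the carbon uptake rate doubles the N and P bounds
  m2 <- apply_uptake_constraints(g$model, perturb_params(p, c(ps = 2)))
  ub2 <- setNames(m2$reactions$upper_bound, m2$reactions$id)
  expect_equal(unname(ub2[["EX_no3"]]), 2 * unname(ub[["EX_no3"]]))
  expect_equal(unname(ub2[["EX_po4"]]), 2 * unname(ub[["EX_po4"]]))
})

test_that("unit biomass flux consumes one gram dry weight of precursors", {
  g <- generate_model(synth_config(seed = 1, composition = "full"))
  m <- g$model
  masses <- setNames(
    vapply(m$metabolites$formula, function(f)
      if (is.na(f) || !nzchar(f)) NA_real_ else robustfba:::formula_mass(f),
      numeric(1)),
    m$metabolites$id)
  spec <- m$biomass_spec
  # per component: monomer mass drawn per unit flux equals its mass fraction
  bs <- build_biomass(g$params, spec$monomer_masses)
  total <- 0
  for (nm in names(spec$component_rxns)) {
    st <- m$stoichiometry[[spec$component_rxns[[nm]]]]
    monomers <- intersect(names(st), spec$monomer_mets)
    grams <- -sum(st[monomers] * masses[monomers]) / 1000
    expect_equal(grams, 1, tolerance = 1e-6, info = nm)
    total <- total + grams * bs$fractions[[nm]]
  }
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("growth is invariant under uniform scaling of a component's monomers", {
  g <- generate_model(synth_config(seed = 1, composition = "full"))
  m <- g$model; p <- g$params
  mu0 <- solve_fba(update_model_params(m, p))$objective_value
  scaled <- perturb_params(p, setNames(rep(2.5, 20),
                                       robustfba:::amino_acid_ids))
  mu1 <- solve_fba(update_model_params(m, scaled))$objective_value
  expect_equal(mu1, mu0, tolerance = 1e-9)
  scaled2 <- perturb_params(p, setNames(rep(0.4, 19),
                                        robustfba:::lipid_ids))
  mu2 <- solve_fba(update_model_params(m, scaled2))$objective_value
  expect_equal(mu2, mu0, tolerance = 1e-9)
})
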