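# Synthetic genome-scale models for testing and validation.
#
# The generator emulates the structural features the robustness analyses
# rely on: exchange reactions for carbon (bicarbonate), nitrate, phosphate
# and photons; a light-driven ATP/NADPH subsystem with linear electron
# flow, an optional cyclic route around photosystem I and a mitochondrial
# respiration route connected through an organelle redox shuttle; energy
# dissipation reactions (photorespiration, Mehler, PTOX) that optimal
# solutions leave inactive; biomass assembled by the biomass module from a
# composition parameter set; GPR rules with OR (isozymes) and AND
# (complexes) structure; and dormant compensatory pathways that carry a
# slightly higher Manhattan-norm cost so parsimonious FBA leaves them
# inactive until a deletion forces a reroute. Every internal reaction with
# real chemistry is balanced over a five-element (C/H/N/O/P) bookkeeping,
# with water and protons as balancing species, so generated models are
# leak-free by construction (and this is re-verified before a model is
# returned).

core_formulas <- c(
  hco3 = "CHO3", no3 = "NO3", po4 = "H3O4P", pi = "H3O4P", photon = "",
  h2o = "H2O", o2 = "O2", h = "H", cfix = "CH2O", nh3 = "H3N",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2",
  nadp = "C21H28N7O17P3", nadph = "C21H29N7O17P3",
  nad = "C21H27N7O14P2", nadh = "C21H28N7O14P2")

# add water/proton coefficients so H and O balance; C, N, P must already
# balance (error otherwise). `formulas` maps metabolite id -> formula.
balance_rxn <- function(stoich, formulas, h2o_id, h_id) {
  res <- setNames(numeric(5), names(element_masses))
  for (met in names(stoich))
    res <- res + stoich[[met]] * formula_counts(formulas[[met]])
  for (el in c("C", "N", "P"))
    if (abs(res[[el]]) > 1e-9)
      stop("reaction cannot be balanced: residual ", el, " = ", res[[el]])
  w <- -res[["O"]]
  p <- -(res[["H"]] + 2 * w)
  if (abs(w) > 1e-12) stoich[h2o_id] <- sum(c(stoich[h2o_id], w), na.rm = TRUE)
  if (abs(p) > 1e-12) stoich[h_id] <- sum(c(stoich[h_id], p), na.rm = TRUE)
  stoich[abs(stoich) > 1e-12]
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic model generator
#'
#' @param seed Integer seed controlling all sampling; the same seed yields
#'   an identical model.
#' @param composition `"full"` uses the complete 69-parameter monomer set;
#'   `"compact"` uses one generic monomer per macromolecular component
#'   (much smaller model, same energetics); `"chain"` builds a minimal
#'   linear uptake-to-biomass chain.
#' @param n_core_pathways Number of parallel carbon-fixation routes (>= 1);
#'   routes beyond the first are dormant alternatives.
#' @param n_isozyme_reactions Reactions receiving a two-gene OR rule.
#' @param n_complex_reactions Reactions receiving a two-gene AND rule.
#' @param allele_fraction Fraction of genes given a divergent allelic
#'   partner in the emitted allele pair table.
#' @param n_alternative_routes Monomer syntheses given a dormant two-step
#'   compensatory route.
#' @param compartments Compartment ids to declare.
#' @param photon_bound Upper bound on photon uptake (mmol gDW^-1 h^-1).
#' @param ngam Non-growth-associated ATP maintenance flux (lower bound of
#'   the ATP maintenance reaction, mmol gDW^-1 h^-1).
#' @param params Optional [composition_params()] set; defaults to nominal.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, composition = c("full", "compact", "chain"),
                         n_core_pathways = 1L, n_isozyme_reactions = 10L,
                         n_complex_reactions = 5L, allele_fraction = 0.3,
                         n_alternative_routes = 8L,
                         compartments = c(e = "extracellular medium",
                                          c = "cytosol", h = "chloroplast",
                                          m = "mitochondria"),
                         photon_bound = 1000, ngam = 0.5, params = NULL) {
  composition <- match.arg(composition)
  stopifnot(n_core_pathways >= 1, n_isozyme_reactions >= 0,
            n_complex_reactions >= 0, n_alternative_routes >= 0,
            allele_fraction >= 0, allele_fraction <= 1)
  structure(list(seed = as.integer(seed), composition = composition,
                 n_core_pathways = n_core_pathways,
                 n_isozyme_reactions = n_isozyme_reactions,
                 n_complex_reactions = n_complex_reactions,
                 allele_fraction = allele_fraction,
                 n_alternative_routes = n_alternative_routes,
                 compartments = compartments, photon_bound = photon_bound,
                 ngam = ngam,
                 params = if (is.null(params)) composition_params() else params),
            class = "synth_config")
}

#' Sample a composition parameter set
#'
#' Nominal values multiplied by independent log-normal noise; `scale = 0`
#' returns the nominal (reference-condition) set exactly.
#'
#' @param seed Integer seed.
#' @param scale Standard deviation of the log-normal multipliers.
#' @return A [composition_params()] set.
#' @export
generate_params <- function(seed = 1L, scale = 0) {
  p <- composition_params()
  if (scale > 0) {
    mult <- with_seed(seed, exp(rnorm(length(p), 0, scale)))
    keep_zero <- p == 0
    p[] <- as.numeric(p) * mult
    p[keep_zero] <- 0
    # keep bounded proportions inside their open intervals
    for (nm in c("gcprop", "propglu", "proptga"))
      p[[nm]] <- min(max(p[[nm]], 1), 99)
  }
  p
}

compact_monomer_defs <- function() {
  data.frame(
    monomer = c("aa_gen", "sugar_gen", "lip_gen", "dntp_gen", "ntp_gen", "pig_gen"),
    class = c("protein", "carbohydrate", "lipid", "dna", "rna", "pigment"),
    formula = c("C5H10N1.4O3", "C6H12O6", "C45H80O8P0.4",
                "C10H14N4O7P", "C10H14N4O8P", "C45H60N2O4"),
    stringsAsFactors = FALSE)
}

generate_chain_model <- function(config) {
  p <- config$params
  mets <- data.frame(id = c("A_e", "A_c"), name = c("substrate (medium)", "substrate"),
                     compartment = c("e", "c"), stringsAsFactors = FALSE)
  rx <- data.frame(id = c("EX_A", "T_A", "BIOMASS"),
                   name = c("substrate exchange", "substrate import", "biomass"),
                   lower_bound = c(0, 0, 0), upper_bound = c(p[["ps"]], 1000, 1000),
                   is_exchange = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  st <- list(EX_A = c(A_e = 1), T_A = c(A_e = -1, A_c = 1), BIOMASS = c(A_c = -1))
  metabolic_model(mets, rx, st,
                  compartments = c(e = "extracellular medium", c = "cytosol"),
                  objective = "BIOMASS",
                  roles = list(carbon_uptake = "EX_A"),
                  id = sprintf("synth_chain_seed%d", config$seed))
}

#' Generate a synthetic genome-scale model
#'
#' Builds a deterministic toy photoautotroph model according to `config`
#' (see [synth_config()]), runs the quality controls, checks that growth is
#' strictly positive, and optionally attaches brute-force deletion ground
#' truth.
#'
#' @param config A [synth_config()].
#' @param ground_truth If `TRUE`, run [brute_force_deletions()] on the
#'   finished model and attach the resulting labels.
#' @param qc If `TRUE` (default), verify the energy-from-nothing and leak
#'   quality controls and positive growth before returning.
#' @param settings A [solver_settings()] object.
#' @return A list with elements `model`, `params`, `allele_table` and
#'   (optionally) `ground_truth`.
#' @export
generate_model <- function(config = synth_config(), ground_truth = FALSE,
                           qc = TRUE, settings = solver_settings()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$composition == "chain") {
    model <- generate_chain_model(config)
    out <- list(model = model, params = config$params,
                allele_table = data.frame(gene_id = character(0),
                                          allele_id = character(0)))
    if (qc) {
      leak <- qc_leak_test(model, settings)
      if (!leak$pass) stop("generated chain model leaks: ",
                           paste(leak$leaky$metabolite, collapse = ", "))
      g <- solve_fba(model, settings)
      if (g$status != "optimal" || g$objective_value <= 0)
        stop("generated chain model has no growth")
    }
    if (ground_truth)
      out$ground_truth <- brute_force_deletions(model, settings = settings)
    return(out)
  }
  out <- with_seed(config$seed, build_synth_core(config, settings))
  if (qc) {
    en <- qc_energy_from_nothing(out$model, settings)
    if (!en$pass)
      stop("generated model fails energy-from-nothing QC in check(s): ",
           paste(en$failed_checks, collapse = ", "), "; flux carriers: ",
           paste(unique(unlist(en$carriers)), collapse = ", "))
    leak <- qc_leak_test(out$model, settings)
    if (!leak$pass)
      stop("generated model leaks metabolites: ",
           paste(leak$leaky$metabolite, collapse = ", "))
    g <- solve_fba(out$model, settings)
    if (g$status != "optimal" || g$objective_value <= settings$objective_zero_tolerance)
      stop("generated model is infeasible or has zero growth (status ",
           g$status, ")")
  }
  if (ground_truth)
    out$ground_truth <- brute_force_deletions(out$model, settings = settings)
  out
}

build_synth_core <- function(config, settings) {
  comp <- config$compartments
  full <- config$composition == "full"
  mets <- list(); stoich <- list(); rx <- list(); formulas <- character(0)

  add_met <- function(base, cmp, formula = NULL, name = base) {
    id <- paste0(base, "_", cmp)
    if (is.null(formula)) formula <- unname(core_formulas[[base]])
    mets[[id]] <<- data.frame(id = id, name = name, compartment = cmp,
                              formula = formula, stringsAsFactors = FALSE)
    formulas[[id]] <<- formula
    id
  }
  add_rxn <- function(id, st, lb = 0, ub = 1000, name = id, balance = TRUE,
                      is_exchange = FALSE) {
    if (balance) st <- balance_rxn(st, formulas, find_h2o(st), find_h(st))
    rx[[id]] <<- data.frame(id = id, name = name, lower_bound = lb,
                            upper_bound = ub, is_exchange = is_exchange,
                            stringsAsFactors = FALSE)
    stoich[[id]] <<- st
    id
  }
  find_h2o <- function(st) {
    cmp <- sub("^.*_", "", names(st)[1])
    paste0("h2o_", cmp)
  }
  find_h <- function(st) {
    cmp <- sub("^.*_", "", names(st)[1])
    paste0("h_", cmp)
  }

  for (b in c("hco3", "no3", "po4", "o2", "h2o", "h")) add_met(b, "e")
  for (b in c("hco3", "no3", "pi", "cfix", "nh3", "atp", "adp", "h2o", "h", "o2"))
    add_met(b, "c")
  add_met("oxc", "c", "C4H4O5", "oxidised redox carrier (oxaloacetate-like)")
  add_met("redc", "c", "C4H6O5", "reduced redox carrier (malate-like)")
  for (b in c("photon", "hco3", "no3", "nh3", "atp", "adp", "pi", "nadp",
              "nadph", "h2o", "h", "o2", "cfix")) add_met(b, "h")
  for (b in c("atp", "adp", "pi", "nad", "nadh", "o2", "h2o", "h")) add_met(b, "m")

  # exchanges (inputs produce into the medium; drains are reversible)
  add_rxn("EX_hco3", c(hco3_e = 1), 0, config$params[["ps"]],
          "bicarbonate uptake", balance = FALSE, is_exchange = TRUE)
  add_rxn("EX_no3", c(no3_e = 1), 0, 1000, "nitrate uptake",
          balance = FALSE, is_exchange = TRUE)
  add_rxn("EX_po4", c(po4_e = 1), 0, 1000, "phosphate uptake",
          balance = FALSE, is_exchange = TRUE)
  # photons are absorbed directly at the thylakoid
  add_rxn("EX_photon", c(photon_h = 1), 0, config$photon_bound,
          "photon absorption", balance = FALSE, is_exchange = TRUE)
  add_rxn("EX_o2", c(o2_e = -1), -1000, 1000, "oxygen exchange",
          balance = FALSE, is_exchange = TRUE)
  add_rxn("EX_h2o", c(h2o_e = -1), -1000, 1000, "water exchange",
          balance = FALSE, is_exchange = TRUE)
  add_rxn("EX_h", c(h_e = -1), -1000, 1000, "proton exchange",
          balance = FALSE, is_exchange = TRUE)

  # transport
  add_rxn("T_hco3", c(hco3_e = -1, hco3_c = 1))
  add_rxn("T_hco3_ch", c(hco3_c = -1, hco3_h = 1))
  add_rxn("T_no3", c(no3_e = -1, no3_c = 1))
  add_rxn("T_no3_ch", c(no3_c = -1, no3_h = 1))
  add_rxn("T_po4", c(po4_e = -1, pi_c = 1))
  add_rxn("T_o2_ec", c(o2_e = -1, o2_c = 1), -1000)
  add_rxn("T_o2_ch", c(o2_h = -1, o2_c = 1), -1000)
  add_rxn("T_o2_cm", c(o2_c = -1, o2_m = 1), -1000)
  add_rxn("T_h2o_ec", c(h2o_e = -1, h2o_c = 1), -1000)
  add_rxn("T_h2o_ch", c(h2o_c = -1, h2o_h = 1), -1000)
  add_rxn("T_h2o_cm", c(h2o_c = -1, h2o_m = 1), -1000)
  add_rxn("T_h_ec", c(h_e = -1, h_c = 1), -1000)
  add_rxn("T_h_ch", c(h_c = -1, h_h = 1), -1000)
  add_rxn("T_h_cm", c(h_c = -1, h_m = 1), -1000)
  add_rxn("T_nh3_hc", c(nh3_h = -1, nh3_c = 1))
  add_rxn("T_cfix_hc", c(cfix_h = -1, cfix_c = 1))
  add_rxn("T_atp_hc", c(atp_h = -1, adp_c = -1, adp_h = 1, atp_c = 1),
          name = "chloroplast ATP/ADP translocase")
  add_rxn("T_atp_mc", c(atp_m = -1, adp_c = -1, adp_m = 1, atp_c = 1),
          name = "mitochondrial ATP/ADP translocase")
  add_rxn("T_pi_ch", c(pi_c = -1, pi_h = 1), -1000)
  add_rxn("T_pi_cm", c(pi_c = -1, pi_m = 1), -1000)

  # energy subsystem
  add_rxn("LEF", c(photon_h = -8, h2o_h = -2, nadp_h = -2, adp_h = -2.57,
                   pi_h = -2.57, nadph_h = 2, o2_h = 1, atp_h = 2.57),
          name = "linear electron flow (PSII+PSI+ATP synthase)")
  add_rxn("CEF", c(photon_h = -2, adp_h = -1, pi_h = -1, atp_h = 1),
          name = "cyclic electron flow around PSI")
  add_rxn("RESP", c(nadh_m = -1, o2_m = -0.5, adp_m = -1.5, pi_m = -1.5,
                    nad_m = 1, atp_m = 1.5),
          name = "mitochondrial respiration (oxidative phosphorylation)")
  add_rxn("AOX", c(nadh_m = -1, o2_m = -0.5, nad_m = 1),
          name = "alternative oxidase")
  # organelle redox shuttle: two legs through a malate-like carrier
  add_rxn("SHUTTLE_EXPORT", c(nadph_h = -1, oxc_c = -1, nadp_h = 1, redc_c = 1),
          name = "redox export from chloroplast (carrier reduction)")
  add_rxn("SHUTTLE_IMPORT", c(redc_c = -1, nad_m = -1, oxc_c = 1, nadh_m = 1),
          name = "redox import into mitochondria (carrier oxidation)")
  add_rxn("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
          lb = config$ngam, name = "ATP maintenance")
  add_rxn("MEHLER", c(o2_h = -0.5, nadph_h = -1, nadp_h = 1),
          name = "Mehler reaction (water-water cycle)")
  add_rxn("PTOX", c(o2_h = -0.5, nadph_h = -1, nadp_h = 1),
          name = "plastid terminal oxidase")
  add_rxn("PHOTORESP", c(cfix_h = -1, o2_h = -1, hco3_h = 1),
          name = "photorespiratory carbon loss")

  # carbon fixation and nitrate reduction
  add_rxn("CBB", c(hco3_h = -1, atp_h = -3, nadph_h = -2, cfix_h = 1,
                   adp_h = 3, pi_h = 3, nadp_h = 2),
          name = "carbon fixation (Calvin cycle lump)")
  if (config$n_core_pathways > 1)
    for (i in 2:config$n_core_pathways)
      add_rxn(paste0("CBB", i),
              c(hco3_h = -1, atp_h = -4, nadph_h = -2, cfix_h = 1,
                adp_h = 4, pi_h = 4, nadp_h = 2),
              name = sprintf("alternative carbon fixation route %d", i))
  add_rxn("NR", c(no3_h = -1, nadph_h = -4, nh3_h = 1, nadp_h = 4),
          name = "nitrate reduction to ammonium")

  # monomer synthesis
  if (full) {
    montab <- monomer_table()
  } else {
    montab <- compact_monomer_defs()
    montab$molar_mass <- vapply(montab$formula, formula_mass, numeric(1))
  }
  atp_cost <- c(amino_acid = 2, sugar = 1, lipid = 4, tag = 4, pigment = 8,
                dna = 5, rna = 5,
                protein = 2, carbohydrate = 1)
  syn_rxns <- character(0)
  for (i in seq_len(nrow(montab))) {
    mon <- montab$monomer[i]
    fc <- formula_counts(montab$formula[i])
    k <- unname(atp_cost[[montab$class[i]]])
    mid <- add_met(mon, "c", montab$formula[i])
    st <- c(setNames(-fc[["C"]], "cfix_c"),
            if (fc[["N"]] > 0) setNames(-fc[["N"]], "nh3_c"),
            setNames(-k, "atp_c"), setNames(k, "adp_c"),
            setNames(k - fc[["P"]], "pi_c"),
            setNames(1, mid))
    st <- st[st != 0]
    syn_rxns <- c(syn_rxns, add_rxn(paste0("SYN_", mon), st,
                                    name = paste("synthesis of", mon)))
  }

  # dormant two-step compensatory routes for a sample of monomers
  n_alt <- min(config$n_alternative_routes, nrow(montab))
  alt_targets <- if (n_alt > 0) sort(sample(montab$monomer, n_alt)) else character(0)
  for (mon in alt_targets) {
    i <- match(mon, montab$monomer)
    pre <- add_met(paste0("pre_", mon), "c", montab$formula[i])
    st1 <- stoich[[paste0("SYN_", mon)]]
    names(st1)[names(st1) == paste0(mon, "_c")] <- pre
    add_rxn(paste0("SYNALT1_", mon), st1, balance = FALSE,
            name = paste("alternative route to", mon, "(step 1)"))
    add_rxn(paste0("SYNALT2_", mon), setNames(c(-1, 1), c(pre, paste0(mon, "_c"))),
            balance = FALSE,
            name = paste("alternative route to", mon, "(step 2)"))
  }

  # biomass component equations and overall biomass (stoichiometry filled in
  # by update_model_params)
  comp_names <- c("protein", "carbohydrate", "lipid", "dna", "rna", "pigment")
  comp_mets <- vapply(comp_names, function(nm)
    add_met(paste0(nm, "_bm"), "c", "", paste(nm, "component (1 g)")),
    character(1))
  comp_rxns <- vapply(comp_names, function(nm)
    add_rxn(paste0("BM_", nm), setNames(1, comp_mets[[nm]]), balance = FALSE,
            name = paste(nm, "assembly")), character(1))
  add_rxn("BIOMASS", setNames(-1, comp_mets[["protein"]]), balance = FALSE,
          name = "biomass (growth)")

  met_df <- do.call(rbind, mets)
  rx_df <- do.call(rbind, rx)

  # gene-reaction rules: isozyme (OR), complex (AND), single-gene
  eligible <- c(syn_rxns,
                grep("^SYNALT", rx_df$id, value = TRUE),
                "LEF", "CEF", "RESP", "AOX", "SHUTTLE_EXPORT",
                "SHUTTLE_IMPORT", "NR", "ATPM",
                grep("^CBB", rx_df$id, value = TRUE),
                "MEHLER", "PTOX", "PHOTORESP",
                "T_atp_hc", "T_atp_mc", "T_nh3_hc", "T_cfix_hc")
  eligible <- sample(eligible)
  n_iso <- min(config$n_isozyme_reactions, length(eligible))
  n_cpx <- min(config$n_complex_reactions, max(0, length(eligible) - n_iso))
  gpr <- list(); gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("g%03d", gene_counter)
  }
  idx <- 0L
  for (r in eligible) {
    idx <- idx + 1L
    if (idx <= n_iso) {
      gpr[[r]] <- list(op = "or", args = list(new_gene(), new_gene()))
    } else if (idx <= n_iso + n_cpx) {
      gpr[[r]] <- list(op = "and", args = list(new_gene(), new_gene()))
    } else {
      gpr[[r]] <- new_gene()
    }
  }

  genes <- sprintf("g%03d", seq_len(gene_counter))
  n_allele <- floor(config$allele_fraction * length(genes))
  allele_genes <- if (n_allele > 0) sort(sample(genes, n_allele)) else character(0)
  allele_table <- data.frame(gene_id = allele_genes,
                             allele_id = paste0(allele_genes, "v"),
                             stringsAsFactors = FALSE)

  model <- metabolic_model(
    met_df, rx_df, stoich, gpr = gpr, compartments = comp,
    objective = "BIOMASS",
    roles = list(carbon_uptake = "EX_hco3", nitrate_uptake = "EX_no3",
                 phosphate_uptake = "EX_po4", photon_uptake = "EX_photon",
                 atp_maintenance = "ATPM", cyclic_psi = "CEF",
                 mito_atp = "RESP", mito_atp_synthase = "RESP", aox = "AOX",
                 redox_shuttle = c("SHUTTLE_EXPORT", "SHUTTLE_IMPORT"),
                 chloro_atp = "LEF",
                 mehler = "MEHLER", ptox = "PTOX",
                 photorespiration = "PHOTORESP",
                 biomass_components = unname(comp_rxns)),
    met_roles = list(atp = "atp_c", adp = "adp_c", pi = "pi_c",
                     nadph = "nadph_h", nadp = "nadp_h", h = "h_h",
                     h2o = "h2o_c"),
    id = sprintf("synth_%s_seed%d", config$composition, config$seed))

  model$biomass_spec <- list(
    mode = if (full) "full" else "compact",
    monomer_mets = setNames(paste0(montab$monomer, "_c"), montab$monomer),
    component_rxns = comp_rxns,
    component_mets = comp_mets,
    biomass_rxn = "BIOMASS",
    energy = c(atp = "atp_c", adp = "adp_c", pi = "pi_c", h = "h_c",
               h2o = "h2o_c"),
    monomer_masses = setNames(montab$molar_mass, montab$monomer),
    compact_monomers = if (!full)
      setNames(as.list(montab$monomer), montab$class))

  model <- update_model_params(model, config$params)

  truth_hint <- list(
    dormant_alternatives = grep("^SYNALT", rx_df$id, value = TRUE),
    backed_by_alternative = paste0("SYN_", alt_targets),
    dissipation = c("MEHLER", "PTOX", "PHOTORESP"),
    expected_essential = c("BIOMASS", comp_rxns, "EX_hco3", "T_hco3"),
    isozyme_or_genes = unlist(lapply(gpr, function(g)
      if (is.list(g) && g$op == "or") unlist(g$args))),
    complex_and_genes = unlist(lapply(gpr, function(g)
      if (is.list(g) && g$op == "and") unlist(g$args))))

  list(model = model, params = config$params, allele_table = allele_table,
       structure_hint = truth_hint)
}

#' Brute-force deletion oracle
#'
#' Exhaustively re-solves the model after deleting every reaction (or
#' knocking out every gene) one at a time, with no shortcuts: inactive
#' targets are re-solved like all others. Used as the independent ground
#' truth the optimised deletion scan is validated against.
#'
#' @param model A `metabolic_model` (at most 200 reactions).
#' @param what `"reactions"` or `"genes"`.
#' @param method `"fba"` (re-optimised parsimonious FBA) or `"moma"`.
#' @param settings A [solver_settings()] object.
#' @param allele_table Optional allele pair table applied (via
#'   [augment_with_alleles()]) before a gene scan.
#' @param photon_constraint Apply the photon-uptake window around the
#'   reference solution (see [constrain_photons()]) as in the deletion scan.
#' @return data.frame with one row per target: growth, growth ratio and
#'   robustness class.
#' @export
brute_force_deletions <- function(model, what = c("reactions", "genes"),
                                  method = c("fba", "moma"),
                                  settings = solver_settings(),
                                  allele_table = NULL,
                                  photon_constraint = TRUE) {
  what <- match.arg(what)
  method <- match.arg(method)
  if (nrow(model$reactions) > 200)
    stop("brute-force oracle is limited to models with <= 200 reactions")
  if (!is.null(allele_table) && nrow(allele_table) > 0)
    model <- augment_with_alleles(model, allele_table)
  ref <- solve_pfba(model, settings)
  if (ref$status != "optimal") stop("intact model is not solvable")
  base <- if (photon_constraint &&
              length(role_rxns(model, "photon_uptake", required = FALSE)))
    constrain_photons(model, ref) else model
  targets <- if (what == "reactions") model$reactions$id else model$genes
  rows <- lapply(targets, function(tg) {
    mod <- if (what == "reactions") knockout_reactions(base, tg)
           else knockout_reactions(base, reactions_disabled_by(base, tg))
    sol <- if (method == "fba") solve_pfba(mod, settings)
           else solve_moma(mod, ref, settings)
    g <- if (sol$status == "optimal") sol$objective_value else 0
    cls <- classify_growth(ref$objective_value, g, settings)
    data.frame(target = tg, kind = sub("s$", "", what), method = method,
               growth_wt = ref$objective_value, growth_del = g,
               growth_ratio = g / ref$objective_value,
               robustness_class = cls$class, near_essential = cls$near_essential,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
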