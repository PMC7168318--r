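# Biomass construction from biochemical composition parameters.
#
# A cell's biochemical composition is summarised by 69 named parameters:
# five pigments (pg/cell), three nucleic-acid descriptors (GC%, genome size,
# RNA:DNA), 19 lipid species (mol/gDW), 20 amino acids (g/gDW), six
# macromolecular totals (g/gDW), two storage proportions (% of carbohydrate
# as glucan, % of lipid as triacylglycerol), nine sugars (mol/gDW), two
# uptake stoichiometry ratios (C:N, N:P, mol/mol), the carbon uptake rate
# (mmol gDW^-1 h^-1), and two per-cell scalars (C and dry weight, pg/cell).
# These are converted to mass-normalised stoichiometric coefficients: within
# each macromolecular component the monomer coefficients are normalised so
# one flux unit consumes exactly 1 g of monomers, and the component mass
# fractions are renormalised to sum to 1, so unit biomass flux consumes
# 1 gDW of precursors.

element_masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974)

formula_counts <- function(formula) {
  out <- setNames(numeric(5), names(element_masses))
  if (is.na(formula) || !nzchar(formula)) return(out)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  for (tk in toks) {
    el <- sub("[0-9.]*$", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(out)) stop("unsupported element '", el, "' in ", formula)
    out[el] <- out[el] + n
  }
  out
}

formula_mass <- function(formula) sum(formula_counts(formula) * element_masses)

amino_acid_ids <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly",
                    "hist", "ile", "leu", "lys", "met", "phe", "pro", "ser",
                    "thr", "trp", "tyr", "val")
sugar_ids <- c("glucose", "galac", "mann", "xylu", "arab", "fuco", "rhamn",
               "glucur", "mannsul")
lipid_ids <- sprintf("lip%02d", 1:19)
pigment_ids <- c("chla", "chlc", "fucoxan", "bcarot", "dd")
dna_ids <- c("damp", "dcmp", "dgmp", "dtmp")
rna_ids <- c("amp", "cmp", "gmp", "ump")

#' Monomer table: formulas and molar masses
#'
#' The biomass precursor monomers used by [build_biomass()]: 20 amino acids,
#' 9 sugars, 19 membrane/structural lipid species plus triacylglycerol, 5
#' pigments, and the 8 (deoxy)nucleoside monophosphates. Formulas are
#' restricted to C/H/N/O/P (sulfur-containing monomers carry an
#' oxygen-substituted surrogate formula so that synthetic models balance
#' over a 5-element chemistry).
#'
#' @return data.frame with columns `monomer`, `class`, `formula`,
#'   `molar_mass` (g/mol).
#' @export
monomer_table <- function() {
  aa_formula <- c(ala = "C3H7NO2", arg = "C6H14N4O2", asn = "C4H8N2O3",
                  asp = "C4H7NO4", cys = "C3H7NO3", gln = "C5H10N2O3",
                  glu = "C5H9NO4", gly = "C2H5NO2", hist = "C6H9N3O2",
                  ile = "C6H13NO2", leu = "C6H13NO2", lys = "C6H14N2O2",
                  met = "C5H11NO3", phe = "C9H11NO2", pro = "C5H9NO2",
                  ser = "C3H7NO3", thr = "C4H9NO3", trp = "C11H12N2O2",
                  tyr = "C9H11NO3", val = "C5H11NO2")
  sugar_formula <- c(glucose = "C6H12O6", galac = "C6H12O6", mann = "C6H12O6",
                     xylu = "C5H10O5", arab = "C5H10O5", fuco = "C6H12O5",
                     rhamn = "C6H12O5", glucur = "C6H10O7", mannsul = "C6H12O9")
  lip_formula <- setNames(vapply(1:19, function(i) {
    C <- 34 + i; H <- 2 * C - 10
    O <- 6 + (i %% 3); P <- if (i <= 8) 1 else 0; N <- if (i <= 4) 1 else 0
    paste0("C", C, "H", H, if (N) paste0("N", N) else "", "O", O,
           if (P) paste0("P", P) else "")
  }, character(1)), lipid_ids)
  pig_formula <- c(chla = "C55H72N4O5", chlc = "C35H30N4O5",
                   fucoxan = "C42H58O6", bcarot = "C40H56", dd = "C40H54O3")
  dna_formula <- c(damp = "C10H14N5O6P", dcmp = "C9H14N3O7P",
                   dgmp = "C10H14N5O7P", dtmp = "C10H15N2O8P")
  rna_formula <- c(amp = "C10H14N5O7P", cmp = "C9H14N3O8P",
                   gmp = "C10H14N5O8P", ump = "C9H13N2O9P")
  f <- c(aa_formula, sugar_formula, lip_formula, tag = "C55H98O6",
         pig_formula, dna_formula, rna_formula)
  cls <- c(rep("amino_acid", 20), rep("sugar", 9), rep("lipid", 19), "tag",
           rep("pigment", 5), rep("dna", 4), rep("rna", 4))
  data.frame(monomer = names(f), class = cls, formula = unname(f),
             molar_mass = vapply(f, formula_mass, numeric(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

default_monomer_masses <- function() {
  tb <- monomer_table()
  setNames(tb$molar_mass, tb$monomer)
}

#' Read a monomer molar-mass table
#'
#' @param path TSV file with columns `monomer_id` and `molar_mass` (g/mol).
#' @return Named numeric vector of molar masses.
#' @export
read_monomer_masses <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("monomer_id", "molar_mass") %in% names(tb)))
  setNames(tb$molar_mass, tb$monomer_id)
}

#' The 69-parameter registry
#'
#' @return data.frame with `name`, `group`, `default`, `unit` and, for
#'   per-monomer parameters, the monomer id the parameter feeds.
#' @export
parameter_registry <- function() {
  reg <- rbind(
    data.frame(name = pigment_ids, group = "pigment",
               default = c(0.14, 0.030, 0.060, 0.0040, 0.0090),
               unit = "pg/cell", monomer = pigment_ids),
    data.frame(name = c("gcprop", "genomesize", "rnadna"), group = "nucleic",
               default = c(40, 6.1e7, 8.0),
               unit = c("% of bases", "bases", "g/g"), monomer = NA),
    data.frame(name = lipid_ids, group = "lipid",
               default = c(0.12, 0.10, 0.09, 0.08, 0.07, 0.06, 0.055, 0.05,
                           0.045, 0.04, 0.035, 0.03, 0.028, 0.025, 0.022,
                           0.02, 0.016, 0.013, 0.010),
               unit = "mol/gDW", monomer = lipid_ids),
    data.frame(name = amino_acid_ids, group = "amino_acid",
               default = c(0.070, 0.048, 0.030, 0.075, 0.008, 0.030, 0.080,
                           0.050, 0.015, 0.035, 0.065, 0.045, 0.018, 0.040,
                           0.040, 0.045, 0.040, 0.010, 0.025, 0.045),
               unit = "g/gDW", monomer = amino_acid_ids),
    data.frame(name = c("totalprot", "totalcarb", "totallip", "totaldna",
                        "totalrna", "totalpigm"), group = "total",
               default = c(0.46, 0.31, 0.21, 0.0022, 0.018, 0.016),
               unit = "g/gDW", monomer = NA),
    data.frame(name = c("propglu", "proptga"), group = "storage",
               default = c(30, 20),
               unit = c("% of carbohydrate", "% of lipid"), monomer = NA),
    data.frame(name = sugar_ids, group = "sugar",
               default = c(0, 0.12, 0.22, 0.10, 0.11, 0.15, 0.13, 0.10, 0.32),
               unit = "mol/gDW", monomer = sugar_ids),
    data.frame(name = c("cn", "np", "ps"), group = "constraint",
               default = c(5.7, 10, 0.78),
               unit = c("mol/mol", "mol/mol", "mmol/gDW/h"), monomer = NA),
    data.frame(name = c("ccell", "dwcell"), group = "cell",
               default = c(7.5, 15), unit = "pg/cell", monomer = NA)
  )
  rownames(reg) <- NULL
  reg
}

#' Construct a composition parameter set
#'
#' @param values Named numeric vector or list covering all 69 parameter
#'   names of [parameter_registry()]; omitted entries take their defaults.
#' @return Named numeric vector of class `composition_params`.
#' @export
#' @examples
#' p <- composition_params()        # nominal values
#' p[["cn"]]
composition_params <- function(values = NULL) {
  reg <- parameter_registry()
  p <- setNames(reg$default, reg$name)
  if (!is.null(values)) {
    values <- unlist(values)
    unk <- setdiff(names(values), reg$name)
    if (length(unk)) stop("unknown parameters: ", paste(unk, collapse = ", "))
    p[names(values)] <- values
  }
  validate_params(p)
  structure(p, class = "composition_params")
}

validate_params <- function(p) {
  reg <- parameter_registry()
  miss <- setdiff(reg$name, names(p))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  nonpos <- names(p)[p <= 0 & names(p) != "glucose"]
  if (length(nonpos)) stop("parameters must be positive: ",
                           paste(nonpos, collapse = ", "))
  if (p[["glucose"]] < 0) stop("glucose must be >= 0")
  if (p[["gcprop"]] <= 0 || p[["gcprop"]] >= 100)
    stop("gcprop must lie in (0, 100)")
  for (nm in c("propglu", "proptga"))
    if (p[[nm]] <= 0 || p[[nm]] >= 100) stop(nm, " must lie in (0, 100)")
  invisible(p)
}

#' Scale selected composition parameters
#'
#' @param params A `composition_params` set.
#' @param multipliers Named numeric vector of positive factors applied to
#'   the named parameters; all other entries are untouched.
#' @return A new `composition_params` set.
#' @export
perturb_params <- function(params, multipliers) {
  unk <- setdiff(names(multipliers), names(params))
  if (length(unk)) stop("unknown parameters: ", paste(unk, collapse = ", "))
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  params[names(multipliers)] <- params[names(multipliers)] * multipliers
  validate_params(params)
  params
}

# ATP cost of polymerisation per mmol of monomer, and growth-associated
# maintenance (mmol ATP per gDW); conventions carried over from template
# photoautotroph reconstructions and held fixed.
polymerization_costs <- function() {
  list(per_monomer = c(protein = 4.3, carbohydrate = 1.0, lipid = 1.0,
                       dna = 3.4, rna = 2.4, pigment = 0),
       gam = 30)
}

#' Build biomass stoichiometry from composition parameters
#'
#' Converts the parameter set into mass-normalised monomer coefficients for
#' six macromolecular component equations (protein, carbohydrate, lipid,
#' DNA, RNA, pigment) and renormalised component mass fractions. DNA base
#' composition follows the GC proportion (G = C = GC/2, A = T = (100-GC)/2
#' of bases; RNA uses the same proportions with uracil); glucan and
#' triacylglycerol enter the carbohydrate and lipid equations as
#' carbon-storage sub-components at their stated mass proportions. Each
#' component equation consumes exactly 1 g of monomers per flux unit, and
#' the component fractions sum to 1, so unit biomass flux consumes 1 gDW.
#'
#' @param params A [composition_params()] set.
#' @param monomer_masses Named molar masses (g/mol); defaults to the
#'   built-in [monomer_table()].
#' @return An object of class `biomass_stoichiometry`: per-component
#'   coefficient maps (mmol per g of component), renormalised mass
#'   fractions, storage sub-fractions and polymerisation energy terms.
#' @export
build_biomass <- function(params, monomer_masses = default_monomer_masses()) {
  validate_params(params)
  M <- monomer_masses
  need <- c(amino_acid_ids, sugar_ids, lipid_ids, "tag", pigment_ids,
            dna_ids, rna_ids)
  miss <- setdiff(need, names(M))
  if (length(miss)) stop("missing monomer masses: ", paste(miss, collapse = ", "))

  mass_norm <- function(weights) {        # mass fractions -> mmol per g
    w <- weights / sum(weights)
    1000 * w / M[names(w)]
  }

  protein <- mass_norm(setNames(as.numeric(params[amino_acid_ids]),
                                amino_acid_ids))

  w_glucan <- params[["propglu"]] / 100
  sug <- setNames(as.numeric(params[sugar_ids]), sugar_ids)
  sug_mass <- sug * M[sugar_ids]
  structural <- mass_norm(sug_mass[sug_mass > 0]) * (1 - w_glucan)
  carbohydrate <- structural
  glucan_coef <- 1000 * w_glucan / M[["glucose"]]
  carbohydrate["glucose"] <- glucan_coef +
    if ("glucose" %in% names(structural)) structural[["glucose"]] else 0

  w_tag <- params[["proptga"]] / 100
  lip <- setNames(as.numeric(params[lipid_ids]), lipid_ids)
  lipid <- c(mass_norm(lip * M[lipid_ids]) * (1 - w_tag),
             tag = unname(1000 * w_tag / M[["tag"]]))

  gc <- params[["gcprop"]] / 100
  dna_frac <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), dna_ids)
  dna <- mass_norm(dna_frac * M[dna_ids])
  rna_frac <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), rna_ids)
  rna <- mass_norm(rna_frac * M[rna_ids])

  pig <- setNames(as.numeric(params[pigment_ids]) / params[["dwcell"]],
                  pigment_ids)                    # pg/cell -> g/gDW
  pigment <- mass_norm(pig)

  totals <- c(protein = params[["totalprot"]], carbohydrate = params[["totalcarb"]],
              lipid = params[["totallip"]], dna = params[["totaldna"]],
              rna = params[["totalrna"]], pigment = params[["totalpigm"]])
  fractions <- totals / sum(totals)

  comp <- list(protein = protein, carbohydrate = carbohydrate, lipid = lipid,
               dna = dna, rna = rna, pigment = pigment)
  for (nm in names(comp)) {
    chk <- sum(comp[[nm]] * M[names(comp[[nm]])]) / 1000
    if (abs(chk - 1) > 1e-6)
      stop("component '", nm, "' fails mass normalisation: ", chk)
  }

  pc <- polymerization_costs()
  structure(list(components = comp,
                 fractions = fractions,
                 raw_total = sum(totals),
                 storage = c(glucan = unname(w_glucan), tag = unname(w_tag)),
                 storage_coefficients = c(glucan_glucose = unname(glucan_coef),
                                          tag = unname(1000 * w_tag / M[["tag"]])),
                 poly_atp = pc$per_monomer, gam = pc$gam,
                 monomer_masses = M[need]),
            class = "biomass_stoichiometry")
}

#' @export
print.biomass_stoichiometry <- function(x, ...) {
  cat("biomass stoichiometry\n")
  cat("  component mass fractions (renormalised from",
      sprintf("%.4f", x$raw_total), "g/gDW):\n")
  for (nm in names(x$fractions))
    cat(sprintf("    %-13s %.5f  (%d monomers)\n", nm, x$fractions[[nm]],
                length(x$components[[nm]])))
  cat(sprintf("  storage: glucan %.0f%% of carbohydrate, TAG %.0f%% of lipid\n",
              100 * x$storage[["glucan"]], 100 * x$storage[["tag"]]))
  invisible(x)
}

set_uptake_bound <- function(model, rxn, rate) {
  st <- model$stoichiometry[[rxn]]
  if (length(st) != 1L)
    stop("uptake reaction '", rxn, "' is not a single-metabolite exchange")
  if (st > 0) model <- set_bounds(model, rxn, 0, rate)
  else model <- set_bounds(model, rxn, -rate, 0)
  model
}

#' Apply nutrient uptake constraints from composition parameters
#'
#' Fixes the bicarbonate uptake bound at the carbon uptake rate `ps`, the
#' nitrogen-source bound at `ps / (C:N)` and the phosphorus-source bound at
#' `N_bound / (N:P)`, as upper limits on the uptake direction of the
#' reactions tagged `carbon_uptake`, `nitrate_uptake` and
#' `phosphate_uptake`.
#'
#' @param model A `metabolic_model` with the three uptake role tags.
#' @param params A [composition_params()] set.
#' @return The constrained model.
#' @export
apply_uptake_constraints <- function(model, params) {
  validate_params(params)
  c_up <- params[["ps"]]
  n_up <- c_up / params[["cn"]]
  p_up <- n_up / params[["np"]]
  model <- set_uptake_bound(model, role_rxns(model, "carbon_uptake")[1], c_up)
  model <- set_uptake_bound(model, role_rxns(model, "nitrate_uptake")[1], n_up)
  model <- set_uptake_bound(model, role_rxns(model, "phosphate_uptake")[1], p_up)
  model
}

#' Rebuild a model's biomass reactions from composition parameters
#'
#' Uses the model's `biomass_spec` (created by the synthetic-model
#' generator or set by the user) to rewrite the stoichiometry of the six
#' component equations and the overall biomass reaction, and re-applies the
#' uptake constraints. This is the hook the sensitivity analyses use to
#' evaluate growth as a function of the parameters.
#'
#' @param model A `metabolic_model` carrying a `biomass_spec`.
#' @param params A [composition_params()] set.
#' @return The updated model.
#' @export
update_model_params <- function(model, params) {
  spec <- model$biomass_spec
  if (is.null(spec)) stop("model has no biomass_spec; cannot rebuild biomass")
  en <- spec$energy
  pc <- polymerization_costs()

  if (spec$mode == "full") {
    bs <- build_biomass(params, spec$monomer_masses)
    comps <- bs$components
    fractions <- bs$fractions
  } else {
    totals <- c(protein = params[["totalprot"]],
                carbohydrate = params[["totalcarb"]],
                lipid = params[["totallip"]], dna = params[["totaldna"]],
                rna = params[["totalrna"]], pigment = params[["totalpigm"]])
    fractions <- totals / sum(totals)
    comps <- lapply(spec$compact_monomers, function(mm)
      setNames(1000 / spec$monomer_masses[[mm]], mm))
  }

  for (nm in names(spec$component_rxns)) {
    rid <- spec$component_rxns[[nm]]
    coefs <- comps[[nm]]
    mets <- spec$monomer_mets[names(coefs)]
    cost <- pc$per_monomer[[nm]] * sum(coefs)
    st <- setNames(-as.numeric(coefs), mets)
    if (cost > 0) {
      st[en[["atp"]]] <- -cost
      st[en[["h2o"]]] <- -cost
      st[en[["adp"]]] <- cost
      st[en[["pi"]]] <- cost
      st[en[["h"]]] <- cost
    }
    st[spec$component_mets[[nm]]] <- 1
    model$stoichiometry[[rid]] <- st[st != 0 | names(st) == spec$component_mets[[nm]]]
  }

  st <- setNames(-as.numeric(fractions), spec$component_mets[names(fractions)])
  gam <- pc$gam
  st[en[["atp"]]] <- -gam
  st[en[["h2o"]]] <- -gam
  st[en[["adp"]]] <- gam
  st[en[["pi"]]] <- gam
  st[en[["h"]]] <- gam
  model$stoichiometry[[spec$biomass_rxn]] <- st

  model <- apply_uptake_constraints(model, params)
  model$params <- params
  model
}

#' Read composition parameters from YAML or TSV
#'
#' @param path A `.yml`/`.yaml` file of named scalars, or a TSV with
#'   columns `name` and `value`.
#' @return A [composition_params()] set.
#' @export
read_composition_params <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    vals <- unlist(yaml::read_yaml(path))
  } else {
    tb <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "value") %in% names(tb)))
    vals <- setNames(tb$value, tb$name)
  }
  composition_params(vals)
}

#' Write composition parameters
#'
#' @param params A [composition_params()] set.
#' @param path Output path; format chosen by extension as in
#'   [read_composition_params()].
#' @export
write_composition_params <- function(params, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(as.list(unclass(params)), path)
  } else {
    write.table(data.frame(name = names(params), value = as.numeric(params)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
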