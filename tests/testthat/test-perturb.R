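settings <- solver_settings()

test_that("photon constraint builds the 1.5-fold window", {
  g <- generate_model(synth_config(seed = 1, composition = "compact"),
                      qc = FALSE)
  m <- g$model
  fl <- setNames(numeric(nrow(m$reactions)), m$reactions$id)
  fl[["EX_photon"]] <- 9
  ref <- robustfba:::new_flux_solution(fl, "optimal", "BIOMASS", "pfba",
                                       settings)
  m2 <- constrain_photons(m, ref)
  i <- match("EX_photon", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], 6)
  expect_equal(m2$reactions$upper_bound[i], 13.5)
  # degenerate reference and idempotence
  fl[["EX_photon"]] <- 0
  ref0 <- robustfba:::new_flux_solution(fl, "optimal", "BIOMASS", "pfba",
                                        settings)
  m0 <- constrain_photons(m, ref0)
  i <- match("EX_photon", m0$reactions$id)
  expect_equal(m0$reactions$lower_bound[i], 0)
  expect_equal(m0$reactions$upper_bound[i], 0)
  m3 <- constrain_photons(m2, ref)
  expect_equal(m3$reactions$lower_bound, m2$reactions$lower_bound)
  expect_equal(m3$reactions$upper_bound, m2$reactions$upper_bound)
})

test_that("growth classification bands are exclusive and exhaustive", {
  cl <- function(g) classify_growth(1, g, settings)
  expect_equal(cl(0)$class, "essential")
  expect_equal(cl(1e-7)$class, "essential")
  expect_equal(cl(0.995)$class, "robust")
  expect_equal(cl(1.0)$class, "robust")
  expect_equal(cl(0.5)$class, "intermediate")
  mid <- cl(0.005)       # >= 99% inhibition but detectable growth
  expect_equal(mid$class, "intermediate")
  expect_true(mid$near_essential)
})

test_that("deleting the biomass reaction is essential; dormant-route deletions are robust with compensation", {
  g <- generate_model(synth_config(seed = 6, composition = "compact"))
  m <- g$model
  scan <- single_reaction_deletion(m, "fba", settings)
  df <- as.data.frame(scan)
  expect_equal(df$robustness_class[df$target == "BIOMASS"], "essential")
  expect_equal(df$growth_del[df$target == "BIOMASS"], 0)
  # reactions backed by a dormant alternative route are robust and their
  # deletion activates the backup (>= 1 newly active reaction)
  backed <- intersect(g$structure_hint$backed_by_alternative, df$target)
  expect_gt(length(backed), 0)
  act <- active_set(attr(scan, "reference"), settings)
  for (rid in intersect(backed, act)) {
    expect_equal(df$robustness_class[df$target == rid], "robust", info = rid)
    expect_gte(df$n_activated[df$target == rid], 1)
  }
  # inactive reactions are trivially robust
  inact <- setdiff(df$target, act)
  expect_true(all(df$robustness_class[df$target %in% inact] == "robust"))
  expect_true(all(df$growth_ratio[df$target %in% inact] == 1))
})

test_that("optimised scan matches the brute-force oracle across seeded models", {
  for (seed in 1:20) {
    g <- generate_model(synth_config(seed = seed, composition = "compact"),
                        qc = FALSE)
    oracle <- brute_force_deletions(g$model, "reactions", "fba", settings)
    scan <- single_reaction_deletion(g$model, "fba", settings)
    df <- as.data.frame(scan)[match(oracle$target, scan$target), ]
    expect_equal(df$robustness_class, oracle$robustness_class,
                 info = paste("seed", seed))
    expect_equal(df$growth_del, oracle$growth_del, tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("MOMA never exceeds re-optimised FBA growth, per target", {
  g <- generate_model(synth_config(seed = 8, composition = "compact"),
                      qc = FALSE)
  ref <- solve_pfba(g$model, settings)
  f <- single_reaction_deletion(g$model, "fba", settings, reference = ref)
  m <- single_reaction_deletion(g$model, "moma", settings, reference = ref)
  expect_equal(f$target, m$target)
  expect_true(all(m$growth_del <= f$growth_del + 1e-6))
})

test_that("gene knockouts honour GPR logic", {
  g <- generate_model(synth_config(seed = 9, composition = "compact"),
                      qc = FALSE)
  m <- g$model
  scan <- single_gene_deletion(m, "fba", settings)
  df <- as.data.frame(scan)
  ref <- attr(scan, "reference")
  act <- active_set(ref, settings)
  rscan <- single_reaction_deletion(m, "fba", settings, reference = ref)
  rdf <- as.data.frame(rscan)
  # single-gene rules: knocking out the gene of an essential active
  # reaction is essential; OR-isozyme genes are robust
  for (gene in df$target) {
    off <- reactions_disabled_by(m, gene)
    if (length(off) == 1 && gene %in% g$structure_hint$isozyme_or_genes) next
    if (length(off) == 1 && off %in% act) {
      expect_equal(df$robustness_class[df$target == gene],
                   rdf$robustness_class[rdf$target == off],
                   info = paste(gene, "->", off))
    }
  }
  iso <- intersect(g$structure_hint$isozyme_or_genes, df$target)
  expect_gt(length(iso), 0)
  expect_true(all(df$robustness_class[df$target %in% iso] == "robust"))
  # reaction-scan essential set contains the gene-induced essential set
  ess_genes <- df$target[df$robustness_class == "essential"]
  for (gene in ess_genes) {
    off <- reactions_disabled_by(m, gene)
    expect_true(any(rdf$robustness_class[rdf$target %in% off] == "essential" |
                      rdf$near_essential[rdf$target %in% off]) ||
                  length(off) > 1,
                info = gene)
  }
})

test_that("allele augmentation never decreases the robust-gene count", {
  for (seed in 1:20) {
    g <- generate_model(synth_config(seed = seed, composition = "compact"),
                        qc = FALSE)
    if (nrow(g$allele_table) == 0) next
    s0 <- single_gene_deletion(g$model, "fba", settings)
    s1 <- single_gene_deletion(g$model, "fba", settings,
                               allele_table = g$allele_table)
    n0 <- sum(s0$robustness_class == "robust" & s0$active_gene)
    n1 <- sum(s1$robustness_class == "robust" & s1$active_gene)
    expect_gte(n1, n0)
  }
})

test_that("classification is invariant to target iteration order", {
  g <- generate_model(synth_config(seed = 10, composition = "compact"),
                      qc = FALSE)
  ref <- solve_pfba(g$model, settings)
  t1 <- g$model$reactions$id
  t2 <- rev(t1)
  s1 <- single_reaction_deletion(g$model, "fba", settings, reference = ref,
                                 targets = t1)
  s2 <- single_reaction_deletion(g$model, "fba", settings, reference = ref,
                                 targets = t2)
  d2 <- as.data.frame(s2)[match(t1, s2$target), ]
  expect_equal(as.data.frame(s1)$robustness_class, d2$robustness_class)
})

test_that("compensatory accounting counts activations and pathway flags", {
  g <- generate_model(synth_config(seed = 6, composition = "compact"))
  ref <- solve_pfba(g$model, settings)
  # identical solutions: all counters zero
  same <- compensatory_response(ref, ref, settings,
                                roles = c("cyclic_psi", "mito_atp"),
                                model = g$model)
  expect_equal(same$n_activated, 0)
  expect_equal(same$n_inactivated, 0)
  expect_false(any(same$pathway$activated))
  expect_false(any(same$pathway$increased))
  # forced reroute through a dormant two-step route activates both steps
  backed <- g$structure_hint$backed_by_alternative[1]
  mon <- sub("^SYN_", "", backed)
  mms <- solve_pfba(knockout_reactions(constrain_photons(g$model, ref),
                                       backed), settings)
  cmp <- compensatory_response(ref, mms, settings, model = g$model)
  steps <- paste0(c("SYNALT1_", "SYNALT2_"), mon)
  expect_true(all(abs(mms$fluxes[steps]) > 1e-9))
  expect_gte(cmp$n_activated, 2)
})

test_that("robustness summaries tally classes and build the cumulative curve", {
  fake <- data.frame(
    target = paste0("r", 1:10), kind = "reaction", method = "fba",
    growth_wt = 1,
    growth_del = c(rep(1, 7), rep(0, 3)),
    growth_ratio = c(rep(1, 7), rep(0, 3)),
    robustness_class = c(rep("robust", 7), rep("essential", 3)),
    near_essential = FALSE, n_activated = 0, n_inactivated = 0,
    stringsAsFactors = FALSE)
  class(fake) <- c("deletion_scan", class(fake))
  s <- summarize_robustness(fake)
  expect_equal(unname(s$counts["robust"]), 7)
  expect_equal(unname(s$counts["essential"]), 3)
  expect_equal(sum(s$counts), s$n_targets)
  # curve: 70% of targets at <= 1% inhibition, then steps to 100%
  expect_true(all(s$curve$inhibition_pct[s$curve$pct_targets <= 70] <= 1))
  expect_equal(s$curve$inhibition_pct[10], 100)
})
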