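# Small hand-built models used across the tests.

toy_chain_model <- function(bound = 2) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     compartment = c("e", "c", "c"))
  rx <- data.frame(id = c("EX_A", "R1", "BIO"),
                   lower_bound = 0, upper_bound = c(bound, 10, 10),
                   is_exchange = c(TRUE, FALSE, FALSE))
  st <- list(EX_A = c(A_e = 1), R1 = c(A_e = -1, B_c = 1), BIO = c(B_c = -1))
  metabolic_model(mets, rx, st, compartments = c(e = "medium", c = "cytosol"),
                  objective = "BIO", roles = list(carbon_uptake = "EX_A"),
                  id = "chain")
}

# two routes from A to B: R1 direct, R2a/R2b via intermediate (costlier L1)
parallel_routes_model <- function(bound = 2) {
  mets <- data.frame(id = c("A_e", "A_c", "I_c", "B_c"),
                     compartment = c("e", "c", "c", "c"))
  rx <- data.frame(id = c("EX_A", "T_A", "R1", "R2a", "R2b", "BIO"),
                   lower_bound = 0, upper_bound = c(bound, 10, 10, 10, 10, 10),
                   is_exchange = c(TRUE, rep(FALSE, 5)))
  st <- list(EX_A = c(A_e = 1), T_A = c(A_e = -1, A_c = 1),
             R1 = c(A_c = -1, B_c = 1),
             R2a = c(A_c = -1, I_c = 1), R2b = c(I_c = -1, B_c = 1),
             BIO = c(B_c = -1))
  metabolic_model(mets, rx, st, compartments = c(e = "medium", c = "cytosol"),
                  objective = "BIO", id = "parallel")
}

# isozyme-backed essential reaction: R1 has "gA or gB"
isozyme_toy_model <- function() {
  m <- toy_chain_model()
  m$gpr[["R1"]] <- parse_gpr("gA or gB")
  m$genes <- c("gA", "gB")
  m
}

# planted fault: free ATP generation cycle (GEN phosphorylates for nothing)
atp_cycle_fault_model <- function() {
  mets <- data.frame(id = c("atp_c", "adp_c", "pi_c"), compartment = "c")
  rx <- data.frame(id = c("GEN", "ATPM"),
                   lower_bound = 0, upper_bound = 1000,
                   is_exchange = FALSE)
  st <- list(GEN = c(adp_c = -1, pi_c = -1, atp_c = 1),
             ATPM = c(atp_c = -1, adp_c = 1, pi_c = 1))
  metabolic_model(mets, rx, st, compartments = c(c = "cytosol"),
                  objective = "ATPM",
                  roles = list(atp_maintenance = "ATPM"),
                  met_roles = list(atp = "atp_c"), id = "atp_fault")
}

# planted fault: stoichiometric error producing 2 B from 1 B
duplication_leak_model <- function() {
  mets <- data.frame(id = c("A_e", "B_c"), compartment = c("e", "c"))
  rx <- data.frame(id = c("EX_A", "R1", "DUP", "BIO"),
                   lower_bound = 0, upper_bound = c(2, 10, 1000, 10),
                   is_exchange = c(TRUE, FALSE, FALSE, FALSE))
  st <- list(EX_A = c(A_e = 1), R1 = c(A_e = -1, B_c = 1),
             DUP = c(B_c = 1),           # mass error: net production of B
             BIO = c(B_c = -1))
  metabolic_model(mets, rx, st, compartments = c(e = "medium", c = "cytosol"),
                  objective = "BIO", id = "leak_fault")
}

# hub toy for network comparisons: reaction RHUB touches a high-degree
# metabolite, chain-end reactions touch degree-1 metabolites
hub_toy_graph <- function() {
  mets <- data.frame(id = c("H", "a", "b", "c", "d", "x", "y"),
                     compartment = "c")
  rx <- data.frame(id = c("RHUB", "R1", "R2", "R3", "REND"),
                   lower_bound = -10, upper_bound = 10, is_exchange = FALSE)
  st <- list(RHUB = c(H = -1, a = 1), R1 = c(H = -1, b = 1),
             R2 = c(H = -1, c = 1), R3 = c(d = -1, H = 1),
             REND = c(x = -1, y = 1))
  model <- metabolic_model(mets, rx, st, compartments = c(c = "cytosol"),
                           objective = "RHUB", id = "hub")
  fluxes <- setNames(rep(1, 5), rx$id)
  sol <- robustfba:::new_flux_solution(fluxes, "optimal", "RHUB", "fba",
                                       solver_settings())
  list(model = model, solution = sol)
}

# random small model with a feasible positive-growth chain plus random
# side reactions; used for property tests at enumerable size
random_small_model <- function(seed, n_extra = 4) {
  set.seed(seed)
  mets <- data.frame(id = c("A_e", "M1", "M2", "M3"),
                     compartment = c("e", "c", "c", "c"))
  rx <- data.frame(id = c("EX_A", "R1", "BIO"),
                   lower_bound = 0, upper_bound = c(2, 10, 10),
                   is_exchange = c(TRUE, FALSE, FALSE))
  st <- list(EX_A = c(A_e = 1), R1 = c(A_e = -1, M1 = 1), BIO = c(M1 = -1))
  internal <- c("M1", "M2", "M3")
  for (i in seq_len(n_extra)) {
    pair <- sample(internal, 2)
    rev <- runif(1) < 0.4
    rid <- paste0("X", i)
    rx <- rbind(rx, data.frame(id = rid, lower_bound = if (rev) -5 else 0,
                               upper_bound = 5, is_exchange = FALSE))
    st[[rid]] <- setNames(c(-1, sample(1:2, 1)), pair)
  }
  metabolic_model(mets, rx, st, compartments = c(e = "medium", c = "cytosol"),
                  objective = "BIO", id = paste0("rand", seed))
}
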