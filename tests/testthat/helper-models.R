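## shared helpers: solved fixtures and a cached bank of random models

solve_fixture <- function(fx, ...) {
  lp <- build_lp(fx$model, fx$params, ...)
  sol <- solve_lp(lp)
  list(lp = lp, sol = sol, model = fx$model, params = fx$params)
}

pruned_fixture <- function(fx, ...) {
  s <- solve_fixture(fx, ...)
  s$pruned <- prune(s$model, s$sol, s$lp)
  s
}

## random-model bank, generated once per test run
.model_bank <- new.env(parent = emptyenv())

random_bank <- function(n = 10L, seed_base = 1000L, n_mets = 6, n_rxns = 10,
                        n_pools = 2) {
  key <- paste("bank", n, seed_base, n_mets, n_rxns, n_pools, sep = "_")
  if (is.null(.model_bank[[key]]))
    .model_bank[[key]] <- lapply(seq_len(n), function(i)
      random_ec_network(seed_base + i, n_mets, n_rxns, n_pools))
  .model_bank[[key]]
}

## a model whose optimum stays degenerate after pruning: two identical-cost
## routes, each capped at 1, jointly forced to carry 1.5 by a fixed demand,
## with pool slack -- every split (x, 1.5 - x), x in [0.5, 1], is optimal
make_degenerate <- function() {
  model <- ec_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("uptake", c(A = 1)),
      reaction("route1", c(A = -1, B = 1), upper_bound = 1,
               isozymes = list(isozyme(c(g1 = 1L), kcat_forward = 2))),
      reaction("route2", c(A = -1, B = 1), upper_bound = 1,
               isozymes = list(isozyme(c(g2 = 1L), kcat_forward = 2))),
      reaction("secretion", c(B = -1), objective_coefficient = 1)),
    gene_products = list(gene_product("g1", 1), gene_product("g2", 1)),
    pools = list(enzyme_pool("pool", c("g1", "g2"), 10)),
    fixed_fluxes = list(fixed_flux("secretion", 1.5)),
    id = "degenerate")
  list(model = model, params = NULL)
}

## stoichiometric matrix of a model (reaction-level)
stoich_matrix <- function(model) {
  mets <- names(model$metabolites)
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in model$reactions) S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

## rays-as-sets comparison up to scaling (columns both L1-normalized)
expect_same_rays <- function(got, want, tol = 1e-8) {
  expect_equal(ncol(got), ncol(want))
  if (ncol(got) == 0L) return(invisible(TRUE))
  expect_true(max(abs(got - want)) <= tol)
}

## a tiny COBRA-style JSON model written on the fly (synthetic stand-in for
## an externally assembled genome-scale model; two pools, two routes)
write_synthetic_cobra_json <- function(path) {
  j <- list(
    id = "synthetic_cobra",
    metabolites = list(
      list(id = "glc_c", compartment = "c"),
      list(id = "atp_c", compartment = "c"),
      list(id = "ac_c", compartment = "c")),
    reactions = list(
      list(id = "EX_glc", metabolites = list(glc_c = 1),
           lower_bound = 0, upper_bound = 1000, gene_reaction_rule = ""),
      list(id = "RESP", metabolites = list(glc_c = -1, atp_c = 3),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "b0001 and b0002"),
      list(id = "FERM", metabolites = list(glc_c = -1, atp_c = 2, ac_c = 1),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "b0003 or b0004"),
      list(id = "EX_ac", metabolites = list(ac_c = -1),
           lower_bound = 0, upper_bound = 1000, gene_reaction_rule = ""),
      list(id = "ATPM", metabolites = list(atp_c = -1),
           lower_bound = 0, upper_bound = 1000, gene_reaction_rule = ""),
      list(id = "BIOMASS", metabolites = list(atp_c = -1),
           lower_bound = 0, upper_bound = 1000,
           gene_reaction_rule = "b0005", objective_coefficient = 1)),
    genes = list(list(id = "b0001"), list(id = "b0002"),
                 list(id = "b0003"), list(id = "b0004"),
                 list(id = "b0005")))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  path
}
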