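#' Deterministic test-model generators
#'
#' Small enzyme-constrained models with closed-form or hand-checkable
#' optima, used throughout the test suite and runnable as study systems in
#' their own right.  Each generator returns `list(model, params)`: the
#' model references every tunable quantity (kcats, capacities, fixed
#' fluxes) through named parameters so the sensitivity machinery can
#' differentiate against all of them.
#'
#' * `make_chain()` -- linear pathway `uptake -> A -> B -> secretion` with
#'   one enzymatic step (kcat = 2 per h, molar mass 1 mg/mmol, pool
#'   capacity 5 mg/gDCW); the optimum is `v* = kcat E / w = 10` in closed
#'   form, with unit scaled sensitivities to both kcat and capacity.
#' * `make_branch()` -- two parallel enzymatic routes `A -> B` (kcat 1
#'   vs 2) competing for one shared pool (E = 1): the faster route wins the
#'   whole pool, the optimum is 2, and pruning removes exactly one reaction
#'   and one enzyme.
#' * `make_overflow()` -- a desk-scale overflow-metabolism model: a
#'   high-yield respiratory route whose enzyme lives in a `membrane` pool,
#'   a low-yield fermentative route spilling a byproduct with its enzyme in
#'   the `cytosol` pool, a biomass reaction consuming ATP, and an ATP
#'   maintenance reaction fixed at 1 (the inhomogeneous constraint).  Both
#'   pools bind at the optimum and both routes carry flux, so the optimum
#'   is a superposition of exactly two OFMs (respiratory and fermentative).
#'
#' @name fixtures
#' @return `list(model = ec_model, params = named numeric)`.
NULL

#' @rdname fixtures
#' @export
make_chain <- function() {
  model <- ec_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("uptake", c(A = 1)),
      reaction("conv", c(A = -1, B = 1),
               isozymes = list(isozyme(c(g1 = 1L),
                                       kcat_forward = param_ref("kcat_conv")))),
      reaction("secretion", c(B = -1), objective_coefficient = 1)),
    gene_products = list(gene_product("g1", molar_mass = 1)),
    pools = list(enzyme_pool("pool", "g1", param_ref("E_pool"))),
    id = "chain")
  list(model = model, params = c(kcat_conv = 2, E_pool = 5))
}

#' @rdname fixtures
#' @export
make_branch <- function() {
  model <- ec_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("uptake", c(A = 1)),
      reaction("route1", c(A = -1, B = 1),
               isozymes = list(isozyme(c(g1 = 1L),
                                       kcat_forward = param_ref("kcat_route1")))),
      reaction("route2", c(A = -1, B = 1),
               isozymes = list(isozyme(c(g2 = 1L),
                                       kcat_forward = param_ref("kcat_route2")))),
      reaction("secretion", c(B = -1), objective_coefficient = 1)),
    gene_products = list(gene_product("g1", 1), gene_product("g2", 1)),
    pools = list(enzyme_pool("pool", c("g1", "g2"), param_ref("E_pool"))),
    id = "branch")
  list(model = model,
       params = c(kcat_route1 = 1, kcat_route2 = 2, E_pool = 1))
}

#' @rdname fixtures
#' @details
#' Overflow constants (chosen once so the optimum mixes both modes with
#' both pools binding, and documented here): respiratory yield 3 ATP/Glc at
#' kcat 1, fermentative yield 2 ATP/Glc at kcat 10, biomass cost 1 ATP at
#' kcat 5, all molar masses 1, both capacities 1, maintenance 1.  The
#' optimum in closed form: `v_resp = 1` (membrane-limited),
#' `v_ferm = 1.2`, biomass `4.4`; OFM weights `lambda_resp = 5/9`,
#' `lambda_ferm = 4/9`.
#' @export
make_overflow <- function() {
  model <- ec_model(
    metabolites = list(metabolite("Glc"), metabolite("ATP"),
                       metabolite("Byp")),
    reactions = list(
      reaction("glc_uptake", c(Glc = 1)),
      reaction("resp", c(Glc = -1, ATP = 3),
               isozymes = list(isozyme(c(gR = 1L),
                                       kcat_forward = param_ref("kcat_resp")))),
      reaction("ferm", c(Glc = -1, ATP = 2, Byp = 1),
               isozymes = list(isozyme(c(gF = 1L),
                                       kcat_forward = param_ref("kcat_ferm")))),
      reaction("byp_secretion", c(Byp = -1)),
      reaction("biomass", c(ATP = -1), objective_coefficient = 1,
               isozymes = list(isozyme(c(gB = 1L),
                                       kcat_forward = param_ref("kcat_biomass")))),
      reaction("atpm", c(ATP = -1))),
    gene_products = list(gene_product("gR", 1), gene_product("gF", 1),
                         gene_product("gB", 1)),
    pools = list(
      enzyme_pool("membrane", "gR", param_ref("E_membrane")),
      enzyme_pool("cytosol", c("gF", "gB"), param_ref("E_cytosol"))),
    fixed_fluxes = list(fixed_flux("atpm", param_ref("atpm_flux"))),
    id = "overflow")
  list(model = model,
       params = c(kcat_resp = 1, kcat_ferm = 10, kcat_biomass = 5,
                  E_membrane = 1, E_cytosol = 1, atpm_flux = 1))
}

## run body with a private RNG stream, leaving the global stream untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Random enzyme-constrained network generator
#'
#' Generates a connected, mass-balanced, feasible network: a cost-free
#' uptake, a backbone chain of enzymatic conversions through all
#' metabolites, extra random enzymatic bypass reactions with small-integer
#' stoichiometry, and a cost-free secretion of the terminal metabolite as
#' objective.  kcats are log-uniform in \[0.1, 100\] per h, molar masses
#' uniform in \[10, 100\] mg/mmol, and pools randomly partition the
#' enzymes.  Generic (continuous) kcats make degenerate optima a
#' measure-zero event; the generator nevertheless rejection-samples until
#' the optimum is positive and, after pruning, unique, so property tests
#' are not polluted by ties.  The same seed always yields byte-identical
#' model JSON.
#'
#' @param seed integer seed (private RNG stream; the global stream is left
#'   untouched).
#' @param n_mets,n_rxns,n_pools size knobs (minimum 2 metabolites, 3
#'   reactions, 1 pool).
#' @param max_tries rejection cap.
#' @return `list(model = ec_model, params = named numeric)`.
#' @export
random_ec_network <- function(seed, n_mets = 6, n_rxns = 10, n_pools = 2,
                              max_tries = 1000L) {
  stopifnot(n_mets >= 2, n_rxns >= 3, n_pools >= 1)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      fx <- random_ec_candidate(n_mets, n_rxns, n_pools)
      lp <- tryCatch(build_lp(fx$model, fx$params), error = function(e) NULL)
      if (is.null(lp)) next
      sol <- solve_lp(lp)
      if (sol$status != "optimal" || sol$objective_value <= 1e-6) next
      pr <- tryCatch(prune(fx$model, sol, lp), error = function(e) NULL)
      if (is.null(pr)) next
      if (!isTRUE(as.logical(verify_unique(pr)))) next
      return(fx)
    }
    stop("random_ec_network: rejection cap (", max_tries, ") exceeded",
         call. = FALSE)
  })
}

random_ec_candidate <- function(n_mets, n_rxns, n_pools) {
  mets <- sprintf("M%02d", seq_len(n_mets))
  rxns <- list()
  enz <- character(0)
  add_enzymatic <- function(id, stoich) {
    g <- paste0("g_", id)
    enz <<- c(enz, g)
    rxns[[length(rxns) + 1L]] <<- reaction(
      id, stoich,
      isozymes = list(isozyme(stats::setNames(1L, g),
                              kcat_forward = param_ref(paste0("kcat_", id)))))
  }
  rxns[[1L]] <- reaction("uptake", stats::setNames(1, mets[1L]))
  for (i in seq_len(n_mets - 1L))
    add_enzymatic(sprintf("chain%02d", i),
                  stats::setNames(c(-1, 1), mets[c(i, i + 1L)]))
  n_extra <- max(0L, n_rxns - (n_mets + 1L))
  for (k in seq_len(n_extra)) {
    if (n_extra == 0L) break
    ij <- sort(sample.int(n_mets, 2L))
    coefs <- sample(1:2, 2L, replace = TRUE)
    add_enzymatic(sprintf("bypass%02d", k),
                  stats::setNames(c(-coefs[1L], coefs[2L]),
                                  mets[c(ij[1L], ij[2L])]))
  }
  rxns[[length(rxns) + 1L]] <- reaction(
    "secretion", stats::setNames(-1, mets[n_mets]),
    objective_coefficient = 1)

  gps <- lapply(enz, function(g)
    gene_product(g, molar_mass = stats::runif(1, 10, 100)))
  assignment <- sample.int(n_pools, length(enz), replace = TRUE)
  assignment[seq_len(min(n_pools, length(enz)))] <-
    seq_len(min(n_pools, length(enz)))   # no empty pools
  pools <- lapply(seq_len(n_pools), function(k)
    enzyme_pool(sprintf("pool%02d", k), enz[assignment == k],
                param_ref(sprintf("E_pool%02d", k))))
  pools <- pools[vapply(pools, function(p) length(p$members) > 0, logical(1))]

  params <- c(
    stats::setNames(10^stats::runif(length(enz), -1, 2),
                    paste0("kcat_", sub("^g_", "", enz))),
    stats::setNames(stats::runif(length(pools), 0.5, 3),
                    vapply(pools, function(p)
                      paste0("E_", p$id), character(1))))
  ## pool capacity param names must match the refs used above
  for (k in seq_along(pools))
    pools[[k]]$capacity <- param_ref(paste0("E_", pools[[k]]$id))

  model <- ec_model(metabolites = lapply(mets, metabolite),
                    reactions = rxns, gene_products = gps, pools = pools,
                    id = "random")
  list(model = model, params = params)
}

#' @rdname fixtures
#' @param name fixture name: `"chain"`, `"branch"`, `"overflow"` or
#'   `"random"`.
#' @param seed,... passed to [random_ec_network()] for `"random"`.
#' @export
make_fixture <- function(name = c("chain", "branch", "overflow", "random"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  switch(name,
         chain = make_chain(),
         branch = make_branch(),
         overflow = make_overflow(),
         random = random_ec_network(seed, ...))
}
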