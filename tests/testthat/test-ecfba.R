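test_that("chain LP has the hand-counted structure and closed-form optimum", {
  s <- solve_fixture(make_chain())
  expect_equal(sum(s$lp$var_table$kind == "flux"), 3L)
  expect_equal(sum(s$lp$var_table$kind == "enzyme"), 1L)
  expect_equal(sum(s$lp$row_table$kind == "steady_state"), 2L)
  expect_equal(sum(s$lp$row_table$kind == "coupling"), 1L)
  expect_equal(sum(s$lp$row_table$kind == "pool"), 1L)
  ## coupling row: exactly two nonzeros, +1 on the flux, -kcat on the enzyme
  cpl <- s$lp$Aeq["cpl__g1", ]
  expect_equal(sum(cpl != 0), 2L)
  expect_equal(unname(cpl["conv"]), 1)
  expect_equal(unname(cpl["e__g1"]), -2)
  ## v* = kcat E / w
  expect_equal(s$sol$status, "optimal")
  expect_equal(s$sol$objective_value, 10, tolerance = 1e-9)
})

test_that("the cheaper branch route loses the whole shared pool", {
  s <- solve_fixture(make_branch())
  expect_equal(s$sol$objective_value, 2, tolerance = 1e-9)
  v <- reaction_fluxes(s$lp, s$sol)
  expect_equal(unname(v["route1"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["route2"]), 2, tolerance = 1e-9)
})

test_that("a vanishing pool capacity forces the objective to zero", {
  fx <- make_chain()
  fx$params["E_pool"] <- 1e-12
  s <- solve_fixture(fx)
  expect_equal(s$sol$objective_value, 0, tolerance = 1e-9)
})

test_that("multiple isozymes expand to parallel coupled flux variables", {
  m <- ec_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("in", c(A = 1)),
      reaction("conv", c(A = -1, B = 1),
               isozymes = list(isozyme(c(g1 = 1L), kcat_forward = 2),
                               isozyme(c(g2 = 1L), kcat_forward = 3))),
      reaction("out", c(B = -1), objective_coefficient = 1)),
    gene_products = list(gene_product("g1", 1), gene_product("g2", 1)),
    pools = list(enzyme_pool("p", c("g1", "g2"), 1)))
  lp <- build_lp(m)
  expect_setequal(lp$rxn_vars[["conv"]], c("conv__iso1", "conv__iso2"))
  expect_equal(sum(lp$row_table$kind == "coupling"), 2L)
  sol <- solve_lp(lp)
  ## whole pool goes to the faster isozyme
  expect_equal(sol$objective_value, 3, tolerance = 1e-9)
  expect_equal(unname(reaction_fluxes(lp, sol)["conv"]), 3, tolerance = 1e-9)
})

test_that("fixed fluxes are encoded as equality rows by default", {
  s <- solve_fixture(make_overflow())
  expect_true("fix__atpm" %in% rownames(s$lp$Aeq))
  expect_equal(unname(s$lp$beq["fix__atpm"]), 1)
  expect_equal(unname(reaction_fluxes(s$lp, s$sol)["atpm"]), 1,
               tolerance = 1e-9)
  ## one-sided mode reproduces the same optimum here (constraint binds)
  s2 <- solve_fixture(make_overflow(), fixed_flux_mode = "at-least")
  expect_equal(s2$sol$objective_value, s$sol$objective_value,
               tolerance = 1e-9)
})

test_that("strong duality and complementary slackness hold at every optimum", {
  cases <- c(lapply(c("chain", "branch", "overflow"), make_fixture),
             random_bank(5))
  for (fx in cases) {
    s <- solve_fixture(fx)
    dual_obj <- sum(s$sol$duals_eq * s$lp$beq) +
      sum(s$sol$duals_in * s$lp$bin)
    expect_equal(dual_obj, s$sol$objective_value,
                 tolerance = 1e-6 * max(1, abs(s$sol$objective_value)))
    expect_true(all(s$sol$duals_in >= -1e-9))
    expect_true(all(abs(s$sol$duals_in * s$sol$slack_in) <= 1e-6))
  }
})

test_that("scaling all kcats by alpha scales a homogeneous optimum by alpha", {
  for (fx in c(list(make_chain(), make_branch()), random_bank(3))) {
    base <- solve_fixture(fx)$sol$objective_value
    kc <- grep("^kcat_", names(fx$params))
    for (alpha in c(0.5, 2, 10)) {
      p <- fx$params
      p[kc] <- p[kc] * alpha
      s <- solve_fixture(list(model = fx$model, params = p))
      expect_equal(s$sol$objective_value, alpha * base,
                   tolerance = 1e-8 * max(1, alpha * base))
    }
  }
})

test_that("FVA at the optimum sandwiches the primal and detects degeneracy", {
  s <- solve_fixture(make_branch())
  fva <- fva_at_optimum(s$lp, s$sol)
  prim <- s$sol$primal[fva$id]
  expect_true(all(fva$min <= prim + 1e-8))
  expect_true(all(prim <= fva$max + 1e-8))
  ## equal kcats and weights: alternate optima, positive range widths
  fx <- make_branch()
  fx$params[c("kcat_route1", "kcat_route2")] <- 2
  sd <- solve_fixture(fx)
  fvad <- fva_at_optimum(sd$lp, sd$sol)
  expect_gt(max(fvad$max - fvad$min), 0.1)
})

test_that("infeasible and unbounded problems are reported as status", {
  ## unbounded: objective reaction with no enzyme cost and no bound
  m <- ec_model(
    metabolites = list(metabolite("A")),
    reactions = list(reaction("in", c(A = 1)),
                     reaction("out", c(A = -1), objective_coefficient = 1)))
  expect_identical(solve_lp(build_lp(m))$status, "unbounded")
  ## infeasible: fixed flux through a capacity-starved enzyme
  fx <- make_overflow()
  fx$params["E_membrane"] <- 1e-9
  fx$params["E_cytosol"] <- 1e-9
  s <- solve_fixture(fx)
  expect_identical(s$sol$status, "infeasible")
})
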