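test_that("chain sensitivities match the closed form v* = kcat E / w", {
  s <- pruned_fixture(make_chain())
  sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
  expect_equal(sens$raw["secretion", "kcat_conv"], 5, tolerance = 1e-9)
  expect_equal(sens$raw["secretion", "E_pool"], 2, tolerance = 1e-9)
  cc <- control_coefficients(sens, s$pruned$solution, s$params)
  expect_equal(cc$scaled["secretion", "kcat_conv"], 1, tolerance = 1e-9)
  expect_equal(cc$scaled["secretion", "E_pool"], 1, tolerance = 1e-9)
  ## enzyme concentration e = E/w is kcat-independent
  expect_equal(sens$raw["e__g1", "kcat_conv"], 0, tolerance = 1e-12)
  expect_equal(sens$raw["e__g1", "E_pool"], 1, tolerance = 1e-9)
})

test_that("the pool row binds at the chain optimum with a positive dual", {
  s <- pruned_fixture(make_chain())
  act <- detect_active_set(s$pruned$lp, s$pruned$solution)
  expect_true("pool__pool" %in% act$active_in)
  expect_gt(s$pruned$solution$duals_in[["pool__pool"]], 0)
})

test_that("slack constraints are excluded and their parameters give zero", {
  ## an upper bound far above the optimum is inactive: exact zero column
  fx <- make_chain()
  fx$model$reactions[["uptake"]]$upper_bound <- param_ref("ub_uptake")
  fx$params <- c(fx$params, ub_uptake = 100)
  s <- pruned_fixture(fx)
  act <- detect_active_set(s$pruned$lp, s$pruned$solution)
  expect_false("ub__uptake" %in% act$active_in)
  sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution, act)
  expect_true(all(sens$raw[, "ub_uptake"] == 0))
  ## while a *binding* bound takes over control completely
  fx$params["ub_uptake"] <- 3
  s2 <- pruned_fixture(fx)
  sens2 <- kkt_differentiate(s2$pruned$lp, s2$pruned$solution)
  expect_equal(sens2$raw["secretion", "ub_uptake"], 1, tolerance = 1e-9)
  expect_equal(sens2$raw["secretion", "kcat_conv"], 0, tolerance = 1e-12)
})

test_that("degenerate optima are stopped at the uniqueness gate", {
  ## pruning resolves plain alternate optima: the equal-kcat branch keeps
  ## only the vertex's route and its pruned optimum is unique again
  fx <- make_branch()
  fx$params[c("kcat_route1", "kcat_route2")] <- 2
  s <- pruned_fixture(fx)
  expect_true(as.logical(verify_unique(s$pruned)))
  ## but equal-cost routes forced jointly active stay degenerate after
  ## pruning and must be refused
  dg <- make_degenerate()
  s2 <- pruned_fixture(dg)
  expect_false(as.logical(verify_unique(s2$pruned)))
  expect_error(run_pipeline(dg$model, dg$params), "verify_unique failed")
})

test_that("implicit sensitivities match central finite differences", {
  cases <- c(lapply(c("chain", "branch", "overflow"), make_fixture),
             random_bank(10))
  for (fx in cases) {
    s <- pruned_fixture(fx)
    sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
    fd <- finite_difference_oracle(s$pruned$model, s$params, sens$params)
    dev <- max(abs(sens$raw - fd$raw[sens$vars, sens$params])) /
      max(1, max(abs(sens$raw)))
    expect_lt(dev, 1e-4)
  }
})

test_that("batched and single-parameter differentiation agree bitwise", {
  s <- pruned_fixture(make_overflow())
  batch <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
  for (p in batch$params) {
    single <- kkt_differentiate(s$pruned$lp, s$pruned$solution,
                                param_names = p)
    expect_identical(unname(single$raw[, p]), unname(batch$raw[, p]))
  }
})

test_that("kcat control coefficients sum to one on homogeneous models", {
  for (fx in c(list(make_chain(), make_branch()), random_bank(5))) {
    s <- pruned_fixture(fx)
    sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
    kc <- grep("^kcat_", sens$params, value = TRUE)
    cc <- control_coefficients(sens, s$pruned$solution, s$params)
    flux_vars <- s$pruned$lp$var_table$id[
      s$pruned$lp$var_table$kind == "flux"]
    sums <- rowSums(cc$scaled[flux_vars, kc, drop = FALSE])
    expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-6)
  }
})

test_that("control coefficients are NA at zero variables, zero at zero raw", {
  s <- pruned_fixture(make_chain())
  sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
  cc <- control_coefficients(sens, s$pruned$solution, s$params)
  expect_equal(cc$scaled["e__g1", "kcat_conv"], 0)       # zero raw
  fake_sol <- s$pruned$solution
  fake_sol$primal["e__g1"] <- 0
  cc2 <- control_coefficients(sens, fake_sol, s$params)
  expect_true(is.na(cc2$scaled["e__g1", "E_pool"]))      # undefined, not 0
})

test_that("the finite-difference oracle rejects a degenerate step", {
  fx <- make_chain()
  expect_error(finite_difference_oracle(fx$model, fx$params, rel_step = 0),
               "rel_step")
})

test_that("chain finite differences are exact for the linear closed form", {
  s <- pruned_fixture(make_chain())
  fd <- finite_difference_oracle(s$pruned$model, s$params, "kcat_conv")
  expect_equal(fd$raw["secretion", "kcat_conv"], 5, tolerance = 1e-6)
})
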