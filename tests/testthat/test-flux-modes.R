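test_that("trivial cones are enumerated correctly", {
  ## a line intersected with the first orthant: one ray along (1, 1)
  r <- double_description(matrix(c(1, -1), 1, 2))
  expect_equal(ncol(r), 1L)
  expect_equal(unname(r[, 1]), c(0.5, 0.5))            # |.|_1 = 1 convention
  expect_equal(brute_force_modes(matrix(c(1, -1), 1, 2)), r)
  ## empty cone: only the zero point
  expect_equal(ncol(double_description(diag(2))), 0L)
})

test_that("fixture networks have the expected elementary flux modes", {
  expect_equal(ncol(double_description(stoich_matrix(make_chain()$model))),
               1L)
  Sb <- stoich_matrix(make_branch()$model)
  rays <- double_description(Sb)
  expect_equal(ncol(rays), 2L)
  supp <- lapply(seq_len(ncol(rays)), function(k)
    rownames(rays)[rays[, k] > 0])
  expect_true(all(c("uptake", "secretion") %in% supp[[1]]))
  expect_setequal(c(supp[[1]], supp[[2]]),
                  c("uptake", "secretion", "route1", "route2"))
  expect_same_rays(rays, brute_force_modes(Sb))
})

test_that("Double Description equals brute force on seeded networks", {
  for (s in 1:10) {
    fx <- random_ec_network(2000 + s, n_mets = 5, n_rxns = 9, n_pools = 2)
    S <- stoich_matrix(fx$model)
    expect_same_rays(double_description(S), brute_force_modes(S))
  }
})

test_that("returned modes are support-minimal (oracle cross-check)", {
  for (s in 1:5) {
    fx <- random_ec_network(3000 + s, n_mets = 5, n_rxns = 9, n_pools = 2)
    S <- stoich_matrix(fx$model)
    rays <- double_description(S)
    supports <- apply(rays > 1e-9, 2, which, simplify = FALSE)
    for (i in seq_along(supports)) for (j in seq_along(supports)) {
      if (i == j) next
      expect_false(all(supports[[j]] %in% supports[[i]]) &&
                     length(supports[[j]]) < length(supports[[i]]))
    }
  }
})

test_that("homogenization folds fixed fluxes and objective into one column", {
  s <- pruned_fixture(make_overflow())
  hs <- homogenize(s$pruned)
  expect_true(hs$has_vbar)
  expect_setequal(hs$folded$reaction, c("atpm", "biomass"))
  expect_equal(ncol(hs$A), length(hs$free_rxns) + 1L)
  ## w aggregates -(ATPM stoichiometry)*1 - (biomass stoichiometry)*4.4
  expect_equal(unname(hs$A["ATP", "vbar__"]), -(1 + 4.4), tolerance = 1e-9)
  ## reference solution with vbar = 1 lies in the cone
  expect_lt(max(abs(hs$A %*% hs$x_ref)), 1e-9)
})

test_that("a homogeneous model passes through to the plain flux cone", {
  s <- pruned_fixture(make_branch())
  hs <- homogenize(s$pruned, fold_objective = FALSE)
  expect_false(hs$has_vbar)
  expect_equal(ncol(hs$A), length(names(s$pruned$model$reactions)))
  fm <- ofms(hs)
  expect_false(fm$has_vbar)
  expect_equal(ncol(fm$modes), 1L)   # pruned branch has a single pathway
})

test_that("the overflow optimum is a superposition of exactly two OFMs", {
  s <- pruned_fixture(make_overflow())
  hs <- homogenize(s$pruned)
  fm <- ofms(hs)
  expect_equal(ncol(fm$modes), 2L)
  ## every OFM is admissible at vbar = 1
  for (k in 1:2)
    expect_lt(max(abs(hs$A %*% fm$modes[, k])), 1e-8)
  ## one respiratory-like (resp, no ferm), one fermentative-like
  supp <- apply(fm$modes > 1e-9, 2, function(x) rownames(fm$modes)[x])
  has_resp <- vapply(supp, function(s) "resp" %in% s, logical(1))
  has_ferm <- vapply(supp, function(s) "ferm" %in% s, logical(1))
  expect_setequal(has_resp, c(TRUE, FALSE))
  expect_identical(has_ferm, !has_resp)
})

test_that("a single-pathway model decomposes onto its own solution", {
  s <- pruned_fixture(make_chain())
  hs <- homogenize(s$pruned)
  fm <- ofms(hs)
  expect_equal(ncol(fm$modes), 1L)
  dec <- decompose(hs, fm, K = 1)
  expect_equal(unname(dec$lambda), 1, tolerance = 1e-9)
  nfree <- length(hs$free_rxns)
  expect_equal(unname(fm$modes[seq_len(nfree), 1]),
               unname(hs$x_ref[seq_len(nfree)]), tolerance = 1e-9)
})

test_that("overflow weights are the closed-form 4/9 and 5/9, summing to 1", {
  s <- pruned_fixture(make_overflow())
  hs <- homogenize(s$pruned)
  dec <- decompose(hs, ofms(hs), K = 2)
  expect_equal(sum(dec$lambda), 1, tolerance = 1e-8)
  expect_equal(sort(unname(dec$lambda)), c(4 / 9, 5 / 9), tolerance = 1e-9)
  expect_lte(dec$n_active, dec$K)
  expect_lt(dec$residual, 1e-8)
})

test_that("decomposition invariants hold across random models", {
  for (fx in random_bank(10)) {
    s <- pruned_fixture(fx)
    hs <- homogenize(s$pruned)
    fm <- ofms(hs)
    dec <- decompose(hs, fm, K = s$pruned$lp$n_pools)
    expect_equal(sum(dec$lambda), 1, tolerance = 1e-8)
    expect_true(all(dec$lambda >= 0))
    expect_lte(dec$n_active, s$pruned$lp$n_pools)
  }
})

test_that("OFM usage sensitivities: conservation, signs, and the FD oracle", {
  s <- pruned_fixture(make_overflow())
  hs <- homogenize(s$pruned)
  dec <- decompose(hs, ofms(hs), K = 2)
  sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
  kin <- c("kcat_resp", "kcat_ferm", "kcat_biomass", "E_membrane",
           "E_cytosol")
  os <- ofm_sensitivity(dec, hs, s$pruned, sens, param_names = kin,
                        params = s$params)
  ## conservation: columns sum to zero; K = 2 antisymmetry is exact
  expect_true(all(abs(colSums(os$raw)) <= 1e-10))
  expect_equal(os$raw[1, ], -os$raw[2, ], tolerance = 1e-12)
  ## membrane-crowding sign structure: cytosolic kcats favour fermentation,
  ## the membrane kcat favours respiration
  ferm <- which(vapply(seq_len(2), function(k)
    dec$modes["ferm", k] > 1e-9, logical(1)))
  resp <- setdiff(1:2, ferm)
  for (p in c("kcat_ferm", "kcat_biomass", "E_cytosol")) {
    expect_gt(os$scaled[ferm, p], 0)
    expect_lt(os$scaled[resp, p], 0)
  }
  for (p in c("kcat_resp", "E_membrane")) {
    expect_gt(os$scaled[resp, p], 0)
    expect_lt(os$scaled[ferm, p], 0)
  }
  ## closed form: lambda_resp(kcat_resp) = 3 k / (4.8 + 0.6 k) at k = 1
  expect_equal(os$raw[resp, "kcat_resp"], 14.4 / 29.16, tolerance = 1e-9)
  ## independent finite-difference oracle (re-solve, re-enumerate,
  ## re-decompose)
  fd <- ofm_fd_oracle(s$pruned, dec, kin)
  expect_lt(max(abs(os$raw - fd)) / max(1, max(abs(os$raw))), 1e-4)
})

test_that("fixed-flux parameters are rejected for OFM differentiation", {
  s <- pruned_fixture(make_overflow())
  hs <- homogenize(s$pruned)
  dec <- decompose(hs, ofms(hs), K = 2)
  sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
  expect_error(
    ofm_sensitivity(dec, hs, s$pruned, sens, param_names = "atpm_flux",
                    params = s$params),
    "alter the cone")
})

test_that("OFM sensitivities agree with the oracle on random models", {
  for (fx in random_bank(5)) {
    s <- pruned_fixture(fx)
    hs <- homogenize(s$pruned)
    dec <- decompose(hs, ofms(hs), K = s$pruned$lp$n_pools)
    sens <- kkt_differentiate(s$pruned$lp, s$pruned$solution)
    os <- ofm_sensitivity(dec, hs, s$pruned, sens, params = s$params)
    expect_true(all(abs(colSums(os$raw)) <= 1e-10))
    fd <- ofm_fd_oracle(s$pruned, dec, os$params)
    expect_lt(max(abs(os$raw - fd)) / max(1, max(abs(os$raw))), 1e-4)
  }
})
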