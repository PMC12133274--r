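test_that("native JSON round-trips every fixture model field-wise", {
  for (name in c("chain", "branch", "overflow")) {
    fx <- make_fixture(name)
    path <- withr::local_tempfile(fileext = ".json")
    save_ec_model(fx$model, path)
    back <- load_ec_model(path)
    expect_equal(back, fx$model, tolerance = 1e-12)
  }
})

test_that("parameter references and infinite bounds survive the round trip", {
  fx <- make_overflow()
  path <- withr::local_tempfile(fileext = ".json")
  save_ec_model(fx$model, path)
  back <- load_ec_model(path)
  iso <- back$reactions[["resp"]]$isozymes[[1]]
  expect_true(is_param_ref(iso$kcat_forward))
  expect_identical(param_name(iso$kcat_forward), "kcat_resp")
  expect_identical(back$reactions[["glc_uptake"]]$upper_bound, Inf)
  expect_true(is_param_ref(back$fixed_fluxes[["atpm"]]$value))
})

test_that("validation reports broken references and bound inversions", {
  fx <- make_chain()
  m <- fx$model
  m$reactions[["conv"]]$stoichiometry <- c(A = -1, Ghost = 1)
  rep <- validate_model(m, fx$params)
  expect_false(rep$valid)
  expect_match(rep$errors, "Ghost", all = FALSE)

  m2 <- fx$model
  m2$reactions[["uptake"]]$lower_bound <- 5
  m2$reactions[["uptake"]]$upper_bound <- 1
  rep2 <- validate_model(m2, fx$params)
  expect_length(rep2$errors, 1L)
  expect_match(rep2$errors, "lower_bound > upper_bound")

  m3 <- fx$model
  m3$pools[["pool"]]$members <- c("g1", "gX")
  rep3 <- validate_model(m3, fx$params)
  expect_length(rep3$errors, 1L)
  expect_match(rep3$errors, "gX")
})

test_that("fixtures validate cleanly, flagging only cost-free exchanges", {
  for (name in c("chain", "branch", "overflow")) {
    fx <- make_fixture(name)
    rep <- validate_model(fx$model, fx$params)
    expect_true(rep$valid)
    expect_gt(length(rep$warnings), 0)
    expect_true(all(grepl("cost-free|enzyme cost", rep$warnings)))
  }
})

test_that("unresolved parameter references are caught and named", {
  fx <- make_chain()
  expect_error(build_lp(fx$model, c(kcat_conv = 2)), "E_pool")
})

test_that("split_reversible halves a reversible reaction by definition", {
  m <- ec_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("in", c(A = 1)),
      reaction("conv", c(A = -1, B = 1), lower_bound = -5, upper_bound = 10,
               isozymes = list(isozyme(c(g = 1L), kcat_forward = 3,
                                       kcat_reverse = 7))),
      reaction("out", c(B = -1), objective_coefficient = 1)),
    gene_products = list(gene_product("g", 1)),
    pools = list(enzyme_pool("p", "g", 1)))
  s <- split_reversible(m)
  expect_setequal(names(s$reactions), c("in", "conv_fwd", "conv_bwd", "out"))
  fwd <- s$reactions[["conv_fwd"]]; bwd <- s$reactions[["conv_bwd"]]
  expect_identical(c(fwd$lower_bound, fwd$upper_bound), c(0, 10))
  expect_identical(c(bwd$lower_bound, bwd$upper_bound), c(0, 5))
  expect_equal(bwd$stoichiometry, c(A = 1, B = -1))
  expect_identical(fwd$isozymes[[1]]$kcat_forward, 3)
  expect_identical(bwd$isozymes[[1]]$kcat_forward, 7)
  ## counts: irreversible + 2 x reversible
  expect_length(s$reactions, 2L + 2L * 1L)
  ## idempotent; identity on irreversible models
  expect_equal(split_reversible(s), s)
  expect_equal(split_reversible(make_chain()$model), make_chain()$model)
})

test_that("a reversible reaction without kcat_reverse warns and loses cost", {
  m <- ec_model(
    metabolites = list(metabolite("A"), metabolite("B")),
    reactions = list(
      reaction("in", c(A = 1)),
      reaction("conv", c(A = -1, B = 1), lower_bound = -5,
               isozymes = list(isozyme(c(g = 1L), kcat_forward = 3))),
      reaction("out", c(B = -1), objective_coefficient = 1)),
    gene_products = list(gene_product("g", 1)),
    pools = list(enzyme_pool("p", "g", 1)))
  expect_warning(s <- split_reversible(m), "no kcat_reverse")
  expect_length(s$reactions[["conv_bwd"]]$isozymes, 0L)
})

test_that("COBRA JSON import maps gene-reaction rules to isozymes", {
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_cobra_json(path)
  m <- read_cobra_json(
    path,
    kcats = c(RESP = 10, FERM = 60, BIOMASS = 30),
    molar_masses = c(b0001 = 30, b0002 = 20, b0003 = 25, b0004 = 25,
                     b0005 = 40),
    pools = list(enzyme_pool("membrane", c("b0001", "b0002"), 100),
                 enzyme_pool("cytosol", c("b0003", "b0004", "b0005"), 150)))
  ## AND -> one complex with unit counts; OR -> two isozymes
  expect_length(m$reactions[["RESP"]]$isozymes, 1L)
  expect_equal(m$reactions[["RESP"]]$isozymes[[1]]$subunit_counts,
               c(b0001 = 1L, b0002 = 1L))
  expect_length(m$reactions[["FERM"]]$isozymes, 2L)
  expect_identical(m$objective_reaction, "BIOMASS")
  expect_true(validate_model(m)$valid)
})

test_that("COBRA import without kinetics warns and imports cost-free", {
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_cobra_json(path)
  expect_warning(m <- read_cobra_json(path), "no kcat")
  expect_length(m$reactions[["RESP"]]$isozymes, 0L)
})
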