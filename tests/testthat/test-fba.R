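test_that("a linear chain gives the closed-form yield times uptake", {
  # EX_A (lb -10) -> A, biomass at 0.5 units per A: optimum 0.5 * 10
  m <- metabolic_model(
    data.frame(id = c("a[c]", "x[c]"), compartment = "c"),
    data.frame(id = c("EX_a", "BIO", "EX_x"), lb = c(-10, 0, 0),
               ub = c(0, 1000, 1000),
               kind = c("exchange", "biomass", "exchange")),
    list(EX_a = c("a[c]" = -1),
         BIO = c("a[c]" = -2, "x[c]" = 1),
         EX_x = c("x[c]" = -1)))
  sol <- fba(m, "BIO")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 5)
  expect_equal(unname(sol$fluxes["EX_a"]), -10)
  # closing the only carbon source removes all growth
  m0 <- apply_condition(m, condition_spec(
    "starve", "BIO", exchange_bounds = list(EX_a = c(0, 0))))
  expect_equal(fba(m0)$objective, 0)
})

test_that("the LP optimum matches vertex enumeration on random toys", {
  agree <- 0L
  cases <- 0L
  for (seed in 1:100) {
    m_sz <- 2L + seed %% 2L
    n_sz <- min(6L, m_sz + 2L + seed %% 2L)
    mod <- make_random_network(m_sz, n_sz, seed = seed)
    set.seed(seed + 1000)
    target <- sample(mod$reactions$id, 1)
    sol <- fba(mod, objective_id = target,
               sense = if (seed %% 2) "max" else "min")
    S <- build_S(mod)
    obj <- as.numeric(mod$reactions$id == target)
    want <- oracle_lp_vertex(S, mod$reactions$lb, mod$reactions$ub,
                             obj, sense = if (seed %% 2) "max" else
                               "min")
    cases <- cases + 1L
    expect_equal(sol$objective, want, tolerance = 1e-7,
                 info = paste("seed", seed))
    if (abs(sol$objective - want) <= 1e-7) agree <- agree + 1L
  }
  expect_equal(agree, cases)
})

test_that("LP optimum is invariant to reaction and metabolite order", {
  toy <- make_toy_core_model(toy_spec())
  base <- fba(toy$model, "BIO_L")$objective
  set.seed(9)
  m <- toy$model
  pr <- sample(nrow(m$reactions))
  pm <- sample(nrow(m$metabolites))
  m$reactions <- m$reactions[pr, ]
  m$stoichiometry <- m$stoichiometry[pr]
  m$metabolites <- m$metabolites[pm, ]
  expect_equal(fba(m, "BIO_L")$objective, base, tolerance = 1e-9)
})

test_that("relaxing a bound never decreases the maximized objective", {
  toy <- make_toy_core_model(toy_spec())
  base <- fba(toy$model, "BIO_L")$objective
  for (id in c("EX_glc", "ROUTE1", "OXPHOS")) {
    m <- halofba:::set_bounds(toy$model, id,
                              lb = toy$model$reactions$lb[
                                halofba:::rxn_index(toy$model, id)] - 5)
    expect_gte(fba(m, "BIO_L")$objective + 1e-9, base)
  }
})

test_that("conditions apply idempotently and switch the objective", {
  toy <- make_toy_core_model(toy_spec())
  cond <- condition_spec("high", "BIO_H",
                         exchange_bounds = list(EX_glc = c(-6.5, 0)),
                         atpm_id = "ATPM", atpm_flux = 7.6)
  m1 <- apply_condition(toy$model, cond)
  expect_equal(m1$objective_id, "BIO_H")
  i <- halofba:::rxn_index(m1, "EX_glc")
  expect_equal(m1$reactions$lb[i], -6.5)
  m2 <- apply_condition(m1, cond)
  expect_identical(m2, m1)
  # the original is untouched
  expect_equal(toy$model$reactions$lb[i], -10)
  expect_error(apply_condition(toy$model, condition_spec(
    "bad", "BIO_L", exchange_bounds = list(ROUTE1 = c(0, 1)))),
    "non-exchange")
})

test_that("minimal medium opens listed ions and closes organics", {
  toy <- make_toy_core_model(toy_spec())
  m <- set_minimal_medium(toy$model, c("EX_o2", "EX_co2"))
  expect_equal(m$reactions$lb[halofba:::rxn_index(m, "EX_o2")], -1000)
  expect_equal(m$reactions$lb[halofba:::rxn_index(m, "EX_glc")], 0)
  expect_warning(set_minimal_medium(toy$model, c("EX_o2", "EX_nope")),
                 "EX_nope")
})

test_that("carbon screens call growth-supporting sources correctly", {
  toy <- make_toy_core_model(toy_spec())
  m <- set_minimal_medium(toy$model, "EX_o2")
  scr <- screen_carbon_sources(m, "EX_glc", uptake = 10)
  expect_true(scr$grows[scr$source == "EX_glc"])
  expect_equal(scr$growth_rate[1], toy$analytic_optimum[["low"]],
               tolerance = 1e-6)
  # with every source closed there is nothing to grow on
  scr0 <- screen_carbon_sources(m, "EX_co2", uptake = 0,
                                close_ids = "EX_glc")
  expect_false(any(scr0$grows))
})

test_that("gene deletions propagate through complexes and isozymes", {
  toy <- make_toy_core_model(toy_spec())
  rep_l <- single_gene_deletions(apply_condition(
    toy$model, make_condition_pair(toy$spec)$low))
  ess <- sort(rep_l$gene[rep_l$essential])
  expect_equal(ess, sort(toy$essential_genes))
  # isozyme-backed route genes survive deletion
  expect_false(rep_l$essential[rep_l$gene == "g_r2a"])
  # complex member on a redundant route is not essential either
  expect_false(rep_l$essential[rep_l$gene == "g_r1a"])
  # a gene absent from all rules never changes the optimum
  m <- toy$model
  m$genes <- c(m$genes, "g_ghost")
  repg <- single_gene_deletions(m, genes = "g_ghost")
  expect_equal(repg$growth_rate, attr(repg, "wild_type_growth"))
})

test_that("two isozymes on the single route mean neither is essential", {
  spec1 <- toy_spec(n_alternate_routes = 1)
  toy1 <- make_toy_core_model(spec1)
  rep1 <- single_gene_deletions(apply_condition(
    toy1$model, make_condition_pair(spec1)$low))
  expect_false(any(rep1$essential[rep1$gene %in% c("g_r1a", "g_r1b")]))
})

test_that("essentiality comparison splits shared and unique genes", {
  a <- data.frame(gene = c("g1", "g2", "g3"),
                  essential = c(TRUE, TRUE, FALSE))
  b <- data.frame(gene = c("g1", "g2", "g3"),
                  essential = c(TRUE, FALSE, TRUE))
  cmp <- compare_essentiality(a, b)
  expect_equal(cmp$shared, "g1")
  expect_equal(cmp$only_a, "g2")
  expect_equal(cmp$only_b, "g3")
})

test_that("ATP yield reflects stoichiometry and oxygen availability", {
  toy <- make_toy_core_model(toy_spec())
  aerobic <- atp_yield_per_substrate(toy$model, "EX_glc")
  # best route gives 1 ATP + 2 NADH (4 ATP at P/O 2) per glucose, and
  # burning both pyruvates adds 8 NADH = 16 ATP: 21 in total
  expect_equal(aerobic, 21, tolerance = 1e-7)
  # without oxidative phosphorylation only substrate-level ATP remains
  fermentative <- atp_yield_per_substrate(
    halofba:::set_bounds(toy$model, "OXPHOS", ub = 0), "EX_glc")
  expect_lte(fermentative, aerobic)
  expect_equal(fermentative, 2, tolerance = 1e-7)
  no_maint <- make_ectoine_cycle_model(2)$model
  expect_error(atp_yield_per_substrate(no_maint, "SYN_1"),
               "maintenance")
})

test_that("bundled example conditions load from YAML and reproduce FBA", {
  ext <- system.file("extdata", package = "halofba")
  model <- suppressMessages(read_model(file.path(ext, "toy_model"),
                                       "tsv"))
  low <- read_condition(file.path(ext, "condition_low_salinity.yaml"))
  high <- read_condition(file.path(ext, "condition_high_salinity.yaml"))
  expect_equal(low$biomass_id, "BIO_L")
  expect_equal(high$atpm_flux, 15.2)
  truth <- make_condition_pair(toy_spec())$truth$growth
  expect_equal(fba(apply_condition(model, low))$objective,
               truth[["low"]], tolerance = 1e-8)
  expect_equal(fba(apply_condition(model, high))$objective,
               truth[["high"]], tolerance = 1e-8)
})
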