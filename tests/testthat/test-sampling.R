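test_that("projection dimension equals n minus rank, with fixed fluxes", {
  # one unconstrained reversible conversion: 1 free coordinate
  m1 <- metabolic_model(
    data.frame(id = c("a[c]", "b[c]"), compartment = "c"),
    data.frame(id = c("EX_a", "R1", "EX_b"), lb = c(-1000, -1000, -1000),
               ub = 1000,
               kind = c("exchange", "metabolic", "exchange")),
    list(EX_a = c("a[c]" = -1), R1 = c("a[c]" = -1, "b[c]" = 1),
         EX_b = c("b[c]" = -1)))
  expect_equal(project_to_independent_variables(m1)$dimension, 1L)
  # a chain with pinned uptake is a point polytope
  proj0 <- project_to_independent_variables(fixed_chain_model(5))
  expect_equal(proj0$dimension, 0L)
  v <- halofba:::fluxes_from_free(proj0, matrix(0, 1, 0),
                                  fixed_chain_model(5)$reactions$id)
  expect_equal(unname(v[1, ]), c(-5, 5, 5, 5))
  # general case: dimension equals n - rank(S) - n_fixed_bound_rows
  for (seed in 1:10) {
    m <- make_random_network(3, 6, seed = seed)
    S <- as.matrix(build_S(m))
    proj <- project_to_independent_variables(m)
    expect_equal(proj$dimension, ncol(S) - qr(S)$rank,
                 info = paste("seed", seed))
    # reconstruction satisfies steady state for arbitrary free values
    set.seed(seed)
    Z <- matrix(stats::runif(3 * proj$dimension, -5, 5), 3)
    V <- halofba:::fluxes_from_free(proj, Z, m$reactions$id)
    expect_lt(max(abs(S %*% t(V))), 1e-9)
  }
})

test_that("rejection sampling matches closed-form box and simplex laws", {
  n <- 2000
  box <- rejection_sample(box_model(10), n, seed = 21)
  mu <- mean(box$samples[, "R_out"])
  se <- (10 / sqrt(12)) / sqrt(n)
  expect_lt(abs(mu - 5), 3 * se)
  simp <- rejection_sample(simplex_model(), n, seed = 22)
  se_simplex <- sqrt(1 / 18) / sqrt(n)
  expect_lt(abs(mean(simp$samples[, "R1"]) - 1 / 3), 3 * se_simplex)
  expect_lt(abs(mean(simp$samples[, "R2"]) - 1 / 3), 3 * se_simplex)
})

test_that("infeasible bounds abort sampling with a clear error", {
  m <- box_model(10)
  m <- halofba:::set_bounds(m, "EX_in", lb = -5, ub = -5)
  m <- halofba:::set_bounds(m, "R_out", lb = 8, ub = 10)
  expect_error(rejection_sample(m, 10, seed = 1), "infeasible")
  expect_error(hit_and_run_sample(m, 10, seed = 1), "nfeasible")
})

test_that("the dimension guard sends big polytopes to hit-and-run", {
  m <- make_ectoine_cycle_model(7)$model
  expect_error(rejection_sample(m, 10, seed = 1, max_dim = 6),
               "hit_and_run")
})

test_that("fixed seeds reproduce sample matrices bitwise", {
  m <- make_ectoine_cycle_model(3)$model
  a <- hit_and_run_sample(m, 100, seed = 77)
  b <- hit_and_run_sample(m, 100, seed = 77)
  expect_identical(a$samples, b$samples)
  r1 <- rejection_sample(m, 100, seed = 78)
  r2 <- rejection_sample(m, 100, seed = 78)
  expect_identical(r1$samples, r2$samples)
  expect_false(identical(
    a$samples, hit_and_run_sample(m, 100, seed = 79)$samples))
})

test_that("every returned point satisfies steady state and bounds", {
  toy <- make_toy_core_model(toy_spec())
  cond <- make_condition_pair(toy$spec)$low
  m <- apply_condition(toy$model, cond)
  s <- hit_and_run_sample(m, 300, seed = 5)
  S <- build_S(m)
  expect_lt(max(abs(as.matrix(S %*% t(s$samples)))), 1e-6)
  expect_gte(min(sweep(s$samples, 2, m$reactions$lb, "-")), -1e-9)
  expect_lte(max(sweep(s$samples, 2, m$reactions$ub, "-")), 1e-9)
})

test_that("marginals are invariant to reaction column order", {
  m <- make_ectoine_cycle_model(2)$model
  s1 <- hit_and_run_sample(m, 1500, seed = 31)
  perm <- c(3, 1, 4, 2)
  mp <- m
  mp$reactions <- mp$reactions[perm, ]
  mp$stoichiometry <- mp$stoichiometry[perm]
  s2 <- hit_and_run_sample(mp, 1500, seed = 32)
  for (id in m$reactions$id) {
    ks <- suppressWarnings(stats::ks.test(s1$samples[, id],
                                          s2$samples[, id]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("median fluxes normalize by glucose uptake", {
  mat <- cbind(EX_glc = rep(-10, 5), R1 = rep(4, 5), R2 = rep(2, 5))
  s <- as_sample_set(mat)
  med <- median_fluxes(s, "EX_glc")
  expect_equal(unname(med["EX_glc"]), -1)
  expect_equal(unname(med["R1"]), 0.4)
  # stoichiometric 2:1 coupling survives normalization in ratio
  m <- coupled_ratio_model()
  sm <- hit_and_run_sample(m, 500, seed = 8)
  med2 <- median_fluxes(sm, "EX_a")
  expect_equal(unname(med2["EX_b"] / med2["R1"]), 2, tolerance = 1e-9)
  zero <- as_sample_set(cbind(EX_glc = rep(0, 5), R1 = rep(1, 5)))
  expect_error(median_fluxes(zero, "EX_glc"), "zero")
})
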