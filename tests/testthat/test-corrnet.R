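test_that("spearman matrix is exact for coupled and self pairs", {
  m <- coupled_ratio_model()
  s <- hit_and_run_sample(m, 300, seed = 12)
  rho <- spearman_matrix(s)
  expect_equal(diag(rho), stats::setNames(rep(1, 3), colnames(rho)))
  # EX_b = 2 R1 in every sample: perfect monotone relation
  expect_equal(rho["EX_b", "R1"], 1)
  # uptake is the negative of the internal flux: rho = -1
  expect_equal(rho["EX_a", "R1"], -1)
  expect_true(all(rho >= -1 & rho <= 1))
  expect_equal(rho, t(rho))
})

test_that("spearman matches the rank-then-Pearson oracle to 1e-12", {
  set.seed(13)
  X <- matrix(stats::rnorm(5 * 100), 100, 5,
              dimnames = list(NULL, paste0("R", 1:5)))
  X[, 2] <- X[, 1]^3 + stats::rnorm(100, 0, 0.1)
  s <- as_sample_set(X)
  expect_equal(spearman_matrix(s), oracle_spearman(X),
               tolerance = 1e-12)
})

test_that("constant flux columns are excluded, not NaN-propagated", {
  X <- cbind(R1 = stats::runif(50), R2 = rep(3.3, 50),
             R3 = stats::runif(50))
  expect_warning(rho <- spearman_matrix(as_sample_set(X)), "R2")
  expect_equal(colnames(rho), c("R1", "R3"))
  allconst <- as_sample_set(cbind(R1 = rep(1, 10), R2 = rep(2, 10)))
  expect_error(suppressWarnings(spearman_matrix(allconst)), "constant")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(14)
  X <- matrix(stats::runif(200), 100, 2,
              dimnames = list(NULL, c("R1", "R2")))
  r1 <- spearman_matrix(as_sample_set(X))
  X2 <- X
  X2[, 2] <- exp(5 * X2[, 2])
  r2 <- spearman_matrix(as_sample_set(X2))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("thresholding produces the expected module structure", {
  # all sub-threshold: edgeless, every node its own module
  rho_low <- diag(3)
  rho_low[rho_low == 0] <- 0.5
  dimnames(rho_low) <- list(paste0("R", 1:3), paste0("R", 1:3))
  net <- threshold_network(rho_low, 0.7)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$n_modules, 3L)
  # two perfect blocks: exactly two modules
  blk <- matrix(0, 4, 4, dimnames = list(paste0("R", 1:4),
                                         paste0("R", 1:4)))
  blk[1:2, 1:2] <- 1
  blk[3:4, 3:4] <- -0.9
  diag(blk) <- 1
  net2 <- threshold_network(blk, 0.7)
  expect_equal(net2$n_modules, 2L)
  mods <- network_modules(net2)
  expect_setequal(mods[[1]], c("R1", "R2"))
  # a tie at exactly the threshold is kept
  tie <- diag(2)
  tie[1, 2] <- tie[2, 1] <- 0.7
  dimnames(tie) <- list(c("a", "b"), c("a", "b"))
  expect_equal(nrow(threshold_network(tie, 0.7)$edges), 1L)
})

test_that("threshold raising removes edges and never merges modules", {
  set.seed(15)
  s <- hit_and_run_sample(make_ectoine_cycle_model(3)$model, 300,
                          seed = 16)
  rho <- spearman_matrix(s)
  n_prev <- Inf
  mods_prev <- 0L
  for (thr in c(0.3, 0.6, 0.9)) {
    net <- threshold_network(rho, thr)
    expect_lte(nrow(net$edges), n_prev)
    expect_gte(net$n_modules, mods_prev)
    n_prev <- nrow(net$edges)
    mods_prev <- net$n_modules
  }
})

test_that("independent osmolyte cycles are recovered as modules", {
  cyc <- make_ectoine_cycle_model(4)
  s <- hit_and_run_sample(cyc$model, 500, seed = 17)
  subsystems <- stats::setNames(cyc$model$reactions$subsystem,
                                cyc$model$reactions$id)
  net <- threshold_network(spearman_matrix(s), 0.7, subsystems)
  expect_equal(net$n_modules, cyc$truth$n_modules)
  mods <- network_modules(net)
  for (members in cyc$truth$module_members) {
    hit <- vapply(mods, function(mm) setequal(mm, members), logical(1))
    expect_equal(sum(hit), 1L)
  }
  # no inter-module edges by construction
  expect_equal(count_correlations(net), 4L)
  expect_equal(count_correlations(net, c("SYN_1", "DEG_1")), 1L)
  expect_equal(count_correlations(net, c("SYN_1", "SYN_2")), 0L)
})

test_that("edge counting matches the complete-graph formula", {
  m <- 5
  full <- matrix(1, m, m, dimnames = list(paste0("R", 1:m),
                                          paste0("R", 1:m)))
  net <- threshold_network(full, 0.7)
  expect_equal(count_correlations(net), m * (m - 1) / 2)
  expect_equal(count_correlations(net, paste0("R", 1:3)), 3L)
  expect_error(count_correlations(net, "nope"), "unknown")
})

test_that("module partition does not depend on node order", {
  set.seed(18)
  s <- hit_and_run_sample(make_ectoine_cycle_model(3)$model, 300,
                          seed = 19)
  rho <- spearman_matrix(s)
  net1 <- threshold_network(rho, 0.7)
  perm <- sample(ncol(rho))
  net2 <- threshold_network(rho[perm, perm], 0.7)
  part1 <- unname(lapply(network_modules(net1), sort))
  part2 <- unname(lapply(network_modules(net2), sort))
  expect_setequal(part1, part2)
})

test_that("networks export to graphml, sif and tsv", {
  cyc <- make_ectoine_cycle_model(2)
  s <- hit_and_run_sample(cyc$model, 200, seed = 20)
  net <- threshold_network(spearman_matrix(s), 0.7)
  d <- withr::local_tempdir()
  gml <- file.path(d, "net.graphml")
  export_network(net, gml, "graphml")
  expect_true(igraph::is_igraph(igraph::read_graph(gml,
                                                   "graphml")))
  sif <- file.path(d, "net.sif")
  export_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), nrow(net$edges))
  ed <- file.path(d, "edges.tsv")
  export_network(net, ed, "edges")
  expect_equal(nrow(utils::read.delim(ed)), nrow(net$edges))
})
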