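#' Specification for a synthetic toy metabolic model
#'
#' Describes a small three-compartment network emulating the structures
#' that matter for salinity-dependent analyses: alternate glucose
#' catabolism routes differing in ATP and redox stoichiometry (as the
#' EMP/ED alternatives do), an optional lumped TCA-like oxidation loop, an
#' ectoine-like osmolyte whose biomass demand differs between two
#' conditions together with a synthesis/degradation futile cycle, exchange
#' reactions in the outward-positive convention, and GPR rules mixing
#' enzyme complexes and isozymes. All flux truths (growth optimum, forced
#' couplings, essential genes) are computed in closed form from this
#' construction, independently of the LP machinery they later test.
#'
#' @param seed integer seed recorded with the model.
#' @param n_alternate_routes number of glucose catabolism routes (>= 1;
#'   route i yields `i` ATP and `n - i + 1` NADH per glucose, so routes
#'   trade substrate-level ATP against reducing power).
#' @param include_tca_loop include the lumped pyruvate-burning loop.
#' @param osmolyte_drain `c(low, high)` biomass coefficients of the
#'   osmolyte (mmol gDW^-1), the condition-dependent ectoine-like demand.
#' @param uptake default glucose uptake bound (mmol gDW^-1 h^-1).
#' @param atpm non-growth-associated maintenance flux.
#' @param biomass_pyr,biomass_atp pyruvate and ATP demand of one unit of
#'   biomass.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(seed = 1L, n_alternate_routes = 2L,
                     include_tca_loop = TRUE,
                     osmolyte_drain = c(low = 0.1, high = 0.5),
                     uptake = 10, atpm = 7.6, biomass_pyr = 10,
                     biomass_atp = 20) {
  stopifnot(n_alternate_routes >= 1L, uptake > 0, atpm >= 0,
            biomass_pyr > 0, biomass_atp >= 0,
            length(osmolyte_drain) == 2L, all(osmolyte_drain >= 0))
  names(osmolyte_drain) <- c("low", "high")
  structure(list(seed = as.integer(seed),
                 n_alternate_routes = as.integer(n_alternate_routes),
                 include_tca_loop = isTRUE(include_tca_loop),
                 osmolyte_drain = osmolyte_drain, uptake = uptake,
                 atpm = atpm, biomass_pyr = biomass_pyr,
                 biomass_atp = biomass_atp),
            class = "toy_spec")
}

# closed-form growth optimum for the toy construction; independent of the
# LP solver on purpose (it is the oracle the solver is tested against).
# Routes produce 2 pyruvate per glucose; burning one pyruvate yields
# 4 NADH = 8 ATP at P/O 2; the osmolyte costs 1 pyruvate + 1 ATP.
toy_analytic_growth <- function(spec, drain, uptake = spec$uptake,
                                atpm = spec$atpm) {
  i <- seq_len(spec$n_alternate_routes)
  y <- i
  r <- spec$n_alternate_routes - i + 1
  best <- max(y + 2 * r)
  peff <- spec$biomass_pyr + drain
  aeff <- spec$biomass_atp + drain
  mu_pyr <- 2 * uptake / peff
  if (spec$include_tca_loop) {
    mu_atp <- (uptake * (best + 16) - atpm) / (aeff + 8 * peff)
    mu <- min(mu_pyr, mu_atp)
  } else {
    slope <- peff * best / 2 - aeff
    if (slope <= 0 || atpm / slope > mu_pyr) {
      stop("infeasible toy spec: without the TCA loop the ATP balance ",
           "cannot support growth at these coefficients", call. = FALSE)
    }
    mu <- mu_pyr
  }
  if (mu <= 0) stop("infeasible toy spec: non-positive growth",
                    call. = FALSE)
  mu
}

#' Build the synthetic core model with its recorded ground truth
#'
#' @param spec a [toy_spec()].
#' @return list with `model` (a `metabolic_model` containing biomass
#'   reactions `BIO_L` and `BIO_H`, maintenance `ATPM`, and exchanges
#'   `EX_glc`, `EX_o2`, `EX_co2`), `analytic_optimum` (named vector, the
#'   closed-form FBA optimum under each biomass at default bounds),
#'   `couplings` (data.frame of reaction pairs whose fluxes are forced to
#'   a fixed ratio by the stoichiometry) and `essential_genes` (the genes
#'   whose single deletion abolishes growth, derived from the
#'   construction).
#' @export
make_toy_core_model <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  k <- spec$n_alternate_routes
  mets <- c("glc[e]", "glc[p]", "glc[c]", "pyr[c]", "atp[c]", "adp[c]",
            "nad[c]", "nadh[c]", "o2[e]", "o2[c]", "ect[c]")
  if (spec$include_tca_loop) mets <- c(mets, "co2[c]", "co2[e]")

  rxns <- list()
  sto <- list()
  addr <- function(id, name, coefs, lb, ub, gpr = "", kind = NA_character_,
                   subsystem = "") {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, name = name, lb = lb, ub = ub, subsystem = subsystem,
      gpr = gpr, kind = kind, stringsAsFactors = FALSE)
    sto[[length(sto) + 1L]] <<- coefs
  }

  addr("EX_glc", "glucose exchange", c("glc[e]" = -1), -spec$uptake, 0,
       kind = "exchange", subsystem = "Exchange")
  addr("EX_o2", "oxygen exchange", c("o2[e]" = -1), -1000, 0,
       kind = "exchange", subsystem = "Exchange")
  addr("T_glc1", "glucose uptake (outer)",
       c("glc[e]" = -1, "glc[p]" = 1), 0, 1000, gpr = "g_t1",
       subsystem = "Transport")
  addr("T_glc2", "glucose uptake (inner)",
       c("glc[p]" = -1, "glc[c]" = 1), 0, 1000, gpr = "g_t2",
       subsystem = "Transport")
  addr("T_o2", "oxygen diffusion", c("o2[e]" = -1, "o2[c]" = 1), 0, 1000,
       subsystem = "Transport")

  for (i in seq_len(k)) {
    y <- i
    r <- k - i + 1
    gpr <- if (k == 1L) {
      "g_r1a or g_r1b"
    } else if (i == 1L) {
      "g_r1a and g_r1b"
    } else if (i == 2L) {
      "g_r2a or g_r2b"
    } else {
      paste0("g_r", i)
    }
    addr(paste0("ROUTE", i), paste0("glucose catabolism route ", i),
         c("glc[c]" = -1, "adp[c]" = -y, "nad[c]" = -r, "pyr[c]" = 2,
           "atp[c]" = y, "nadh[c]" = r),
         0, 1000, gpr = gpr, subsystem = "Glycolysis")
  }

  if (spec$include_tca_loop) {
    addr("TCA", "pyruvate oxidation loop",
         c("pyr[c]" = -1, "nad[c]" = -4, "co2[c]" = 3, "nadh[c]" = 4),
         0, 1000, gpr = "g_tca", subsystem = "TCA cycle")
    addr("T_co2", "CO2 diffusion", c("co2[c]" = -1, "co2[e]" = 1),
         0, 1000, subsystem = "Transport")
    addr("EX_co2", "CO2 exchange", c("co2[e]" = -1), 0, 1000,
         kind = "exchange", subsystem = "Exchange")
  }

  addr("OXPHOS", "oxidative phosphorylation",
       c("nadh[c]" = -1, "o2[c]" = -0.5, "adp[c]" = -2, "nad[c]" = 1,
         "atp[c]" = 2),
       0, 1000, gpr = "g_ox", subsystem = "Oxidative phosphorylation")
  addr("NOX", "uncoupled NADH oxidase",
       c("nadh[c]" = -1, "o2[c]" = -0.5, "nad[c]" = 1), 0, 1000,
       subsystem = "Oxidative phosphorylation")
  addr("ESYN", "osmolyte synthesis",
       c("pyr[c]" = -1, "atp[c]" = -1, "ect[c]" = 1, "adp[c]" = 1),
       0, 1000, gpr = "g_es1 and g_es2",
       subsystem = "Compatible solutes")
  addr("EDEG", "osmolyte degradation", c("ect[c]" = -1, "pyr[c]" = 1),
       0, 1000, gpr = "g_deg", subsystem = "Compatible solutes")
  addr("ATPM", "ATP maintenance", c("atp[c]" = -1, "adp[c]" = 1),
       spec$atpm, 1000, kind = "maintenance", subsystem = "Maintenance")
  for (cond in c("low", "high")) {
    e <- spec$osmolyte_drain[[cond]]
    addr(paste0("BIO_", toupper(substr(cond, 1, 1))),
         paste0("biomass (", cond, " salinity)"),
         c("pyr[c]" = -spec$biomass_pyr, "atp[c]" = -spec$biomass_atp,
           "ect[c]" = -e, "adp[c]" = spec$biomass_atp),
         0, 1000, kind = "biomass", subsystem = "Biomass")
  }

  met_df <- data.frame(id = mets, compartment = compartment_of(mets),
                       stringsAsFactors = FALSE)
  model <- metabolic_model(met_df, do.call(rbind, rxns), sto,
                           objective_id = "BIO_L")

  analytic <- c(
    low = toy_analytic_growth(spec, spec$osmolyte_drain[["low"]]),
    high = toy_analytic_growth(spec, spec$osmolyte_drain[["high"]]))

  # forced couplings: glc[e] and glc[p] each connect exactly two columns,
  # so T_glc1 = T_glc2 = -EX_glc in every steady state; o2 likewise.
  couplings <- data.frame(
    rxn_a = c("T_glc1", "EX_glc", "T_o2"),
    rxn_b = c("T_glc2", "T_glc1", "EX_o2"),
    ratio = c(1, -1, -1), stringsAsFactors = FALSE)

  # glucose transport and (for nonzero osmolyte demand) the synthesis
  # complex sit on mandatory paths; respiration and the TCA loop are
  # dispensable as long as substrate-level ATP alone covers maintenance,
  # which the guard below pins down so the recorded set stays exact
  if (max(seq_len(k)) * spec$uptake <= spec$atpm) {
    stop("infeasible toy spec: substrate-level ATP cannot cover ",
         "maintenance without respiration; essential-gene truth would ",
         "be ambiguous", call. = FALSE)
  }
  essential <- c("g_t1", "g_t2")
  if (min(spec$osmolyte_drain) > 0) essential <- c(essential, "g_es1",
                                                   "g_es2")
  list(model = model, analytic_optimum = analytic, couplings = couplings,
       essential_genes = essential, spec = spec)
}

#' Build a matched low/high-salinity condition pair with recorded truth
#'
#' The two conditions differ in biomass formulation (`BIO_L` vs `BIO_H`,
#' i.e. the osmolyte demand), in glucose uptake, and in the maintenance
#' flux, which is fixed higher under the high-salinity condition (salt
#' stress is energetically expensive). Because the maintenance flux is an
#' equality in both conditions, its sampled flux distribution is a point
#' mass in each, making the between-condition shift of that reaction known
#' exactly — the `planted_shift` entry records it for recovery tests.
#'
#' @param spec a [toy_spec()].
#' @param uptake_high glucose uptake bound of the high-salinity condition.
#' @param atpm_high maintenance flux fixed under high salinity.
#' @return list with `low` and `high` [condition_spec()]s and `truth`
#'   (`growth`, named low/high closed-form optima under each condition;
#'   `planted_shift`, reaction id and exact high-minus-low difference).
#' @export
make_condition_pair <- function(spec = toy_spec(), uptake_high = 6.5,
                                atpm_high = 15.2) {
  low <- condition_spec("low", "BIO_L",
                        exchange_bounds = list(EX_glc = c(-spec$uptake, 0)),
                        atpm_id = "ATPM", atpm_flux = spec$atpm)
  high <- condition_spec("high", "BIO_H",
                         exchange_bounds = list(EX_glc = c(-uptake_high, 0)),
                         atpm_id = "ATPM", atpm_flux = atpm_high)
  truth <- list(
    growth = c(
      low = toy_analytic_growth(spec, spec$osmolyte_drain[["low"]]),
      high = toy_analytic_growth(spec, spec$osmolyte_drain[["high"]],
                                 uptake = uptake_high,
                                 atpm = atpm_high)),
    planted_shift = list(reaction = "ATPM",
                         difference = atpm_high - spec$atpm))
  list(low = low, high = high, truth = truth)
}

#' Independent osmolyte futile cycles for module-recovery tests
#'
#' A model of `n_cycles` disconnected synthesis/degradation cycles: within
#' cycle k the two reactions `SYN_k` and `DEG_k` are forced to equal flux
#' (a free cycle flux in `[0, cap]`), while fluxes of different cycles are
#' mutually unconstrained. Uniform sampling therefore gives perfect rank
#' correlation within a cycle and vanishing correlation between cycles, so
#' a thresholded correlation network must recover exactly `n_cycles`
#' modules with no inter-module edges.
#'
#' @param n_cycles number of independent cycles.
#' @param cap upper flux bound of every cycle reaction.
#' @return list with `model` and `truth` (`n_modules`, `module_members`).
#' @export
make_ectoine_cycle_model <- function(n_cycles = 4L, cap = 10) {
  stopifnot(n_cycles >= 1L, cap > 0)
  mets <- character(0)
  rxns <- list()
  sto <- list()
  members <- vector("list", n_cycles)
  for (kk in seq_len(n_cycles)) {
    x <- sprintf("cyc%d_a[c]", kk)
    y <- sprintf("cyc%d_b[c]", kk)
    mets <- c(mets, x, y)
    syn <- sprintf("SYN_%d", kk)
    deg <- sprintf("DEG_%d", kk)
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = syn, name = syn, lb = 0, ub = cap,
      subsystem = sprintf("Cycle %d", kk), gpr = "",
      kind = "metabolic", stringsAsFactors = FALSE)
    sto[[length(sto) + 1L]] <- stats::setNames(c(-1, 1), c(x, y))
    rxns[[length(rxns) + 1L]] <- data.frame(
      id = deg, name = deg, lb = 0, ub = cap,
      subsystem = sprintf("Cycle %d", kk), gpr = "",
      kind = "metabolic", stringsAsFactors = FALSE)
    sto[[length(sto) + 1L]] <- stats::setNames(c(-1, 1), c(y, x))
    members[[kk]] <- c(syn, deg)
  }
  met_df <- data.frame(id = mets, compartment = compartment_of(mets),
                       stringsAsFactors = FALSE)
  model <- metabolic_model(met_df, do.call(rbind, rxns), sto)
  list(model = model,
       truth = list(n_modules = n_cycles, module_members = members))
}

#' Random sparse feasible network for oracle fuzzing
#'
#' Builds a random network that is feasible by construction: a spanning
#' uptake-chain-secretion pathway touches every metabolite, and the
#' remaining reaction budget is filled with random unit-coefficient
#' reactions over random metabolite pairs or triples, randomly reversible.
#' Used to fuzz the LP engine against vertex enumeration, the gap finder
#' against graph reachability, and the readers/writers against round
#' trips.
#'
#' @param m number of internal metabolites (>= 1).
#' @param n number of reactions (>= m + 1, to fit the spanning pathway).
#' @param seed integer seed; output is deterministic given `(m, n, seed)`.
#' @param simple if `TRUE`, extra reactions have one substrate and one
#'   product only (keeps stoichiometry BFS-equivalent for gap oracles).
#' @return a `metabolic_model`.
#' @export
make_random_network <- function(m, n, seed = 1L, simple = TRUE) {
  stopifnot(m >= 1L, n >= m + 1L)
  set.seed(seed)
  mets <- sprintf("m%d[c]", seq_len(m))
  rxns <- list()
  sto <- list()
  addr <- function(id, coefs, lb, ub) {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, name = id, lb = lb, ub = ub, subsystem = "", gpr = "",
      kind = NA_character_, stringsAsFactors = FALSE)
    sto[[length(sto) + 1L]] <<- coefs
  }
  addr("EX_in", stats::setNames(-1, mets[1]), -10, 0)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      addr(sprintf("CHAIN%d", i),
           stats::setNames(c(-1, 1), mets[c(i, i + 1L)]), 0, 10)
    }
  }
  addr("EX_out", stats::setNames(-1, mets[m]), 0, 10)
  extra <- n - length(rxns)
  for (jj in seq_len(extra)) {
    size <- if (simple || m < 3L) 2L else sample(2:3, 1L)
    size <- min(size, m)
    picks <- sample.int(m, size)
    coefs <- stats::setNames(c(-1, rep(1, size - 1L)), mets[picks])
    lb <- if (stats::runif(1) < 0.3) -10 else 0
    addr(sprintf("RND%d", jj), coefs, lb, 10)
  }
  met_df <- data.frame(id = mets, compartment = compartment_of(mets),
                       stringsAsFactors = FALSE)
  metabolic_model(met_df, do.call(rbind, rxns), sto)
}
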