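#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject to
#' steady-state mass balance `S v = 0` and the reaction bounds. When the
#' objective is a biomass reaction the optimum is the maximum specific growth
#' rate in h^-1. Infeasibility and unboundedness are reported in the
#' `status` field, not as errors. Only the objective value is canonical: at
#' degenerate optima many flux vectors achieve it, and the one returned is
#' whichever vertex the simplex ended on.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction id to optimize; defaults to the model's
#'   objective.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"failed"`), `objective` (the optimum), `fluxes`
#'   (named vector over all reactions) and `objective_id`.
#' @examples
#' toy <- make_toy_core_model(toy_spec(seed = 1))
#' sol <- fba(toy$model)
#' sol$objective
#' @export
fba <- function(model, objective_id = model$objective_id,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.null(objective_id) || is.na(objective_id)) {
    stop("model has no objective reaction", call. = FALSE)
  }
  j <- rxn_index(model, objective_id)
  S <- build_S(model)
  obj <- numeric(ncol(S))
  obj[j] <- 1
  res <- lp_flux(S, model$reactions$lb, model$reactions$ub, obj,
                 sense = sense)
  fluxes <- stats::setNames(res$fluxes, model$reactions$id)
  if (res$status == "optimal" &&
      !flux_is_valid(S, res$fluxes, model$reactions$lb,
                     model$reactions$ub, balance_tol = 1e-6,
                     bound_tol = 1e-6)) {
    warning("LP solution failed post-validation at 1e-6; treating as failed")
    res$status <- "failed"
  }
  structure(list(status = res$status, objective = res$objective,
                 fluxes = fluxes, objective_id = objective_id,
                 sense = sense),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  %s of %s = %.6g\n", x$sense, x$objective_id,
                x$objective))
  }
  invisible(x)
}

# growth below this (h^-1) counts as no growth
growth_epsilon <- 1e-6

#' Condition specifications: exchange-bound overrides plus a biomass choice
#'
#' A condition bundles what distinguishes one simulated environment from
#' another: which biomass reaction is the objective (e.g. the low- versus
#' high-salinity formulation), overrides of exchange-reaction bounds
#' (measured uptake and secretion rates; uptake is a negative lower bound),
#' and the obligatory non-growth-associated ATP maintenance flux, fixed as
#' an equality because upkeep is not optional.
#'
#' @param name label of the condition.
#' @param biomass_id id of the biomass reaction to use as objective.
#' @param exchange_bounds named list mapping exchange (or maintenance)
#'   reaction ids to `c(lower, upper)` bounds in mmol gDW^-1 h^-1.
#' @param atpm_id id of the ATP maintenance reaction, or `NULL` if the
#'   model has none.
#' @param atpm_flux maintenance flux fixed at both bounds; default 7.6
#'   mmol gDW^-1 h^-1.
#' @return A `condition_spec` object.
#' @export
condition_spec <- function(name, biomass_id, exchange_bounds = list(),
                           atpm_id = NULL, atpm_flux = 7.6) {
  stopifnot(is.character(name), is.character(biomass_id))
  for (b in exchange_bounds) {
    if (length(b) != 2L || b[1] > b[2]) {
      stop("each exchange override must be c(lower, upper) with lower <= upper",
           call. = FALSE)
    }
  }
  structure(list(name = name, biomass_id = biomass_id,
                 exchange_bounds = exchange_bounds, atpm_id = atpm_id,
                 atpm_flux = atpm_flux),
            class = "condition_spec")
}

#' @rdname condition_spec
#' @param path YAML file with fields `name`, `biomass`, optional `exchanges`
#'   (map of id to `[lower, upper]`), optional `atpm: {id: ..., flux: ...}`.
#' @export
read_condition <- function(path) {
  y <- yaml::read_yaml(path)
  condition_spec(
    name = y$name %||% basename(path),
    biomass_id = y$biomass,
    exchange_bounds = lapply(y$exchanges %||% list(), as.numeric),
    atpm_id = y$atpm$id,
    atpm_flux = y$atpm$flux %||% 7.6)
}

#' Apply a condition to a model
#'
#' Returns a modified copy: exchange overrides installed, ATP maintenance
#' fixed at both bounds, the objective switched to the condition's biomass
#' reaction, and any alternate biomass formulations closed to zero flux.
#' The original model is untouched, and applying the same condition twice
#' is a no-op the second time.
#'
#' @param model a `metabolic_model`.
#' @param cond a [condition_spec()].
#' @return the modified model.
#' @export
apply_condition <- function(model, cond) {
  stopifnot(inherits(cond, "condition_spec"))
  if (!(cond$biomass_id %in% model$reactions$id)) {
    stop("condition biomass reaction '", cond$biomass_id,
         "' not in model", call. = FALSE)
  }
  ids <- names(cond$exchange_bounds)
  idx <- rxn_index(model, ids)
  not_boundary <- !(model$reactions$kind[idx] %in%
                      c("exchange", "maintenance"))
  if (any(not_boundary)) {
    stop("condition overrides non-exchange reaction(s): ",
         paste(ids[not_boundary], collapse = ", "), call. = FALSE)
  }
  for (id in ids) {
    b <- cond$exchange_bounds[[id]]
    model <- set_bounds(model, id, lb = b[1], ub = b[2])
  }
  if (!is.null(cond$atpm_id)) {
    model <- set_bounds(model, cond$atpm_id, lb = cond$atpm_flux,
                        ub = cond$atpm_flux)
  }
  # the condition selects one biomass formulation; alternates are closed
  other_bio <- setdiff(
    model$reactions$id[model$reactions$kind == "biomass"],
    cond$biomass_id)
  for (id in other_bio) model <- set_bounds(model, id, lb = 0, ub = 0)
  model$objective_id <- cond$biomass_id
  model
}

#' Configure a minimal mineral medium
#'
#' Mirrors an M63-style minimal medium: the listed inorganic exchanges
#' (salts, ions, water, O2 for aerobic growth) are opened to (-1000, 1000),
#' while every other exchange has its lower bound closed to 0, so nothing
#' organic enters until a carbon source is opened explicitly.
#'
#' @param model a `metabolic_model`.
#' @param medium_exchanges character vector of exchange reaction ids to
#'   open; ids absent from the model are reported with a warning and
#'   skipped.
#' @return the modified model.
#' @export
set_minimal_medium <- function(model, medium_exchanges) {
  ex <- exchange_reactions(model)
  missing_ids <- setdiff(medium_exchanges, ex)
  if (length(missing_ids)) {
    warning("medium exchanges not in model, skipped: ",
            paste(missing_ids, collapse = ", "))
    medium_exchanges <- intersect(medium_exchanges, ex)
  }
  for (id in setdiff(ex, medium_exchanges)) {
    model <- set_bounds(model, id, lb = 0)
  }
  for (id in medium_exchanges) {
    model <- set_bounds(model, id, lb = -1000, ub = 1000)
  }
  model
}

#' Screen candidate carbon sources for growth support
#'
#' One FBA per candidate: all candidate exchanges (and the reference carbon
#' source, typically glucose) are closed, the candidate under test is opened
#' at the given uptake rate, and growth is maximized. A source supports
#' growth when the optimum exceeds the no-growth threshold of 1e-6 h^-1;
#' infeasible problems count as no growth.
#'
#' @param model a `metabolic_model`, normally after [set_minimal_medium()].
#' @param source_exchange_ids exchange reaction ids of the candidate carbon
#'   sources.
#' @param uptake uptake rate tested, mmol gDW^-1 h^-1 (default 10; applied
#'   as lower bound `-uptake`).
#' @param close_ids additional exchange ids to keep closed throughout
#'   (e.g. the default glucose supply).
#' @return data.frame with columns `source`, `growth_rate`, `grows`.
#' @export
screen_carbon_sources <- function(model, source_exchange_ids, uptake = 10,
                                  close_ids = character()) {
  all_ids <- union(source_exchange_ids, close_ids)
  idx <- rxn_index(model, all_ids)
  not_ex <- model$reactions$kind[idx] != "exchange"
  if (any(not_ex)) {
    stop("not exchange reactions: ",
         paste(all_ids[not_ex], collapse = ", "), call. = FALSE)
  }
  base <- model
  for (id in all_ids) base <- set_bounds(base, id, lb = 0)
  res <- lapply(source_exchange_ids, function(id) {
    m <- set_bounds(base, id, lb = -uptake)
    sol <- fba(m)
    g <- if (sol$status == "optimal") sol$objective else 0
    data.frame(source = id, growth_rate = g,
               grows = g > growth_epsilon, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Single-gene deletion essentiality screen
#'
#' For each gene, every reaction whose GPR rule evaluates to inactive with
#' that gene knocked out is constrained to zero flux, and growth is
#' re-maximized. Isozymes (OR) rescue a deletion; complexes (AND) do not. A
#' gene is essential when post-deletion growth falls below 1e-6 h^-1. Genes
#' absent from all GPR rules never change the optimum.
#'
#' @param model a `metabolic_model` (apply the condition first).
#' @param genes genes to screen; defaults to all model genes.
#' @return An `essentiality_report`: data.frame with columns `gene`,
#'   `growth_rate`, `essential`, plus attributes `wild_type_growth` and
#'   `condition`.
#' @export
single_gene_deletions <- function(model, genes = model$genes) {
  wt <- fba(model)
  if (wt$status != "optimal") {
    stop("wild-type FBA not optimal (", wt$status,
         "); cannot screen deletions", call. = FALSE)
  }
  trees <- lapply(model$reactions$gpr, parse_gpr)
  gene_sets <- lapply(trees, gpr_genes)
  rows <- lapply(genes, function(g) {
    hit <- which(vapply(seq_along(trees), function(i) {
      g %in% gene_sets[[i]] && !evaluate_gpr(trees[[i]], g)
    }, logical(1)))
    if (!length(hit)) {
      growth <- wt$objective
    } else {
      m <- model
      m$reactions$lb[hit] <- 0
      m$reactions$ub[hit] <- 0
      sol <- fba(m)
      growth <- if (sol$status == "optimal") sol$objective else 0
    }
    data.frame(gene = g, growth_rate = growth,
               essential = growth < growth_epsilon,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "wild_type_growth") <- wt$objective
  class(out) <- c("essentiality_report", class(out))
  out
}

#' Compare gene essentiality between two conditions
#'
#' @param report_a,report_b `essentiality_report`s from
#'   [single_gene_deletions()] run under two conditions (e.g. low and high
#'   salinity).
#' @return list with `essential_a`, `essential_b`, `shared`, `only_a`,
#'   `only_b` gene-id vectors.
#' @export
compare_essentiality <- function(report_a, report_b) {
  ea <- report_a$gene[report_a$essential]
  eb <- report_b$gene[report_b$essential]
  list(essential_a = ea, essential_b = eb,
       shared = intersect(ea, eb),
       only_a = setdiff(ea, eb), only_b = setdiff(eb, ea))
}

#' Maximum ATP yield per mole of substrate
#'
#' Fixes biomass production to zero and the substrate uptake to the given
#' rate, relaxes the ATP maintenance reaction to (0, 1000) and maximizes its
#' flux; the yield is that optimum divided by the uptake, in mol ATP per mol
#' substrate.
#'
#' @param model a `metabolic_model`.
#' @param substrate_exchange_id exchange reaction of the substrate.
#' @param atpm_id id of the ATP-hydrolysis maintenance reaction; defaults to
#'   the first reaction of kind `"maintenance"`.
#' @param uptake substrate uptake rate (default 10 mmol gDW^-1 h^-1).
#' @return the yield (mol ATP per mol substrate), or `NA` if infeasible.
#' @export
atp_yield_per_substrate <- function(model, substrate_exchange_id,
                                    atpm_id = NULL, uptake = 10) {
  if (is.null(atpm_id)) {
    maint <- model$reactions$id[model$reactions$kind == "maintenance"]
    if (!length(maint)) {
      stop("model has no ATP maintenance reaction", call. = FALSE)
    }
    atpm_id <- maint[[1]]
  }
  bio <- model$reactions$id[model$reactions$kind == "biomass"]
  for (id in bio) model <- set_bounds(model, id, lb = 0, ub = 0)
  model <- set_bounds(model, substrate_exchange_id, lb = -uptake,
                      ub = -uptake)
  model <- set_bounds(model, atpm_id, lb = 0, ub = 1000)
  sol <- fba(model, objective_id = atpm_id, sense = "max")
  if (sol$status != "optimal") return(NA_real_)
  sol$objective / uptake
}
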