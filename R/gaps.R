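#' Root no-production and no-consumption metabolites
#'
#' A sign scan of the stoichiometric matrix after expanding every reversible
#' reaction into its forward and reverse directions: a metabolite every
#' signed occurrence of which is negative can never be produced (root
#' no-production); one whose occurrences are all positive can never be
#' consumed (root no-consumption). Exchange reactions count — an open uptake
#' produces its metabolite in the reverse direction. Metabolites that occur
#' in no reaction fall in both sets.
#'
#' @param model a `metabolic_model`.
#' @return list with character vectors `root_no_production` and
#'   `root_no_consumption`.
#' @export
root_gaps <- function(model) {
  S <- as.matrix(build_S(model))
  rev <- model$reactions$lb < 0
  S_dir <- cbind(S, -S[, rev, drop = FALSE])
  produced <- rowSums(S_dir > 0) > 0
  consumed <- rowSums(S_dir < 0) > 0
  list(root_no_production = rownames(S)[!produced],
       root_no_consumption = rownames(S)[!consumed])
}

#' Detect blocked (dead-end) metabolites by flux-capacity testing
#'
#' For each metabolite, production capacity is probed by adding a temporary
#' sink and maximizing its flux with all exchange reactions opened to
#' (-1000, 1000); the metabolite is blocked for production when the optimum
#' stays at zero (within `tol`). Consumption is probed symmetrically with a
#' temporary source. Downstream no-production and upstream no-consumption
#' gaps are the blocked sets minus the corresponding root sets of
#' [root_gaps()].
#'
#' Two mass-balance modes are reported by the same machinery: `"strict"`
#' enforces S v = 0 for every metabolite, while `"relaxed"` lets every
#' metabolite accumulate (S v >= 0) by giving each row its own slack sink,
#' so only true synthesis capability, not downstream consumption, limits
#' the test.
#'
#' @param model a `metabolic_model`.
#' @param mode `"strict"` or `"relaxed"` mass balance.
#' @param tol flux threshold below which capacity counts as zero.
#' @return a `gap_report`: list with the four gap sets, `blocked_total`,
#'   `blocked_fraction` and `mode`.
#' @export
blocked_metabolites <- function(model, mode = c("strict", "relaxed"),
                                tol = 1e-8) {
  mode <- match.arg(mode)
  for (id in exchange_reactions(model)) {
    model <- set_bounds(model, id, lb = -1000, ub = 1000)
  }
  S <- as.matrix(build_S(model))
  m <- nrow(S)
  n <- ncol(S)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  if (mode == "relaxed") {
    S <- cbind(S, -diag(m))
    lb <- c(lb, rep(0, m))
    ub <- c(ub, rep(1000, m))
    n <- n + m
  }
  can_produce <- logical(m)
  can_consume <- logical(m)
  for (i in seq_len(m)) {
    sink <- numeric(m); sink[i] <- -1
    Si <- cbind(S, sink)
    obj <- c(numeric(n), 1)
    res <- lp_flux(Si, c(lb, 0), c(ub, 1000), obj, sense = "max")
    can_produce[i] <- res$status == "optimal" && res$objective > tol
    Si[, n + 1L] <- -sink
    res <- lp_flux(Si, c(lb, 0), c(ub, 1000), obj, sense = "max")
    can_consume[i] <- res$status == "optimal" && res$objective > tol
  }
  met_ids <- model$metabolites$id
  roots <- root_gaps(model)
  no_prod <- met_ids[!can_produce]
  no_cons <- met_ids[!can_consume]
  all_blocked <- union(union(no_prod, no_cons),
                       union(roots$root_no_production,
                             roots$root_no_consumption))
  structure(list(
    root_no_production = roots$root_no_production,
    root_no_consumption = roots$root_no_consumption,
    downstream_no_production = setdiff(no_prod,
                                       roots$root_no_production),
    upstream_no_consumption = setdiff(no_cons,
                                      roots$root_no_consumption),
    blocked_total = length(all_blocked),
    blocked_fraction = length(all_blocked) / length(met_ids),
    mode = mode), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Gap report (", x$mode, " mass balance)\n", sep = "")
  cat("  root no-production:      ", length(x$root_no_production), "\n")
  cat("  root no-consumption:     ", length(x$root_no_consumption), "\n")
  cat("  downstream no-production:", length(x$downstream_no_production),
      "\n")
  cat("  upstream no-consumption: ", length(x$upstream_no_consumption),
      "\n")
  cat(sprintf("  blocked total: %d (%.2f%% of metabolites)\n",
              x$blocked_total, 100 * x$blocked_fraction))
  invisible(x)
}
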