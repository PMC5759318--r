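#' Construct a compartmentalized metabolic model
#'
#' The central container of the package: a stoichiometric reconstruction with
#' metabolites assigned to compartments (cytoplasm `c`, periplasm `p`,
#' extracellular `e`), reactions with flux bounds in mmol gDW^-1 h^-1,
#' gene-protein-reaction rules, and an objective reaction (normally a biomass
#' pseudo-reaction whose flux is the specific growth rate in h^-1).
#'
#' Metabolite ids carry their compartment as a bracketed suffix
#' (`"glc-d[c]"`); the `compartment` column must agree with the suffix.
#' Exchange reactions follow the outward-positive convention: negative flux
#' is uptake, so a glucose supply of 10 mmol gDW^-1 h^-1 is a lower bound of
#' -10 on the glucose exchange.
#'
#' @param metabolites data.frame with columns `id`, `name`, `formula`,
#'   `charge`, `compartment`. Missing optional columns are filled.
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `subsystem`, `gpr`, `kind`; `kind` is one of `"metabolic"`,
#'   `"transport"`, `"exchange"`, `"biomass"`, `"maintenance"` and is
#'   auto-classified from the stoichiometry when `NA`.
#' @param stoichiometry named list parallel to `reactions$id`; each element a
#'   named numeric vector mapping metabolite id to coefficient (negative =
#'   consumed, positive = produced).
#' @param genes character vector of gene ids; defaults to the union of genes
#'   appearing in GPR rules.
#' @param objective_id id of the objective reaction; defaults to the first
#'   reaction of kind `"biomass"`, if any.
#' @return An object of class `metabolic_model`.
#' @examples
#' mets <- data.frame(id = c("a[c]", "b[c]"), compartment = c("c", "c"))
#' rxns <- data.frame(id = c("EX_a", "R1"), lb = c(-10, 0), ub = c(0, 1000))
#' sto <- list(EX_a = c("a[c]" = -1), R1 = c("a[c]" = -1, "b[c]" = 1))
#' m <- metabolic_model(mets, rxns, sto)
#' m
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL, objective_id = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  metabolites <- fill_columns(metabolites, list(
    name = NA_character_, formula = "", charge = NA_integer_,
    compartment = NA_character_))
  reactions <- fill_columns(reactions, list(
    name = NA_character_, lb = -1000, ub = 1000, subsystem = "",
    gpr = "", kind = NA_character_))
  metabolites$name <- ifelse(is.na(metabolites$name), metabolites$id,
                             metabolites$name)
  reactions$name <- ifelse(is.na(reactions$name), reactions$id,
                           reactions$name)
  miss_cmp <- is.na(metabolites$compartment)
  metabolites$compartment[miss_cmp] <-
    compartment_of(metabolites$id[miss_cmp])
  reactions$gpr[is.na(reactions$gpr)] <- ""

  stoichiometry <- lapply(stoichiometry, function(x) x[x != 0])
  names(stoichiometry) <- reactions$id

  na_kind <- is.na(reactions$kind)
  if (any(na_kind)) {
    reactions$kind[na_kind] <- vapply(
      stoichiometry[na_kind], classify_reaction, character(1))
  }
  reactions$reversible <- reactions$lb < 0 & reactions$kind != "exchange"

  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  if (is.null(objective_id)) {
    bio <- reactions$id[reactions$kind == "biomass"]
    objective_id <- if (length(bio)) bio[[1]] else NA_character_
  }

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = genes,
         objective_id = objective_id),
    class = "metabolic_model")
  validate_model(model)
  model
}

fill_columns <- function(df, defaults) {
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  }
  df
}

# exchange: single metabolite; transport: spans >1 compartment;
# biomass/maintenance cannot be inferred and must be declared.
classify_reaction <- function(coefs) {
  if (length(coefs) <= 1L) return("exchange")
  cmp <- unique(compartment_of(names(coefs)))
  if (length(cmp) > 1L) "transport" else "metabolic"
}

#' Extract the compartment suffix of metabolite ids
#'
#' @param ids character vector of metabolite ids such as `"glc-d[c]"`.
#' @return character vector of compartment codes (`"c"`, `"p"`, `"e"`, ...).
#' @export
compartment_of <- function(ids) {
  out <- sub("^.*\\[([^]]+)\\]$", "\\1", ids)
  out[!grepl("\\[[^]]+\\]$", ids)] <- NA_character_
  out
}

reaction_kinds <- c("metabolic", "transport", "exchange", "biomass",
                    "maintenance")

#' Validate a metabolic model's internal consistency
#'
#' Checks id uniqueness, compartment suffix agreement, bound ordering,
#' resolution of stoichiometry keys and GPR genes, and the objective id.
#' Called by [metabolic_model()]; exported so readers can re-validate.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "),
         call. = FALSE)
  }
  suffix <- compartment_of(mets$id)
  bad <- !is.na(suffix) & suffix != mets$compartment
  if (any(bad)) {
    stop("compartment field disagrees with id suffix for: ",
         paste(mets$id[bad], collapse = ", "), call. = FALSE)
  }
  if (any(rxns$lb > rxns$ub)) {
    stop("lower bound exceeds upper bound for: ",
         paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "), call. = FALSE)
  }
  if (!all(rxns$kind %in% reaction_kinds)) {
    stop("unknown reaction kind: ",
         paste(setdiff(rxns$kind, reaction_kinds), collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(unlist(lapply(model$stoichiometry, names)))
  unknown <- setdiff(keys, mets$id)
  if (length(unknown)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rule_genes <- unique(unlist(lapply(rxns$gpr, gpr_genes)))
  orphan <- setdiff(rule_genes, model$genes)
  if (length(orphan)) {
    stop("GPR rules reference genes missing from the gene list: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (!is.na(model$objective_id) &&
      !(model$objective_id %in% rxns$id)) {
    stop("objective_id '", model$objective_id,
         "' is not a reaction id", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes\n")
  kinds <- table(x$reactions$kind)
  cat("  reactions by kind:",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  cat("  objective:", x$objective_id, "\n")
  invisible(x)
}

#' Build the stoichiometric matrix S
#'
#' Returns the m x n sparse matrix whose entry (i, j) is the coefficient of
#' metabolite i in reaction j; at steady state the flux vector v satisfies
#' `S %*% v = 0` (no net accumulation of any internal metabolite).
#'
#' @param model a `metabolic_model`.
#' @return a sparse `Matrix::dgCMatrix` with metabolite ids as rownames and
#'   reaction ids as colnames.
#' @export
build_S <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(rxn_ids)) {
    coefs <- model$stoichiometry[[j]]
    if (!length(coefs)) next
    ii <- c(ii, met_index[names(coefs)])
    jj <- c(jj, rep.int(j, length(coefs)))
    xx <- c(xx, unname(coefs))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Ids of exchange reactions
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids with kind `"exchange"`.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[model$reactions$kind == "exchange"]
}

#' Summary counts of a model, optionally as JSON
#'
#' Tabulates metabolites per compartment and reactions per kind and per
#' compartment class. A reaction's compartment class is derived from the set
#' of distinct compartments among its participants: a single compartment
#' yields that compartment, several yield `"multiple"`; this classification
#' rule is the package's own and is reported alongside the raw counts.
#'
#' @param model a `metabolic_model`.
#' @param json if `TRUE`, return a JSON string instead of a list.
#' @return a list (or JSON string) of summary counts.
#' @export
model_summary <- function(model, json = FALSE) {
  rxns <- model$reactions
  cmp_class <- vapply(model$stoichiometry, function(coefs) {
    if (!length(coefs)) return("none")
    cmp <- unique(compartment_of(names(coefs)))
    if (length(cmp) == 1L) cmp else "multiple"
  }, character(1))
  out <- list(
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(rxns),
    n_genes = length(model$genes),
    reactions_by_kind = as.list(table(rxns$kind)),
    metabolic_reactions_by_compartment =
      as.list(table(cmp_class[rxns$kind == "metabolic"])),
    metabolites_by_compartment =
      as.list(table(model$metabolites$compartment)),
    objective_id = model$objective_id)
  if (json) jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE) else out
}

# convenience accessors used across modules -------------------------------

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}
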