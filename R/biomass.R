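#' Growth-associated ATP maintenance (GAM)
#'
#' Total GAM is the sum of a growth-associated base cost (ATP spent on
#' processes that scale with growth but are not polymerization) and the
#' macromolecule polymerization cost, both in mmol ATP per gDW. The two
#' published-style inputs carry two decimals, so the sum is computed in
#' integer hundredths to keep reports free of floating-point drift: 36.94 +
#' 23.04 gives exactly 59.98 and 36.94 + 8.79 exactly 45.73.
#'
#' @param gam_base base growth-associated maintenance, mmol gDW^-1.
#' @param polymerization_cost polymerization ATP cost, mmol gDW^-1; under
#'   osmotic stress the macromolecular composition shifts, so this differs
#'   between salinities.
#' @return total GAM in mmol gDW^-1.
#' @examples
#' compute_gam(36.94, 23.04) # low-salinity biomass
#' compute_gam(36.94, 8.79)  # high-salinity biomass
#' @export
compute_gam <- function(gam_base, polymerization_cost) {
  if (gam_base < 0 || polymerization_cost < 0) {
    stop("GAM components must be non-negative", call. = FALSE)
  }
  (round(gam_base * 100) + round(polymerization_cost * 100)) / 100
}

#' Amino-acid molar ratios from a proteome
#'
#' Computes the molar ratio of each of the 20 proteinogenic amino acids
#' under the equal-expression assumption: every protein contributes its
#' residues once, and the ratio of residue a is count(a) over the total
#' residue count of the concatenated proteome.
#'
#' @param coding_sequences character vector of protein sequences over the
#'   standard 20-letter alphabet; ambiguity codes are rejected.
#' @return named numeric vector of 20 ratios summing to 1.
#' @export
amino_acid_ratios_from_proteome <- function(coding_sequences) {
  if (length(coding_sequences) == 0L ||
      sum(nchar(coding_sequences)) == 0L) {
    stop("empty proteome", call. = FALSE)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in seq_along(coding_sequences)) {
    letters_i <- strsplit(toupper(coding_sequences[i]), "")[[1]]
    bad <- setdiff(letters_i, aa)
    if (length(bad)) {
      stop("non-standard amino acid letter(s) ",
           paste(bad, collapse = ", "), " in sequence ", i, call. = FALSE)
    }
  }
  all_res <- strsplit(paste(toupper(coding_sequences), collapse = ""),
                      "")[[1]]
  counts <- table(factor(all_res, levels = aa))
  ratios <- as.numeric(counts) / length(all_res)
  stats::setNames(ratios, aa)
}

#' Deoxyribonucleotide molar ratios from genomic G+C content
#'
#' With strand symmetry, dG and dC each take half the G+C fraction and dA
#' and dT each half the remainder.
#'
#' @param gc_fraction genomic G+C content in `[0, 1]`.
#' @return named numeric vector `c(dA, dC, dG, dT)` summing to 1.
#' @export
dnt_ratios_from_gc <- function(gc_fraction) {
  if (!is.finite(gc_fraction) || gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  c(dA = (1 - gc_fraction) / 2, dC = gc_fraction / 2,
    dG = gc_fraction / 2, dT = (1 - gc_fraction) / 2)
}

#' Condition-specific biomass composition
#'
#' Bundles everything needed to assemble one salinity-specific biomass
#' reaction: macromolecule mass fractions (g per gDW), molar ratios of the
#' monomers within each macromolecule group, growth-associated solute
#' demands (ectoine and hydroxyectoine accumulate with growth, so they enter
#' the biomass reaction directly, with coefficients that rise with
#' salinity), and the ATP maintenance parameters.
#'
#' @param condition label, conventionally `"low"` or `"high"` (salinity).
#' @param mass_fractions named numeric, g gDW^-1 per macromolecule group
#'   (e.g. protein, dna, rna, lipid); must sum to 1 within 0.05 (template
#'   values are rounded).
#' @param monomer_ratios named list, one numeric vector per group in
#'   `mass_fractions`, mapping monomer metabolite ids to molar ratios that
#'   sum to 1 within 1e-9.
#' @param solute_coefficients named numeric, mmol gDW^-1 demands keyed by
#'   metabolite id (ectoine-like osmolytes).
#' @param gam_base,polymerization_cost see [compute_gam()].
#' @param ngam non-growth-associated maintenance, mmol gDW^-1 h^-1
#'   (default 7.6); carried along for conditions.
#' @return a `biomass_composition` object.
#' @export
biomass_composition <- function(condition, mass_fractions, monomer_ratios,
                                solute_coefficients = numeric(),
                                gam_base = 36.94, polymerization_cost = 0,
                                ngam = 7.6) {
  stopifnot(is.numeric(mass_fractions), !is.null(names(mass_fractions)))
  if (any(mass_fractions < 0) || any(unlist(monomer_ratios) < 0) ||
      any(solute_coefficients < 0)) {
    stop("composition entries must be non-negative", call. = FALSE)
  }
  if (abs(sum(mass_fractions) - 1) > 0.05) {
    stop("mass fractions sum to ", sum(mass_fractions),
         "; expected 1 within 0.05", call. = FALSE)
  }
  active <- names(mass_fractions)[mass_fractions > 0]
  missing_groups <- setdiff(active, names(monomer_ratios))
  if (length(missing_groups)) {
    stop("no monomer ratios for group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  for (g in names(monomer_ratios)) {
    s <- sum(monomer_ratios[[g]])
    if (abs(s - 1) > 1e-9) {
      stop("monomer ratios for '", g, "' sum to ", s, ", not 1",
           call. = FALSE)
    }
  }
  structure(list(condition = condition, mass_fractions = mass_fractions,
                 monomer_ratios = monomer_ratios,
                 solute_coefficients = solute_coefficients,
                 gam_base = gam_base,
                 polymerization_cost = polymerization_cost, ngam = ngam),
            class = "biomass_composition")
}

#' Assemble a biomass reaction from a composition
#'
#' For each macromolecule group with mass fraction f and monomer molar
#' ratios r_i (monomer weights w_i in g mmol^-1), the group contributes
#' monomer coefficients -(f / sum(r w)) * r_i, so the total mass drained by
#' the group is exactly f grams per gDW. The GAM energy term ATP + H2O ->
#' ADP + Pi + H enters with coefficient equal to
#' `compute_gam(gam_base, polymerization_cost)`, and growth-associated
#' solutes with their condition-specific coefficients. Flux through the
#' resulting reaction has h^-1 units (specific growth rate).
#'
#' @param comp a [biomass_composition()].
#' @param monomer_weights named numeric, g mmol^-1 for every monomer and
#'   solute metabolite id in the composition.
#' @param id reaction id for the biomass reaction.
#' @param energy_metabolites named character vector with entries `atp`,
#'   `h2o`, `adp`, `pi`, `h` giving the metabolite ids of the energy term.
#' @return a one-reaction list with fields `id`, `name`, `stoichiometry`,
#'   `lb`, `ub`, `subsystem`, `gpr`, `kind` suitable for [add_reaction()].
#' @export
assemble_biomass_reaction <- function(comp, monomer_weights, id = "BIO",
                                      energy_metabolites = c(
                                        atp = "atp[c]", h2o = "h2o[c]",
                                        adp = "adp[c]", pi = "pi[c]",
                                        h = "h[c]")) {
  stopifnot(inherits(comp, "biomass_composition"))
  coefs <- numeric(0)
  for (g in names(comp$mass_fractions)) {
    f <- comp$mass_fractions[[g]]
    if (f == 0) next
    r <- comp$monomer_ratios[[g]]
    mons <- names(r)
    missing_w <- setdiff(mons, names(monomer_weights))
    if (length(missing_w)) {
      stop("no molecular weight for monomer(s): ",
           paste(missing_w, collapse = ", "), call. = FALSE)
    }
    w_avg <- sum(r * monomer_weights[mons])
    add <- -(f / w_avg) * r
    coefs <- merge_coefs(coefs, add)
  }
  if (length(comp$solute_coefficients)) {
    missing_w <- setdiff(names(comp$solute_coefficients),
                         names(monomer_weights))
    if (length(missing_w)) {
      stop("no molecular weight for solute(s): ",
           paste(missing_w, collapse = ", "), call. = FALSE)
    }
    coefs <- merge_coefs(coefs, -comp$solute_coefficients)
  }
  gam <- compute_gam(comp$gam_base, comp$polymerization_cost)
  em <- energy_metabolites
  energy <- stats::setNames(c(-gam, -gam, gam, gam, gam),
                            em[c("atp", "h2o", "adp", "pi", "h")])
  coefs <- merge_coefs(coefs, energy)
  list(id = id, name = paste0("Biomass (", comp$condition, " salinity)"),
       stoichiometry = coefs, lb = 0, ub = 1000, subsystem = "Biomass",
       gpr = "", kind = "biomass")
}

merge_coefs <- function(a, b) {
  for (nm in names(b)) a[nm] <- (if (nm %in% names(a)) a[[nm]] else 0) + b[[nm]]
  a[a != 0]
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param rxn a list with fields `id`, `stoichiometry` and optionally
#'   `name`, `lb`, `ub`, `subsystem`, `gpr`, `kind` (as produced by
#'   [assemble_biomass_reaction()]).
#' @param set_objective if `TRUE`, make the new reaction the objective.
#' @return the extended, revalidated model.
#' @export
add_reaction <- function(model, rxn, set_objective = FALSE) {
  row <- data.frame(
    id = rxn$id, name = rxn$name %||% rxn$id, lb = rxn$lb %||% 0,
    ub = rxn$ub %||% 1000, subsystem = rxn$subsystem %||% "",
    gpr = rxn$gpr %||% "", kind = rxn$kind %||% NA_character_,
    stringsAsFactors = FALSE)
  rxns <- model$reactions
  rxns$reversible <- NULL
  rxns <- rbind(rxns[, names(row)], row)
  sto <- c(model$stoichiometry, list(rxn$stoichiometry))
  metabolic_model(model$metabolites, rxns, sto,
                  objective_id = if (set_objective) rxn$id else
                    model$objective_id)
}

#' Built-in template biomass compositions
#'
#' A literature-style template for when organism-specific composition data
#' are unavailable: macromolecule mass fractions typical of an
#' enterobacterial reference composition, uniform amino-acid ratios, and
#' nucleotide ratios derived from a G+C content of 0.647. Every value
#' carries the attribute `template = TRUE` so downstream reports can flag
#' that it is a fallback, not a measurement. The two conditions differ in
#' polymerization cost and in the ectoine/hydroxyectoine demand, the
#' features that actually distinguish the salinities.
#'
#' @param condition `"low"` or `"high"` salinity.
#' @param ectoine_id,hydroxyectoine_id metabolite ids for the osmolyte
#'   terms.
#' @return a [biomass_composition()] with attribute `template = TRUE`.
#' @export
template_biomass <- function(condition = c("low", "high"),
                             ectoine_id = "ect-l[c]",
                             hydroxyectoine_id = "hdect[c]") {
  condition <- match.arg(condition)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aa_ids <- paste0("aa_", aa, "[c]")
  dnt <- dnt_ratios_from_gc(0.647)
  dnt_ids <- paste0(c("dA", "dC", "dG", "dT"), "[c]")
  nt_ids <- paste0(c("rA", "rC", "rG", "rU"), "[c]")
  solutes <- if (condition == "high") {
    stats::setNames(c(0.30, 0.15), c(ectoine_id, hydroxyectoine_id))
  } else {
    stats::setNames(c(0.05, 0.02), c(ectoine_id, hydroxyectoine_id))
  }
  comp <- biomass_composition(
    condition = condition,
    mass_fractions = c(protein = 0.55, rna = 0.20, dna = 0.03,
                       lipid = 0.09, other = 0.13),
    monomer_ratios = list(
      protein = stats::setNames(rep(1 / 20, 20), aa_ids),
      rna = stats::setNames(rep(0.25, 4), nt_ids),
      dna = stats::setNames(as.numeric(dnt), dnt_ids),
      lipid = stats::setNames(1, "lipid[c]"),
      other = stats::setNames(1, "other[c]")),
    solute_coefficients = solutes,
    gam_base = 36.94,
    polymerization_cost = if (condition == "low") 23.04 else 8.79)
  attr(comp, "template") <- TRUE
  comp
}
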