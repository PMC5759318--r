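#' SBML Level 3 read/write (flux-balance subset)
#'
#' Serializes a model as SBML Level 3 Version 1 with the flux-balance
#' constraints (`fbc`) annotations used by constraint-based modeling tools:
#' per-reaction flux bounds as shared parameters, gene products with nested
#' and/or gene associations, and an active maximization objective.
#' Subsystem and reaction kind, which core SBML has no slot for, travel in a
#' `notes` body (`SUBSYSTEM:` / `KIND:` lines), the convention used by the
#' common constraint-based toolkits.
#'
#' Identifiers containing characters outside the SBML id grammar (brackets,
#' dashes) are escaped reversibly (`_0x<hex>_`), so write-then-read restores
#' the original ids exactly.
#'
#' @param model a `metabolic_model`.
#' @param path file path of the SBML document.
#' @return `read_sbml()` a `metabolic_model`; `write_sbml()` `path`,
#'   invisibly.
#' @keywords internal
write_sbml <- function(model, path) {
  ns_sbml <- "http://www.sbml.org/sbml/level3/version1/core"
  ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root(
    "sbml", xmlns = ns_sbml, "xmlns:fbc" = ns_fbc,
    level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = "model",
                             "fbc:strict" = "true")

  cmps <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cmp in sort(unique(model$metabolites$compartment))) {
    xml2::xml_add_child(cmps, "compartment", id = cmp, constant = "true")
  }

  sps <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    met <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      sps, "species", id = sbml_encode(met$id, "M_"), name = met$name,
      compartment = met$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.na(met$charge)) {
      xml2::xml_set_attr(sp, "fbc:charge", as.character(met$charge))
    }
    if (nzchar(met$formula %||% "")) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula)
    }
  }

  # shared bound parameters, one per distinct value
  bkey <- function(x) sprintf("%.17g", x)
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  par_id <- stats::setNames(sprintf("bound_%d", seq_along(bounds)),
                            bkey(bounds))
  pars <- xml2::xml_add_child(mod, "listOfParameters")
  for (k in seq_along(bounds)) {
    xml2::xml_add_child(pars, "parameter", id = par_id[[k]],
                        value = bkey(bounds[k]),
                        constant = "true", "sbo" = "SBO:0000626")
  }

  rxs <- xml2::xml_add_child(mod, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    node <- xml2::xml_add_child(
      rxs, "reaction", id = sbml_encode(rx$id, "R_"), name = rx$name,
      reversible = tolower(as.character(rx$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = par_id[[bkey(rx$lb)]],
      "fbc:upperFluxBound" = par_id[[bkey(rx$ub)]])
    notes <- xml2::xml_add_child(node, "notes")
    body <- xml2::xml_add_child(
      notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", rx$subsystem))
    xml2::xml_add_child(body, "p", paste0("KIND: ", rx$kind))
    coefs <- model$stoichiometry[[i]]
    if (any(coefs < 0)) {
      lhs <- xml2::xml_add_child(node, "listOfReactants")
      for (met in names(coefs)[coefs < 0]) {
        xml2::xml_add_child(lhs, "speciesReference",
                            species = sbml_encode(met, "M_"),
                            stoichiometry = format(-coefs[[met]],
                                                   digits = 17),
                            constant = "true")
      }
    }
    if (any(coefs > 0)) {
      rhs <- xml2::xml_add_child(node, "listOfProducts")
      for (met in names(coefs)[coefs > 0]) {
        xml2::xml_add_child(rhs, "speciesReference",
                            species = sbml_encode(met, "M_"),
                            stoichiometry = format(coefs[[met]],
                                                   digits = 17),
                            constant = "true")
      }
    }
    tree <- parse_gpr(rx$gpr)
    if (!is.null(tree)) {
      assoc <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      sbml_write_gpr(assoc, tree)
    }
  }

  gps <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(gps, "fbc:geneProduct",
                        "fbc:id" = sbml_encode(g, "G_"), "fbc:label" = g)
  }

  objs <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  if (!is.na(model$objective_id)) {
    fl <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(fl, "fbc:fluxObjective",
                        "fbc:reaction" = sbml_encode(model$objective_id,
                                                     "R_"),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpr <- function(parent, tree) {
  if (is.character(tree)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_encode(tree, "G_"))
    return(invisible())
  }
  node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
  for (a in tree$args) sbml_write_gpr(node, a)
  invisible()
}

#' @rdname write_sbml
#' @keywords internal
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse SBML file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML file has no species: ", path,
                              call. = FALSE)
  mets <- data.frame(
    id = sbml_decode(xml2::xml_attr(sp_nodes, "id")),
    name = xml2::xml_attr(sp_nodes, "name"),
    formula = ifelse(is.na(xml2::xml_attr(sp_nodes, "chemicalFormula")),
                     "", xml2::xml_attr(sp_nodes, "chemicalFormula")),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes,
                                                        "charge"))),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  sto <- vector("list", length(rx_nodes))
  rxns <- data.frame(
    id = sbml_decode(xml2::xml_attr(rx_nodes, "id")),
    name = xml2::xml_attr(rx_nodes, "name"),
    lb = unname(par_val[xml2::xml_attr(rx_nodes, "lowerFluxBound")]),
    ub = unname(par_val[xml2::xml_attr(rx_nodes, "upperFluxBound")]),
    subsystem = "", gpr = "", kind = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    notes <- xml2::xml_text(xml2::xml_find_all(node, ".//notes//p"))
    sub <- sub("^SUBSYSTEM:\\s*", "", grep("^SUBSYSTEM:", notes,
                                           value = TRUE))
    knd <- sub("^KIND:\\s*", "", grep("^KIND:", notes, value = TRUE))
    if (length(sub)) rxns$subsystem[i] <- sub[[1]]
    if (length(knd) && nzchar(knd[[1]])) rxns$kind[i] <- knd[[1]]
    reac <- xml2::xml_find_all(node, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(node, "./listOfProducts/speciesReference")
    coefs <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      sbml_decode(xml2::xml_attr(reac, "species"))),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      sbml_decode(xml2::xml_attr(prod, "species"))))
    sto[[i]] <- coefs
    assoc <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']")
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids)) {
        rxns$gpr[i] <- deparse_gpr(sbml_read_gpr(kids[[1]]))
      }
    }
  }

  gene_nodes <- xml2::xml_find_all(doc,
                                   ".//*[local-name()='geneProduct']")
  genes <- if (length(gene_nodes)) {
    labs <- xml2::xml_attr(gene_nodes, "label")
    ids <- sbml_decode(xml2::xml_attr(gene_nodes, "id"))
    sort(unique(ifelse(is.na(labs), ids, labs)))
  } else NULL

  obj_node <- xml2::xml_find_first(doc,
                                   ".//*[local-name()='fluxObjective']")
  objective_id <- if (!inherits(obj_node, "xml_missing")) {
    sbml_decode(xml2::xml_attr(obj_node, "reaction"))
  } else NULL

  metabolic_model(mets, rxns, sto, genes = genes,
                  objective_id = objective_id)
}

sbml_read_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(sbml_decode(xml2::xml_attr(node, "geneProduct")))
  }
  if (!nm %in% c("and", "or")) {
    stop("unsupported gene association element: ", nm, call. = FALSE)
  }
  list(op = nm, args = lapply(xml2::xml_children(node), sbml_read_gpr))
}

# reversible escaping of characters outside the SBML id grammar
sbml_encode <- function(ids, prefix) {
  vapply(ids, function(id) {
    chars <- strsplit(id, "")[[1]]
    ok <- grepl("[A-Za-z0-9_]", chars)
    chars[!ok] <- sprintf("_0x%x_",
                          vapply(chars[!ok], utf8ToInt, integer(1)))
    paste0(prefix, paste(chars, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

sbml_decode <- function(ids) {
  out <- sub("^[MRG]_", "", ids)
  vapply(out, function(id) {
    m <- gregexpr("_0x[0-9a-f]+_", id)[[1]]
    if (m[1] == -1) return(id)
    codes <- regmatches(id, gregexpr("_0x[0-9a-f]+_", id))[[1]]
    for (code in unique(codes)) {
      ch <- intToUtf8(strtoi(sub("^_0x", "", sub("_$", "", code)), 16L))
      id <- gsub(code, ch, id, fixed = TRUE)
    }
    id
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
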