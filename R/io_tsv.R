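#' Read or write a metabolic model
#'
#' Two on-disk dialects are supported. The tabular (`"tsv"`) dialect mirrors
#' the spreadsheet layout in which curated reconstructions are usually
#' distributed: a directory holding `reactions.tsv` (id, name, stoichiometry
#' string such as `"-1 a[c] + 1 b[c]"`, lb, ub, subsystem, gpr, kind,
#' objective flag) and `metabolites.tsv` (id, name, formula, charge,
#' compartment). The `"sbml"` dialect is an SBML Level 3 subset with
#' flux-bound and gene-association annotations (see [write_sbml()]).
#'
#' `write_model()` followed by `read_model()` reproduces the model
#' field-for-field in both dialects.
#'
#' @param path for `"tsv"`, a directory; for `"sbml"`, an `.xml` file path.
#' @param format `"tsv"` or `"sbml"`.
#' @param model a `metabolic_model`.
#' @return `read_model()` returns a validated `metabolic_model`;
#'   `write_model()` returns `path` invisibly.
#' @seealso [metabolic_model()]
#' @export
read_model <- function(path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path,
                               call. = FALSE)
  model <- switch(format,
                  tsv = read_model_tsv(path),
                  sbml = read_sbml(path))
  message(sprintf("read model: %d metabolites, %d reactions, %d genes",
                  nrow(model$metabolites), nrow(model$reactions),
                  length(model$genes)))
  model
}

#' @rdname read_model
#' @export
write_model <- function(model, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format,
         tsv = write_model_tsv(model, path),
         sbml = write_sbml(model, path))
  invisible(path)
}

read_model_tsv <- function(path) {
  rxn_file <- file.path(path, "reactions.tsv")
  met_file <- file.path(path, "metabolites.tsv")
  for (f in c(rxn_file, met_file)) {
    if (!file.exists(f)) stop("missing model table: ", f, call. = FALSE)
  }
  rxns <- utils::read.delim(rxn_file, stringsAsFactors = FALSE,
                            na.strings = character())
  mets <- utils::read.delim(met_file, stringsAsFactors = FALSE,
                            na.strings = character())
  # a fully empty column arrives as logical NA; restore character type
  for (nm in c("name", "subsystem", "gpr", "kind", "stoichiometry")) {
    if (!is.null(rxns[[nm]])) {
      x <- as.character(rxns[[nm]])
      x[is.na(x)] <- ""
      rxns[[nm]] <- x
    }
  }
  for (nm in c("name", "formula", "compartment")) {
    if (!is.null(mets[[nm]])) {
      x <- as.character(mets[[nm]])
      x[is.na(x)] <- ""
      mets[[nm]] <- x
    }
  }
  if (!is.null(rxns$kind)) rxns$kind[!nzchar(rxns$kind)] <- NA_character_
  if (nrow(rxns) == 0L) stop("empty reactions table: ", rxn_file,
                             call. = FALSE)
  needed <- c("id", "stoichiometry", "lb", "ub")
  missing_cols <- setdiff(needed, names(rxns))
  if (length(missing_cols)) {
    stop("reactions.tsv lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sto <- lapply(seq_len(nrow(rxns)), function(i) {
    parse_stoich_string(rxns$stoichiometry[i], context = rxns$id[i])
  })
  objective_id <- NULL
  if (!is.null(rxns$objective)) {
    flagged <- rxns$id[as.logical(rxns$objective) %in% TRUE]
    if (length(flagged)) objective_id <- flagged[[1]]
  }
  rxns$stoichiometry <- NULL
  rxns$objective <- NULL
  if (!is.null(mets$charge)) mets$charge <- suppressWarnings(
    as.integer(mets$charge))
  metabolic_model(mets, rxns, sto, objective_id = objective_id)
}

write_model_tsv <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rxns <- model$reactions
  out <- data.frame(
    id = rxns$id, name = rxns$name,
    stoichiometry = vapply(model$stoichiometry, format_stoich_string,
                           character(1)),
    lb = rxns$lb, ub = rxns$ub, subsystem = rxns$subsystem,
    gpr = rxns$gpr, kind = rxns$kind,
    objective = !is.na(model$objective_id) & rxns$id == model$objective_id,
    stringsAsFactors = FALSE)
  utils::write.table(out, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mets <- model$metabolites[, c("id", "name", "formula", "charge",
                                "compartment")]
  utils::write.table(mets, file.path(path, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# "-1 a[c] + 2 b[c]" -> c("a[c]" = -1, "b[c]" = 2); empty string -> empty
parse_stoich_string <- function(s, context = "") {
  s <- trimws(s)
  if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
  terms <- strsplit(s, "\\s*\\+\\s+")[[1]]
  coefs <- numeric(length(terms))
  ids <- character(length(terms))
  for (k in seq_along(terms)) {
    m <- regmatches(terms[k],
                    regexec("^(-?[0-9.]+(?:[eE][+-]?[0-9]+)?)\\s+(\\S+)$",
                            terms[k]))[[1]]
    if (length(m) != 3L) {
      stop("cannot parse stoichiometry term '", terms[k], "' in reaction ",
           context, call. = FALSE)
    }
    coefs[k] <- as.numeric(m[2])
    ids[k] <- m[3]
  }
  stats::setNames(coefs, ids)
}

format_stoich_string <- function(coefs) {
  if (!length(coefs)) return("")
  paste(paste(format(unname(coefs), scientific = FALSE, trim = TRUE,
                     digits = 15),
              names(coefs)),
        collapse = " + ")
}
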