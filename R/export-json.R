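# Native JSON persistence. Schema:
# {
#   "species": ["A", ...],
#   "rules":   {"A": {"inputs": ["B", ...], "table": [0,1,...]}, ...},
#   "parameters":   {"tau": {"A": 1}, "hill": {"A<-B": {"n": 3, "k": 0.5}}},
#   "compartments": {"compartments": 6, "intercompartment": ["S"],
#                    "include_self": false}
# }
# Tables are flattened in canonical index order (first input
# slowest-varying). "parameters" and "compartments" are optional.

#' Save a Boolean model (and optional parameters) as JSON
#'
#' @param model A [boolean_model].
#' @param path Output file path.
#' @param params Optional `parameter_set`.
#' @param compartments Optional [compartment_spec].
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, params = NULL, compartments = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  doc <- list(species = model$species,
              rules = lapply(model$rules, function(r) {
                list(inputs = r$inputs, table = r$table)
              }))
  if (!is.null(params)) {
    stopifnot(inherits(params, "parameter_set"))
    doc$parameters <- list(
      tau = as.list(params$tau),
      hill = lapply(params$hill, function(p) list(n = p$n, k = p$k)))
  }
  if (!is.null(compartments)) {
    stopifnot(inherits(compartments, "compartment_spec"))
    doc$compartments <- list(compartments = compartments$n_compartments,
                             intercompartment = compartments$intercompartment,
                             include_self = compartments$include_self)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

json_field_error <- function(pointer, msg) {
  stop("model file schema error at ", pointer, ": ", msg, call. = FALSE)
}

#' Load a Boolean model from JSON
#'
#' Validates the document against the native schema and reports the first
#' offending field on failure.
#'
#' @param path Path to a JSON model file written by [save_model].
#' @return A list with elements `model` ([boolean_model]), `params`
#'   (`parameter_set` or NULL) and `compartments` ([compartment_spec] or
#'   NULL).
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$species) || length(doc$species) == 0L) {
    json_field_error("/species", "missing or empty species list")
  }
  species <- vapply(doc$species, function(s) {
    if (!is.character(s)) json_field_error("/species", "species names must be strings")
    s
  }, character(1))

  rules <- list()
  for (target in names(doc$rules)) {
    entry <- doc$rules[[target]]
    ptr <- paste0("/rules/", target)
    if (!target %in% species) json_field_error(ptr, "rule target not in species list")
    inputs <- as.character(unlist(entry$inputs, use.names = FALSE))
    table <- unlist(entry$table, use.names = FALSE)
    if (is.null(table)) json_field_error(paste0(ptr, "/table"), "missing table")
    if (length(table) != 2L^length(inputs)) {
      json_field_error(paste0(ptr, "/table"),
                       sprintf("table has %d entries, expected 2^%d = %d",
                               length(table), length(inputs), 2L^length(inputs)))
    }
    if (!all(table %in% c(0, 1))) {
      json_field_error(paste0(ptr, "/table"), "table entries must be 0 or 1")
    }
    bad <- setdiff(inputs, species)
    if (length(bad)) {
      json_field_error(paste0(ptr, "/inputs"),
                       paste("undeclared species:", paste(bad, collapse = ", ")))
    }
    rules[[target]] <- update_rule(target, inputs, as.integer(table))
  }
  model <- boolean_model(species, rules)

  params <- NULL
  if (!is.null(doc$parameters)) {
    pp <- doc$parameters
    tau <- vapply(pp$tau, function(v) as.numeric(v), numeric(1))
    if (any(!names(tau) %in% species)) {
      json_field_error("/parameters/tau", "tau entry for unknown species")
    }
    hill <- lapply(pp$hill, function(h) {
      if (is.null(h$n) || is.null(h$k)) {
        json_field_error("/parameters/hill", "each entry needs fields n and k")
      }
      hill_parameters(h$n, h$k)
    })
    full_tau <- rep(1, length(species)); names(full_tau) <- species
    full_tau[names(tau)] <- tau
    params <- structure(list(tau = full_tau, hill = hill), class = "parameter_set")
  }

  compartments <- NULL
  if (!is.null(doc$compartments)) {
    cc <- doc$compartments
    if (is.null(cc$compartments)) {
      json_field_error("/compartments/compartments", "missing compartment count")
    }
    compartments <- compartment_spec(
      cc$compartments,
      as.character(unlist(cc$intercompartment, use.names = FALSE)),
      isTRUE(cc$include_self))
    bad <- setdiff(compartments$intercompartment, species)
    if (length(bad)) {
      json_field_error("/compartments/intercompartment",
                       paste("unknown species:", paste(bad, collapse = ", ")))
    }
  }

  list(model = model, params = params, compartments = compartments)
}
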