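# SBML Level 3 Version 2 export. The converted system is a
# phenomenological ODE, not mass-action chemistry, so each species gets a
# rate rule (not reactions) whose MathML encodes
#   (C_i(...) - x_i) / tau_i
# with the cube written as an explicit corner sum over (optionally
# Hill-transformed) inputs, so the exported file is self-contained.

sbml_sanitize_ids <- function(names) {
  ids <- gsub("[^A-Za-z0-9_]", "_", names)
  bad_start <- grepl("^[^A-Za-z_]", ids)
  ids[bad_start] <- paste0("x_", ids[bad_start])
  ids <- make.unique(ids, sep = "_")
  names(ids) <- names
  ids
}

# --- tiny MathML builders (nested xml2-compatible lists) -----------------

mml_ci <- function(id) paste0("<ci> ", id, " </ci>")
mml_cn <- function(value) {
  if (value == as.integer(value)) {
    sprintf('<cn type="integer"> %d </cn>', as.integer(value))
  } else {
    sprintf("<cn> %s </cn>", format(value, digits = 15))
  }
}
mml_apply <- function(op, ...) {
  paste0("<apply> <", op, "/> ", paste(c(...), collapse = " "), " </apply>")
}

# Hill term for one (target, input) interaction as MathML, by method.
#   boolecube:     x
#   hillcube:      x^n / (x^n + k^n)
#   hillcubenorm:  [x^n / (x^n + k^n)] * (1 + k^n)     (= hill(x)/hill(1))
mml_hill_term <- function(x_id, n_id, k_id, method) {
  if (method == "boolecube") return(mml_ci(x_id))
  xn <- mml_apply("power", mml_ci(x_id), mml_ci(n_id))
  kn <- mml_apply("power", mml_ci(k_id), mml_ci(n_id))
  h <- mml_apply("divide", xn, mml_apply("plus", xn, kn))
  if (method == "hillcube") return(h)
  mml_apply("times", h, mml_apply("plus", mml_cn(1), kn))
}

# Corner-sum expansion of one rule's cube as MathML.
mml_cube <- function(rule, hill_terms) {
  d <- rule_indegree(rule)
  if (d == 0L) return(mml_cn(rule$table[[1L]]))
  on <- which(rule$table == 1L)
  if (length(on) == 0L) return(mml_cn(0))
  cm <- corner_matrix(d)
  terms <- vapply(on, function(r) {
    factors <- vapply(seq_len(d), function(j) {
      if (cm[r, j] == 1L) hill_terms[[j]]
      else mml_apply("minus", mml_cn(1), hill_terms[[j]])
    }, character(1))
    if (length(factors) == 1L) factors else do.call(mml_apply, c("times", as.list(factors)))
  }, character(1))
  if (length(terms) == 1L) terms else do.call(mml_apply, c("plus", as.list(terms)))
}

#' Export a converted model as SBML
#'
#' Writes an SBML Level 3 Version 2 document with one species per model
#' species (initial amount 0.5, dimensionless, non-boundary), global
#' constant parameters for every life-time (`tau_<species>`) and every
#' interaction (`n_<target>_<input>`, `k_<target>_<input>`), and one rate
#' rule per species encoding `(C_i(...) - x_i)/tau_i` in fully expanded
#' corner-sum form. Species names that are not valid SBML identifiers are
#' sanitized; the mapping is attached as the `id_map` attribute of the
#' return value.
#'
#' @param model A [boolean_model].
#' @param method Conversion method tag (`"boolecube"`, `"hillcube"`,
#'   `"hillcubenorm"`).
#' @param params A `parameter_set` (completed from defaults if needed).
#' @param path Optional output file; when given, the document is written
#'   there.
#' @return The SBML document as a character string (invisibly if `path`
#'   is given), with attribute `id_map` (named character vector original
#'   name -> SBML id).
#' @export
to_sbml <- function(model, method = c("hillcubenorm", "hillcube", "boolecube"),
                    params = default_parameters(model), path = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  method <- match.arg(method)
  params <- suppressWarnings(complete_parameters(model, params, method))
  ids <- sbml_sanitize_ids(model$species)

  species_xml <- vapply(model$species, function(s) {
    sprintf(paste0('      <species id="%s" name="%s" compartment="default" ',
                   'initialAmount="0.5" hasOnlySubstanceUnits="true" ',
                   'boundaryCondition="false" constant="false"/>'),
            ids[[s]], s)
  }, character(1))

  param_xml <- character(0)
  add_param <- function(id, value) {
    param_xml[[length(param_xml) + 1L]] <<-
      sprintf('      <parameter id="%s" value="%s" constant="true"/>',
              id, format(value, digits = 15))
  }
  for (s in model$species) add_param(paste0("tau_", ids[[s]]), params$tau[[s]])
  if (method != "boolecube") {
    for (s in names(model$rules)) {
      for (i in model$rules[[s]]$inputs) {
        p <- params$hill[[hill_key(s, i)]]
        add_param(sprintf("n_%s_%s", ids[[s]], ids[[i]]), p$n)
        add_param(sprintf("k_%s_%s", ids[[s]], ids[[i]]), p$k)
      }
    }
  }

  rule_xml <- vapply(model$species, function(s) {
    rule <- model$rules[[s]]
    if (is.null(rule)) {
      math <- mml_cn(0)   # constant input: rate 0
    } else {
      hill_terms <- vapply(rule$inputs, function(i) {
        mml_hill_term(ids[[i]],
                      sprintf("n_%s_%s", ids[[s]], ids[[i]]),
                      sprintf("k_%s_%s", ids[[s]], ids[[i]]),
                      method)
      }, character(1))
      cube <- mml_cube(rule, hill_terms)
      math <- mml_apply("divide",
                        mml_apply("minus", cube, mml_ci(ids[[s]])),
                        mml_ci(paste0("tau_", ids[[s]])))
    }
    paste0('      <rateRule variable="', ids[[s]], '">\n',
           '        <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
           '          ', math, '\n',
           '        </math>\n',
           '      </rateRule>')
  }, character(1))

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    sprintf('  <model id="boolcube_%s" name="boolcube export (%s)">\n',
            method, method),
    '    <listOfCompartments>\n',
    '      <compartment id="default" spatialDimensions="3" size="1" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n',
    paste(species_xml, collapse = "\n"), "\n",
    '    </listOfSpecies>\n',
    '    <listOfParameters>\n',
    paste(param_xml, collapse = "\n"), "\n",
    '    </listOfParameters>\n',
    '    <listOfRules>\n',
    paste(rule_xml, collapse = "\n"), "\n",
    '    </listOfRules>\n',
    '  </model>\n',
    '</sbml>\n')

  # well-formedness check (and fail early on broken MathML)
  xml2::read_xml(doc)

  attr(doc, "id_map") <- ids
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
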