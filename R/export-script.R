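# Plain-text ODE script export via pluggable templates. Each dialect
# renders the right-hand sides as human-readable infix expressions with
# every Hill transform bound to a named term once per (target, input)
# interaction. Output is deterministic.

script_sanitize <- function(names) {
  ids <- gsub("[^A-Za-z0-9_]", "_", names)
  bad_start <- grepl("^[^A-Za-z_]", ids)
  ids[bad_start] <- paste0("x_", ids[bad_start])
  ids <- make.unique(ids, sep = "_")
  names(ids) <- names
  ids
}

# infix corner-sum of one rule over precomputed term strings
infix_cube <- function(rule, terms) {
  d <- rule_indegree(rule)
  if (d == 0L) return(as.character(rule$table[[1L]]))
  on <- which(rule$table == 1L)
  if (length(on) == 0L) return("0")
  cm <- corner_matrix(d)
  prods <- vapply(on, function(r) {
    factors <- vapply(seq_len(d), function(j) {
      if (cm[r, j] == 1L) terms[[j]] else paste0("(1 - ", terms[[j]], ")")
    }, character(1))
    paste(factors, collapse = " * ")
  }, character(1))
  paste(prods, collapse = " + ")
}

# shared per-model rendering data
script_pieces <- function(model, method, params) {
  params <- suppressWarnings(complete_parameters(model, params, method))
  ids <- script_sanitize(model$species)
  pars <- list()  # name -> value, in declaration order
  for (s in model$species) pars[[paste0("tau_", ids[[s]])]] <- params$tau[[s]]
  hill_defs <- character(0)   # "h_T_I = <expr>" definitions
  rhs <- character(0)         # per-species RHS referencing h terms
  for (s in model$species) {
    rule <- model$rules[[s]]
    if (is.null(rule)) { rhs[[s]] <- "0"; next }
    terms <- character(0)
    for (i in rule$inputs) {
      if (method == "boolecube") {
        terms[[i]] <- ids[[i]]
      } else {
        p <- params$hill[[hill_key(s, i)]]
        nid <- sprintf("n_%s_%s", ids[[s]], ids[[i]])
        kid <- sprintf("k_%s_%s", ids[[s]], ids[[i]])
        pars[[nid]] <- p$n
        pars[[kid]] <- p$k
        hname <- sprintf("h_%s_%s", ids[[s]], ids[[i]])
        core <- sprintf("%s^%s / (%s^%s + %s^%s)",
                        ids[[i]], nid, ids[[i]], nid, kid, nid)
        expr <- if (method == "hillcubenorm") {
          sprintf("(%s) * (1 + %s^%s)", core, kid, nid)
        } else {
          paste0("(", core, ")")
        }
        hill_defs[[hname]] <- expr
        terms[[i]] <- hname
      }
    }
    rhs[[s]] <- sprintf("(%s - %s) / tau_%s",
                        infix_cube(rule, terms), ids[[s]], ids[[s]])
  }
  list(ids = ids, pars = pars, hill_defs = hill_defs, rhs = rhs)
}

render_r_script <- function(model, method, params) {
  pc <- script_pieces(model, method, params)
  ids <- pc$ids
  lines <- c(
    sprintf("## ODE system generated by boolcube (method: %s)", method),
    sprintf("## species: %s", paste(model$species, collapse = ", ")),
    "",
    "parameters <- c(",
    paste0("  ", names(pc$pars), " = ", vapply(pc$pars, format, character(1), digits = 15),
           c(rep(",", length(pc$pars) - 1L), "")),
    ")",
    "",
    "rhs <- function(t, x, p) {",
    "  with(as.list(c(x, p)), {")
  if (length(pc$hill_defs)) {
    lines <- c(lines, paste0("    ", names(pc$hill_defs), " <- ", pc$hill_defs))
  }
  lines <- c(lines,
    paste0("    d", ids[model$species], " <- ", pc$rhs[model$species]),
    sprintf("    list(c(%s))", paste0("d", ids[model$species], collapse = ", ")),
    "  })",
    "}",
    "",
    sprintf("## example: deSolve::ode(y = c(%s), times = seq(0, 10, 0.1), func = rhs, parms = parameters)",
            paste0(ids[model$species], " = 0.5", collapse = ", ")))
  paste(lines, collapse = "\n")
}

render_matlab_script <- function(model, method, params) {
  pc <- script_pieces(model, method, params)
  ids <- pc$ids
  n <- length(model$species)
  lines <- c(
    "function dx = boolcube_rhs(t, x)",
    sprintf("%% ODE system generated by boolcube (method: %s)", method),
    sprintf("%% species: %s", paste(model$species, collapse = ", ")),
    paste0(names(pc$pars), " = ", vapply(pc$pars, format, character(1), digits = 15), ";"),
    paste0(ids[model$species], " = x(", seq_len(n), ");"))
  if (length(pc$hill_defs)) {
    lines <- c(lines, paste0(names(pc$hill_defs), " = ", pc$hill_defs, ";"))
  }
  lines <- c(lines,
    sprintf("dx = zeros(%d, 1);", n),
    paste0("dx(", seq_len(n), ") = ", pc$rhs[model$species], ";"),
    "end")
  paste(lines, collapse = "\n")
}

script_dialects <- list(r = render_r_script, matlab = render_matlab_script,
                        octave = render_matlab_script)

#' Export a converted model as an ODE script file
#'
#' Renders the continuous system as a self-contained plain-text script in
#' the requested dialect, with all cube expressions expanded to infix
#' corner sums and every Hill transform defined exactly once per
#' (target, input) interaction. Rendering is deterministic: the same
#' model, method and parameters always produce byte-identical output.
#'
#' @param model A [boolean_model].
#' @param method Conversion method tag.
#' @param params A `parameter_set`.
#' @param dialect Template name: `"r"`, `"matlab"` or `"octave"`.
#' @param path Optional output file.
#' @return The script text (invisibly if `path` is given).
#' @export
to_script <- function(model, method = c("hillcubenorm", "hillcube", "boolecube"),
                      params = default_parameters(model),
                      dialect = "r", path = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  method <- match.arg(method)
  dialect <- tolower(dialect)
  render <- script_dialects[[dialect]]
  if (is.null(render)) {
    stop("unknown script dialect '", dialect, "'; registered: ",
         paste(names(script_dialects), collapse = ", "), call. = FALSE)
  }
  text <- render(model, method, params)
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
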