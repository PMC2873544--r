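# Shared fixtures: canonical toggle switches, a mid-hindbrain-boundary
# style multicompartment fixture, random-expression generators and an
# independent MathML reader used to cross-validate the SBML export.

or_switch <- function() parse_boolean_equations("X = X || ~Y\nY = Y || ~X")
and_switch <- function() parse_boolean_equations("X = X && ~Y\nY = Y && ~X")

# Roeder-comparison parameterization: n = 2 everywhere, sensitive
# self-activation (k = 0.01), standard inhibition threshold (k = 0.5).
roeder_parameters <- function(model) {
  p <- default_parameters(model, n = 2)
  p <- set_hill(p, "X", "X", k = 0.01)
  set_hill(p, "Y", "Y", k = 0.01)
}

# Four-factor boundary-maintenance network: mutual inhibition of the two
# transcription factors, mutual (cross-compartment) dependence of the two
# secreted factors, TF gating of secretion. Maintains the six-compartment
# boundary pattern below.
mhb_model <- function() {
  parse_boolean_equations(paste(
    "Otx2 = ~Gbx2",
    "Gbx2 = ~Otx2",
    "Wnt1 = Otx2 && Fgf8",
    "Fgf8 = Gbx2 && Wnt1",
    sep = "\n"))
}

mhb_spec <- function(C = 6L) {
  compartment_spec(C, intercompartment = c("Wnt1", "Fgf8"))
}

# compartments x species (Otx2, Gbx2, Wnt1, Fgf8); boundary between
# compartments 3 and 4: Wnt1 on the anterior side, Fgf8 on the posterior.
mhb_pattern <- function() {
  matrix(c(1, 0, 0, 0,
           1, 0, 0, 0,
           1, 0, 1, 0,
           0, 1, 0, 1,
           0, 1, 0, 0,
           0, 1, 0, 0),
         nrow = 6, byrow = TRUE,
         dimnames = list(NULL, c("Otx2", "Gbx2", "Wnt1", "Fgf8")))
}

# Hand-validated variants of the boundary network (all keep the pattern).
mhb_valid_models <- function() {
  list(
    mhb_model(),
    parse_boolean_equations(paste(        # secreted factors also need their TF off
      "Otx2 = ~Gbx2",
      "Gbx2 = ~Otx2",
      "Wnt1 = Otx2 && Fgf8 && ~Gbx2",
      "Fgf8 = Gbx2 && Wnt1 && ~Otx2",
      sep = "\n")),
    parse_boolean_equations(paste(        # TFs with auto-activation
      "Otx2 = Otx2 && ~Gbx2",
      "Gbx2 = Gbx2 && ~Otx2",
      "Wnt1 = Otx2 && Fgf8",
      "Fgf8 = Gbx2 && Wnt1",
      sep = "\n")))
}

# Uniform random expression tree over the given variables.
random_expression <- function(vars, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.15) return(bool_const(sample(0:1, 1)))
    return(bool_var(sample(vars, 1)))
  }
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") return(bool_not(random_expression(vars, depth - 1L)))
  a <- random_expression(vars, depth - 1L)
  b <- random_expression(vars, depth - 1L)
  if (op == "and") bool_and(a, b) else bool_or(a, b)
}

# Random update rule with in-degree d over generic input names.
random_rule <- function(d, target = "T_") {
  inputs <- if (d > 0L) paste0("V", seq_len(d)) else character(0)
  update_rule(target, inputs, sample(c(0L, 1L), 2L^d, replace = TRUE))
}

# Minimal GraphML writer for import tests (dialect: node attr 'label',
# edge attr 'sign').
write_test_graphml <- function(nodes, edges, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  node_xml <- vapply(seq_along(nodes), function(i) {
    sprintf('    <node id="n%d"><data key="d0">%s</data></node>', i, esc(nodes[[i]]))
  }, character(1))
  edge_xml <- vapply(seq_len(nrow(edges)), function(r) {
    sprintf('    <edge source="n%s" target="n%s"><data key="d1">%s</data></edge>',
            edges[r, 1], edges[r, 2], edges[r, 3])
  }, character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="d1" for="edge" attr.name="sign" attr.type="string"/>',
    '  <graph id="G" edgedefault="directed">',
    node_xml, edge_xml,
    '  </graph>', '</graphml>'), path)
  path
}

# Independent oracle for attractors: follow each state for 2^N steps to
# land inside its terminal cycle, then walk once around the cycle.
attractors_by_iteration <- function(model) {
  n <- length(model$species)
  n_states <- 2L^n
  found <- list()
  for (code in 0:(n_states - 1L)) {
    s <- bitwAnd(bitwShiftR(code, (n - 1L):0L), 1L)
    for (step in seq_len(n_states)) s <- synchronous_update(model, s)
    cyc <- list(s)
    nxt <- synchronous_update(model, s)
    while (!identical(unname(nxt), unname(s))) {
      cyc[[length(cyc) + 1L]] <- nxt
      nxt <- synchronous_update(model, nxt)
    }
    key <- paste(sort(vapply(cyc, paste, character(1), collapse = "")),
                 collapse = ";")
    found[[key]] <- cyc
  }
  found
}

# Independent MathML reader: converts an SBML rate-rule document into a
# derivative function, without touching the package's own evaluators.
sbml_to_derivative_function <- function(sbml_text) {
  doc <- xml2::read_xml(sbml_text)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core",
          m = "http://www.w3.org/1998/Math/MathML")
  pars <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  env_pars <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                              xml2::xml_attr(pars, "id"))
  sp <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:species", ns), "id")

  mathml_to_call <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
    if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
    stopifnot(nm == "apply")
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_call)
    fun <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^",
                  stop("unhandled MathML operator: ", op))
    Reduce(function(a, b) call(fun, a, b), args)
  }

  rules <- xml2::xml_find_all(doc, ".//s:rateRule", ns)
  vars <- xml2::xml_attr(rules, "variable")
  exprs <- lapply(rules, function(r) {
    mathml_to_call(xml2::xml_child(xml2::xml_find_first(r, ".//m:math", ns)))
  })
  names(exprs) <- vars

  function(t, y, parms) {
    e <- as.list(c(y, env_pars))
    d <- vapply(sp, function(v) {
      if (is.null(exprs[[v]])) 0 else eval(exprs[[v]], e)
    }, numeric(1))
    list(unname(d))
  }
}
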