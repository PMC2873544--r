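# GraphML import of regulatory interaction graphs and hypergraphs.
#
# Dialect: every node carries a string attribute `label`; nodes whose
# label is exactly "&" are conjunction hypernodes, all other labels are
# species names. Every edge carries a string attribute `sign`, "+" for
# activation or "-" for inhibition. This replaces editor-specific styling
# with a minimal documented convention.

#' Import a Boolean model from a GraphML interaction graph
#'
#' Reads a directed GraphML graph of activating (`sign = "+"`) and
#' inhibiting (`sign = "-"`) edges and derives one Boolean update rule per
#' regulated species.
#'
#' Two styles can be mixed freely per target species:
#' \itemize{
#'   \item Plain interaction graph: all regulators of a species point at it
#'     directly. The rule is the generic activator/inhibitor logic
#'     ([build_generic_rule]) with `default_ops`; with the default
#'     connectives the species turns on iff at least one activator and no
#'     inhibitor is active. A regulator with both a `+` and a `-` edge
#'     appears in both lists.
#'   \item Hypergraph (sum-of-products): a node labelled `&` collects a
#'     conjunction; every edge path through an `&` node contributes one
#'     conjunctive term in which inhibiting edges negate their source
#'     literal. Direct edges into the species become single-literal terms
#'     (negated if inhibiting), and all terms are joined by OR.
#' }
#' Species with no incoming edges get no rule and act as constant inputs.
#'
#' @param path Path to a GraphML file.
#' @param default_ops [logic_operators] used for plain-graph targets.
#' @return A [boolean_model].
#' @export
import_interaction_graph <- function(path, default_ops = logic_operators()) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  labels <- va$label
  if (is.null(labels)) {
    stop("GraphML import: nodes must carry a string attribute 'label'",
         call. = FALSE)
  }
  signs <- igraph::edge_attr(g, "sign")
  if (is.null(signs) || anyNA(signs) || !all(signs %in% c("+", "-"))) {
    stop("GraphML import: every edge needs attribute 'sign' with value \"+\" or \"-\"",
         call. = FALSE)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  is_hyper <- labels == "&"
  species <- labels[!is_hyper]
  if (anyDuplicated(species)) {
    stop("GraphML import: duplicate species labels", call. = FALSE)
  }

  nv <- length(labels)
  in_edges <- lapply(seq_len(nv), function(v) which(el[, 2L] == v))
  out_edges <- lapply(seq_len(nv), function(v) which(el[, 1L] == v))

  for (v in which(is_hyper)) {
    if (length(in_edges[[v]]) == 0L) {
      stop("GraphML import: '&' node with no incoming edges", call. = FALSE)
    }
    if (length(out_edges[[v]]) == 0L) {
      stop("GraphML import: '&' node with no outgoing edges", call. = FALSE)
    }
  }
  # chains of '&' nodes must be acyclic
  hyper_edges <- el[is_hyper[el[, 1L]] & is_hyper[el[, 2L]], , drop = FALSE]
  if (nrow(hyper_edges) > 0L) {
    hg <- igraph::graph_from_edgelist(matrix(as.character(hyper_edges), ncol = 2L),
                                      directed = TRUE)
    if (!igraph::is_dag(hg)) {
      stop("GraphML import: cyclic chain of '&' nodes", call. = FALSE)
    }
  }

  # Resolve an '&' node to its list of signed literals (name, positive).
  hyper_cache <- vector("list", nv)
  hyper_literals <- function(v) {
    if (!is.null(hyper_cache[[v]])) return(hyper_cache[[v]])
    lits <- list()
    for (e in in_edges[[v]]) {
      src <- el[e, 1L]
      if (is_hyper[src]) {
        if (signs[e] == "-") {
          stop("GraphML import: inhibiting edge between '&' nodes is not a sum-of-products term",
               call. = FALSE)
        }
        lits <- c(lits, hyper_literals(src))
      } else {
        lits <- c(lits, list(list(name = labels[src], positive = signs[e] == "+")))
      }
    }
    hyper_cache[[v]] <<- lits
    lits
  }

  literal_expr <- function(lit) {
    if (lit$positive) bool_var(lit$name) else bool_not(bool_var(lit$name))
  }

  rules <- list()
  for (v in which(!is_hyper)) {
    ie <- in_edges[[v]]
    if (length(ie) == 0L) next
    srcs <- el[ie, 1L]
    if (any(is_hyper[srcs])) {
      # sum-of-products: one conjunctive term per '&' in-edge, one literal
      # term per direct edge
      terms <- list()
      for (e in ie) {
        src <- el[e, 1L]
        if (is_hyper[src]) {
          if (signs[e] == "-") {
            stop("GraphML import: inhibiting edge from an '&' node to '",
                 labels[v], "' cannot be expressed as a product term",
                 call. = FALSE)
          }
          terms <- c(terms, list(fold_expr(lapply(hyper_literals(src), literal_expr), "and")))
        } else {
          terms <- c(terms, list(literal_expr(list(name = labels[src],
                                                   positive = signs[e] == "+"))))
        }
      }
      expr <- fold_expr(terms, "or")
    } else {
      activators <- labels[srcs[signs[ie] == "+"]]
      inhibitors <- labels[srcs[signs[ie] == "-"]]
      expr <- build_generic_rule(activators, inhibitors, default_ops)
    }
    rules[[labels[v]]] <- expression_to_rule(expr, expression_variables(expr),
                                             target = labels[v])
  }
  boolean_model(species, rules)
}
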