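# Boolean model container: species list plus per-species update rules
# stored as truth tables over the rule's inputs ("hypercubes with edge
# length 2"). Table index order is fixed: the first input is the
# slowest-varying coordinate, so for inputs (A, B) the flat table is
# (B(0,0), B(0,1), B(1,0), B(1,1)).

# All 2^d input tuples in canonical order; row r holds the bits of r-1
# with the first input in the leftmost (slowest) position.
corner_matrix <- function(d) {
  if (d == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  idx <- 0:(2L^d - 1L)
  m <- vapply(seq_len(d), function(j) bitwAnd(bitwShiftR(idx, d - j), 1L), integer(2L^d))
  matrix(m, nrow = 2L^d, ncol = d)
}

# Table position (1-based) of an input tuple in canonical order.
corner_index <- function(bits) {
  d <- length(bits)
  if (d == 0L) return(1L)
  as.integer(sum(as.integer(bits) * 2^((d - 1L):0L)) + 1)
}

#' Construct an update rule
#'
#' An update rule gives the next Boolean value of one target species as a
#' truth table over an ordered list of input species. A rule with zero
#' inputs is a constant rule.
#'
#' @param target Name of the regulated species.
#' @param inputs Character vector of distinct input species names (possibly
#'   empty).
#' @param table Integer vector of 0/1 with `2^length(inputs)` entries, in
#'   canonical index order (first input slowest-varying).
#' @return An object of class `update_rule`.
#' @examples
#' update_rule("X", c("X", "Y"), c(1L, 0L, 1L, 1L))  # X || ~Y
#' @export
update_rule <- function(target, inputs, table) {
  stopifnot(is.character(target), length(target) == 1L, nzchar(target))
  inputs <- as.character(inputs)
  if (anyDuplicated(inputs)) {
    stop("duplicate input species in rule for '", target, "'", call. = FALSE)
  }
  table <- as.integer(table)
  if (length(table) != 2L^length(inputs)) {
    stop(sprintf("rule for '%s': table has %d entries, expected 2^%d = %d",
                 target, length(table), length(inputs), 2L^length(inputs)),
         call. = FALSE)
  }
  if (anyNA(table) || !all(table %in% c(0L, 1L))) {
    stop("rule for '", target, "': table entries must be 0 or 1", call. = FALSE)
  }
  structure(list(target = target, inputs = inputs, table = table),
            class = "update_rule")
}

#' @export
print.update_rule <- function(x, ...) {
  cat(x$target, "=", format(rule_to_expression(x)), "\n")
  invisible(x)
}

rule_indegree <- function(rule) length(rule$inputs)

#' Construct a Boolean model
#'
#' A Boolean model is an ordered list of N species together with at most
#' one [update_rule] per species. Species without a rule are constant model
#' inputs: their Boolean value never changes and their continuous
#' derivative is zero.
#'
#' @param species Character vector of distinct species names.
#' @param rules List of [update_rule] objects (at most one per species).
#' @param max_indegree Hard cap on rule in-degree (table size is
#'   `2^indegree`); exceeded in-degrees raise an error.
#' @return An object of class `boolean_model`.
#' @examples
#' boolean_model(c("A", "B"), list(update_rule("B", "A", c(0L, 1L))))
#' @export
boolean_model <- function(species, rules = list(), max_indegree = 16L) {
  species <- as.character(species)
  stopifnot(length(species) >= 1L)
  if (anyDuplicated(species)) stop("duplicate species names", call. = FALSE)
  # names must be usable as tokens downstream: no whitespace, operator
  # characters or comment markers (the equation parser itself only emits
  # identifier-style names; constructed models may be freer, e.g. "2fa")
  bad <- grep("^[^\\s&|!~()=#\"']+$", species, invert = TRUE, value = TRUE, perl = TRUE)
  if (length(bad)) {
    stop("invalid species name(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(rules)) stop("'rules' must be a list of update_rule objects", call. = FALSE)
  out_rules <- list()
  for (r in rules) {
    if (!inherits(r, "update_rule")) stop("all rules must be update_rule objects", call. = FALSE)
    if (!r$target %in% species) {
      stop("rule target '", r$target, "' is not a declared species", call. = FALSE)
    }
    missing_in <- setdiff(r$inputs, species)
    if (length(missing_in)) {
      stop("rule for '", r$target, "' references undeclared species: ",
           paste(sQuote(missing_in), collapse = ", "), call. = FALSE)
    }
    if (rule_indegree(r) > max_indegree) {
      stop(sprintf("rule for '%s' has in-degree %d, exceeding the cap of %d (table size 2^d)",
                   r$target, rule_indegree(r), max_indegree), call. = FALSE)
    }
    if (!is.null(out_rules[[r$target]])) {
      stop("duplicate rule for species '", r$target, "'", call. = FALSE)
    }
    out_rules[[r$target]] <- r
  }
  structure(list(species = species, rules = out_rules), class = "boolean_model")
}

n_species <- function(model) length(model$species)

# Species without an update rule (constant model inputs).
input_species <- function(model) setdiff(model$species, names(model$rules))

#' @export
print.boolean_model <- function(x, ...) {
  cat(sprintf("Boolean model: %d species, %d update rules\n",
              n_species(x), length(x$rules)))
  for (s in x$species) {
    if (is.null(x$rules[[s]])) {
      cat(sprintf("  %s  (input, constant)\n", s))
    } else {
      cat(" ", s, "=", format(rule_to_expression(x$rules[[s]])), "\n")
    }
  }
  invisible(x)
}

#' Tabulate a Boolean expression into an update rule
#'
#' Evaluates `expr` at all `2^d` assignments of `input_order` and stores
#' the results as a truth table.
#'
#' @param expr A `boolean_expression`.
#' @param input_order Character vector containing every variable used in
#'   `expr` exactly once; defines the table's index order.
#' @param target Target species name recorded in the rule.
#' @return An [update_rule].
#' @examples
#' expression_to_rule(parse_boolean_expression("A || B"), c("A", "B"), "C")
#' @export
expression_to_rule <- function(expr, input_order = expression_variables(expr),
                               target = "y") {
  stopifnot(inherits(expr, "boolean_expression"))
  input_order <- as.character(input_order)
  used <- expression_variables(expr)
  if (anyDuplicated(input_order)) stop("duplicate names in input_order", call. = FALSE)
  missing_in <- setdiff(used, input_order)
  if (length(missing_in)) {
    stop("input_order is missing variable(s): ",
         paste(sQuote(missing_in), collapse = ", "), call. = FALSE)
  }
  d <- length(input_order)
  cm <- corner_matrix(d)
  table <- vapply(seq_len(nrow(cm)), function(r) {
    env <- as.integer(cm[r, ])
    names(env) <- input_order
    eval_expression(expr, env)
  }, integer(1))
  update_rule(target, input_order, table)
}

#' Read an update rule back as a sum-of-products expression
#'
#' Returns the disjunction of the minterms at which the table is 1 (the
#' canonical sum-of-products form); a constant rule yields the constant.
#'
#' @param rule An [update_rule].
#' @return A `boolean_expression` that tabulates back to the same table.
#' @export
rule_to_expression <- function(rule) {
  stopifnot(inherits(rule, "update_rule"))
  d <- rule_indegree(rule)
  if (d == 0L) return(bool_const(rule$table[[1L]]))
  on_rows <- which(rule$table == 1L)
  if (length(on_rows) == 0L) return(bool_const(0L))
  if (length(on_rows) == 2L^d) return(bool_const(1L))
  cm <- corner_matrix(d)
  minterms <- lapply(on_rows, function(r) {
    lits <- lapply(seq_len(d), function(j) {
      v <- bool_var(rule$inputs[[j]])
      if (cm[r, j] == 1L) v else bool_not(v)
    })
    fold_expr(lits, "and")
  })
  fold_expr(minterms, "or")
}

#' Serialize a Boolean model as equation text
#'
#' Produces one `Name = expression` line per update rule (sum-of-products
#' form) plus a comment line listing rule-less input species, in a form
#' that [parse_boolean_equations] reads back to identical truth tables.
#'
#' @param model A [boolean_model].
#' @return Character scalar of equation text.
#' @export
model_to_equations <- function(model) {
  stopifnot(inherits(model, "boolean_model"))
  lines <- vapply(names(model$rules), function(s) {
    paste(s, "=", format(rule_to_expression(model$rules[[s]])))
  }, character(1))
  ins <- input_species(model)
  if (length(ins)) {
    lines <- c(lines, paste("# inputs:", paste(ins, collapse = " ")))
  }
  paste(lines, collapse = "\n")
}

#' Generic activator/inhibitor logic
#'
#' The three connectives of the generic update logic used when a rule is
#' derived from a plain interaction graph:
#' `(A_1 ⊖ ... ⊖ A_m) ⊙ ¬(I_1 ⊗ ... ⊗ I_n)`,
#' where ⊖ combines activators, ⊗ combines inhibitors and ⊙ joins the two
#' sides. The defaults (⊖ = OR, ⊙ = AND, ⊗ = OR) encode "on iff at least
#' one activator and no inhibitor is active".
#'
#' @param activators,inhibitors,link Each `"and"` or `"or"`; `link` is the
#'   connective ⊙ between the activator and the negated inhibitor side.
#' @return An object of class `logic_operators`.
#' @export
logic_operators <- function(activators = "or", link = "and", inhibitors = "or") {
  pick <- function(x, what) {
    x <- tolower(x)
    if (!(is.character(x) && length(x) == 1L && x %in% c("and", "or"))) {
      stop("'", what, "' must be \"and\" or \"or\"", call. = FALSE)
    }
    x
  }
  structure(list(activators = pick(activators, "activators"),
                 link = pick(link, "link"),
                 inhibitors = pick(inhibitors, "inhibitors")),
            class = "logic_operators")
}

#' Build a generic activator/inhibitor update expression
#'
#' Combines a set of activators and a set of inhibitors with the three
#' connectives of [logic_operators]. With only activators the result is
#' the ⊖-combination alone; with only inhibitors it is the negated
#' ⊗-combination alone. A species may appear in both lists and is kept in
#' both (no deduplication), so e.g. activators {A, C} and inhibitors
#' {B, C} with the defaults give `(A || C) && ~(B || C)`.
#'
#' @param activators,inhibitors Character vectors of species names; not
#'   both empty.
#' @param ops A [logic_operators] object.
#' @return A `boolean_expression`.
#' @examples
#' format(build_generic_rule(c("A", "C"), c("B", "C")))
#' @export
build_generic_rule <- function(activators = character(0),
                               inhibitors = character(0),
                               ops = logic_operators()) {
  stopifnot(inherits(ops, "logic_operators"))
  activators <- as.character(activators)
  inhibitors <- as.character(inhibitors)
  if (length(activators) == 0L && length(inhibitors) == 0L) {
    stop("at least one activator or inhibitor is required", call. = FALSE)
  }
  act <- if (length(activators)) {
    fold_expr(lapply(activators, bool_var), ops$activators)
  }
  inh <- if (length(inhibitors)) {
    bool_not(fold_expr(lapply(inhibitors, bool_var), ops$inhibitors))
  }
  if (is.null(act)) return(inh)
  if (is.null(inh)) return(act)
  if (ops$link == "and") bool_and(act, inh) else bool_or(act, inh)
}

#' Generate a random Boolean model
#'
#' Draws, for every species, a uniformly random in-degree between 0 and
#' `max_indegree`, a uniform sample of distinct input species, and a
#' uniformly random truth table. Used as the ensemble of arbitrary
#' regulatory networks in model-selection screens.
#'
#' @param n_species Number of species (>= 1).
#' @param max_indegree Maximum rule in-degree (0 gives all-constant rules).
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @param species Optional character vector of species names (default
#'   `X1..Xn`).
#' @return A [boolean_model] in which every species has a rule.
#' @examples
#' random_boolean_model(4, 2, seed = 1)
#' @export
random_boolean_model <- function(n_species, max_indegree, seed = NULL,
                                 species = NULL) {
  n_species <- as.integer(n_species)
  max_indegree <- as.integer(max_indegree)
  if (is.na(n_species) || n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (is.na(max_indegree) || max_indegree < 0L || max_indegree > n_species) {
    stop("max_indegree must be between 0 and n_species", call. = FALSE)
  }
  if (is.null(species)) species <- paste0("X", seq_len(n_species))
  stopifnot(length(species) == n_species)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }

  rules <- lapply(species, function(s) {
    d <- sample.int(max_indegree + 1L, 1L) - 1L
    inputs <- if (d > 0L) sample(species, d) else character(0)
    table <- sample(c(0L, 1L), 2L^d, replace = TRUE)
    update_rule(s, inputs, table)
  })
  boolean_model(species, rules)
}
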