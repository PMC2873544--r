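# Expansion of a single-cell Boolean model into a linear row of C coupled
# compartments. Species flagged as intercompartmental (secreted factors)
# act on the two adjacent compartments: wherever a flagged species appears
# as a rule input, it is replaced by the OR of its copies in the existing
# neighbours (one neighbour at the row ends).

#' Specify a multicompartment expansion
#'
#' @param n_compartments Number of compartments C (>= 1), arranged as a
#'   non-periodic linear row.
#' @param intercompartment Character vector of species to flag as
#'   intercompartmental (secreted) factors.
#' @param include_self Should a secreted factor also act on its own
#'   compartment? Default `FALSE`: influence is exerted on the two
#'   neighbouring cells only.
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(n_compartments, intercompartment = character(0),
                             include_self = FALSE) {
  n_compartments <- as.integer(n_compartments)
  if (is.na(n_compartments) || n_compartments < 1L) {
    stop("n_compartments must be >= 1", call. = FALSE)
  }
  structure(list(n_compartments = n_compartments,
                 intercompartment = as.character(intercompartment),
                 include_self = isTRUE(include_self)),
            class = "compartment_spec")
}

compartment_name <- function(species, c) sprintf("%s_%d", species, c)

#' Expand a Boolean model into coupled compartments
#'
#' Builds the N*C-species model of a linear row of C compartments all
#' driven by the same regulatory network. Copy c of species S is named
#' `S_c` (1-based). In compartment c, every rule input that is a flagged
#' (intercompartmental) species is replaced by the OR of that species'
#' copies in the neighbouring compartments c-1 and c+1 (one neighbour at
#' the row ends; the compartment itself is included only with
#' `include_self = TRUE`); non-flagged inputs map to their same-compartment
#' copy. With C = 1 and no self-inclusion a flagged input has no neighbour
#' and is substituted by constant 0, with a warning.
#'
#' @param model A [boolean_model].
#' @param spec A [compartment_spec].
#' @return The expanded [boolean_model] with `N * C` species, ordered
#'   compartment-major (all species of compartment 1, then compartment 2,
#'   ...).
#' @examples
#' m <- parse_boolean_equations("T_ = S")
#' expand_multicompartment(m, compartment_spec(3, intercompartment = "S"))
#' @export
expand_multicompartment <- function(model, spec) {
  stopifnot(inherits(model, "boolean_model"), inherits(spec, "compartment_spec"))
  C <- spec$n_compartments
  flagged <- spec$intercompartment
  unknown <- setdiff(flagged, model$species)
  if (length(unknown)) {
    stop("intercompartment flag on unknown species: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }

  species_out <- unlist(lapply(seq_len(C), function(c) {
    compartment_name(model$species, c)
  }), use.names = FALSE)

  warned_empty <- FALSE
  rules_out <- list()
  for (c in seq_len(C)) {
    neigh <- c(c - 1L, if (spec$include_self) c, c + 1L)
    neigh <- neigh[neigh >= 1L & neigh <= C]
    for (s in names(model$rules)) {
      rule <- model$rules[[s]]
      d <- rule_indegree(rule)
      # replacement copies for each original input (possibly several, or none)
      repl <- lapply(rule$inputs, function(inp) {
        if (inp %in% flagged) compartment_name(inp, neigh)
        else compartment_name(inp, c)
      })
      if (any(lengths(repl) == 0L) && !warned_empty) {
        warning("intercompartmental input has no neighbouring compartment; ",
                "substituting constant 0", call. = FALSE)
        warned_empty <- TRUE
      }
      new_inputs <- unlist(repl, use.names = FALSE)
      dd <- length(new_inputs)
      cm_new <- corner_matrix(dd)
      # map each assignment of the new inputs to the original input tuple
      offsets <- cumsum(c(0L, lengths(repl)))
      table_new <- vapply(seq_len(nrow(cm_new)), function(r) {
        orig <- vapply(seq_len(d), function(j) {
          lj <- lengths(repl)[[j]]
          if (lj == 0L) return(0L)
          cols <- (offsets[[j]] + 1L):offsets[[j + 1L]]
          as.integer(any(cm_new[r, cols] == 1L))
        }, integer(1))
        rule$table[[corner_index(orig)]]
      }, integer(1))
      rules_out[[length(rules_out) + 1L]] <-
        update_rule(compartment_name(s, c), new_inputs, table_new)
    }
  }
  boolean_model(species_out, rules_out)
}
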