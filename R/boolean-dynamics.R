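# Synchronous Boolean dynamics: exhaustive state enumeration, steady
# states, state-transition graph and attractors.
#
# A state is a 0/1 vector ordered as model$species; internally states are
# encoded as integers 0..2^N-1 with species 1 as the most significant bit,
# so ascending codes are lexicographic state order.

state_to_code <- function(state) {
  n <- length(state)
  sum(as.integer(state) * 2L^((n - 1L):0L))
}

code_to_state <- function(code, n) {
  bitwAnd(bitwShiftR(code, (n - 1L):0L), 1L)
}

check_enumeration_limit <- function(model, limit) {
  n <- n_species(model)
  if (n > limit) {
    stop(sprintf("model has %d species; exhaustive enumeration is limited to %d (2^N states)",
                 n, limit), call. = FALSE)
  }
  n
}

# Successor code for every state 0..2^N-1 under the synchronous update.
successor_codes <- function(model) {
  n <- n_species(model)
  codes <- 0:(2L^n - 1L)
  succ <- integer(2L^n)
  for (i in seq_len(n)) {
    s <- model$species[[i]]
    rule <- model$rules[[s]]
    if (is.null(rule)) {
      nxt <- bitwAnd(bitwShiftR(codes, n - i), 1L)  # inputs keep their value
    } else {
      d <- rule_indegree(rule)
      if (d == 0L) {
        nxt <- rep.int(rule$table[[1L]], length(codes))
      } else {
        pos <- match(rule$inputs, model$species)
        idx <- integer(length(codes))
        for (j in seq_len(d)) {
          idx <- idx + bitwAnd(bitwShiftR(codes, n - pos[[j]]), 1L) * 2L^(d - j)
        }
        nxt <- rule$table[idx + 1L]
      }
    }
    succ <- succ + nxt * 2L^(n - i)
  }
  as.integer(succ)
}

#' Synchronous update of a Boolean state
#'
#' Applies every species' update rule simultaneously: each next value is
#' the rule's truth table evaluated on the current values of its inputs.
#' Species without a rule keep their value.
#'
#' @param model A [boolean_model].
#' @param state 0/1 vector of length N, ordered as `model$species`.
#' @return The successor state (integer 0/1 vector, named by species).
#' @examples
#' m <- parse_boolean_equations("X = X || ~Y\nY = Y || ~X")
#' synchronous_update(m, c(0, 0))
#' @export
synchronous_update <- function(model, state) {
  stopifnot(inherits(model, "boolean_model"))
  n <- n_species(model)
  if (length(state) != n) {
    stop(sprintf("state has length %d, expected %d", length(state), n), call. = FALSE)
  }
  state <- as.integer(state)
  if (anyNA(state) || !all(state %in% c(0L, 1L))) {
    stop("state entries must be 0 or 1", call. = FALSE)
  }
  names(state) <- model$species
  out <- state
  for (s in names(model$rules)) {
    rule <- model$rules[[s]]
    out[[s]] <- rule$table[[corner_index(state[rule$inputs])]]
  }
  out
}

codes_to_state_matrix <- function(codes, model) {
  n <- n_species(model)
  m <- matrix(0L, nrow = length(codes), ncol = n,
              dimnames = list(NULL, model$species))
  for (r in seq_along(codes)) m[r, ] <- code_to_state(codes[[r]], n)
  m
}

#' Enumerate Boolean steady states
#'
#' Finds all states that map to themselves under the synchronous update,
#' by exhaustive enumeration of the 2^N state space.
#'
#' @param model A [boolean_model].
#' @param limit Maximum N for exhaustive enumeration.
#' @return Integer 0/1 matrix, one steady state per row (lexicographic
#'   order), columns named by species.
#' @examples
#' boolean_steady_states(parse_boolean_equations("X = X || ~Y\nY = Y || ~X"))
#' @export
boolean_steady_states <- function(model, limit = 22L) {
  stopifnot(inherits(model, "boolean_model"))
  check_enumeration_limit(model, limit)
  succ <- successor_codes(model)
  fixed <- which(succ == seq_along(succ) - 1L) - 1L
  codes_to_state_matrix(fixed, model)
}

#' State-transition graph of the synchronous dynamics
#'
#' Builds the directed graph on all 2^N states with one edge from each
#' state to its synchronous successor (out-degree exactly 1; steady states
#' are self-loops).
#'
#' @param model A [boolean_model].
#' @param limit Maximum N for exhaustive enumeration.
#' @return An object of class `state_transition_graph` with elements
#'   `species`, `states` (2^N x N matrix) and `successor` (row index of
#'   each state's successor).
#' @export
state_transition_graph <- function(model, limit = 22L) {
  stopifnot(inherits(model, "boolean_model"))
  check_enumeration_limit(model, limit)
  succ <- successor_codes(model)
  structure(list(species = model$species,
                 states = codes_to_state_matrix(seq_along(succ) - 1L, model),
                 successor = succ + 1L),
            class = "state_transition_graph")
}

#' @export
print.state_transition_graph <- function(x, ...) {
  cat(sprintf("State-transition graph: %d states, %d species, %d fixed point(s)\n",
              nrow(x$states), length(x$species),
              sum(x$successor == seq_along(x$successor))))
  invisible(x)
}

#' Convert a state-transition graph to igraph
#'
#' @param stg A `state_transition_graph`.
#' @return An [igraph][igraph::graph_from_edgelist] graph whose vertex
#'   names are the concatenated 0/1 state strings.
#' @export
stg_as_igraph <- function(stg) {
  stopifnot(inherits(stg, "state_transition_graph"))
  lab <- apply(stg$states, 1L, paste0, collapse = "")
  g <- igraph::graph_from_edgelist(cbind(lab, lab[stg$successor]), directed = TRUE)
  igraph::set_graph_attr(g, "species", paste(stg$species, collapse = ","))
}

#' Write a state-transition graph as GraphML
#'
#' @param stg A `state_transition_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
stg_to_graphml <- function(stg, path) {
  igraph::write_graph(stg_as_igraph(stg), path, format = "graphml")
  invisible(path)
}

#' Attractors of the synchronous dynamics
#'
#' Finds every terminal cycle of the state-transition graph (fixed points
#' are length-1 cycles). Since the synchronous update is deterministic,
#' every state reaches exactly one attractor.
#'
#' @param model A [boolean_model].
#' @param limit Maximum N for exhaustive enumeration.
#' @return Object of class `attractor_set`: a list with `attractors` (list
#'   of 0/1 matrices, one cycle state per row in cycle order, starting at
#'   the lexicographically smallest state) and `basin` (integer vector over
#'   all 2^N states giving the attractor index each state reaches).
#'   Attractors are ordered by their smallest state.
#' @examples
#' synchronous_attractors(parse_boolean_equations("X = ~X"))
#' @export
synchronous_attractors <- function(model, limit = 22L) {
  stopifnot(inherits(model, "boolean_model"))
  check_enumeration_limit(model, limit)
  succ <- successor_codes(model) + 1L  # 1-based
  n_states <- length(succ)
  attractor_of <- integer(n_states)    # 0 = unknown
  cycles <- list()

  for (s0 in seq_len(n_states)) {
    if (attractor_of[[s0]] != 0L) next
    path <- integer(0)
    on_path <- integer(0)
    s <- s0
    while (attractor_of[[s]] == 0L && !(s %in% on_path)) {
      path[[length(path) + 1L]] <- s
      on_path <- path
      s <- succ[[s]]
    }
    if (attractor_of[[s]] != 0L) {
      aid <- attractor_of[[s]]
    } else {
      # new cycle: s is the first repeated state on the path
      start <- match(s, path)
      cyc <- path[start:length(path)]
      rot <- which.min(cyc)
      cyc <- c(cyc[rot:length(cyc)], if (rot > 1L) cyc[1:(rot - 1L)])
      cycles[[length(cycles) + 1L]] <- cyc
      aid <- length(cycles)
    }
    attractor_of[path] <- aid
  }

  ord <- order(vapply(cycles, function(c) c[[1L]], integer(1)))
  cycles <- cycles[ord]
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  attractor_of <- remap[attractor_of]

  attractors <- lapply(cycles, function(cyc) {
    codes_to_state_matrix(cyc - 1L, model)
  })
  structure(list(attractors = attractors, basin = attractor_of,
                 species = model$species),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  lens <- vapply(x$attractors, nrow, integer(1))
  cat(sprintf("%d attractor(s): %d fixed point(s), %d cycle(s)\n",
              length(lens), sum(lens == 1L), sum(lens > 1L)))
  for (i in seq_along(x$attractors)) {
    cat(sprintf("  [%d] length %d, basin size %d\n", i, lens[[i]],
                sum(x$basin == i)))
  }
  invisible(x)
}

#' Write Boolean states to CSV
#'
#' One state per row, header row of species names.
#'
#' @param states 0/1 matrix with columns named by species (as returned by
#'   [boolean_steady_states]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
states_to_csv <- function(states, path) {
  utils::write.csv(as.data.frame(states), path, row.names = FALSE)
  invisible(path)
}
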