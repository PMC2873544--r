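# Assembly of the continuous system
#   dx_i/dt = (Bbar_i(x_inputs) - x_i) / tau_i
# where Bbar_i is the BooleCube / HillCube / normalized HillCube of rule i
# and tau_i is the life-time (first-order decay time-scale) of species i.

hill_key <- function(target, input) paste0(target, "<-", input)

#' Default dynamical parameters for a converted model
#'
#' Boolean models are parameter-free; the converted ODE needs one
#' (n, k) pair per interaction and one life-time tau per species. This
#' returns the standard defaults n = 3, k = 0.5, tau = 1 for every
#' interaction and species, which give switch-like but smooth kinetics on
#' the natural \[0,1\] scale.
#'
#' @param model A [boolean_model].
#' @param n,k,tau Values applied uniformly.
#' @return An object of class `parameter_set` with elements `tau` (named
#'   numeric per species) and `hill` (named list of [hill_parameters],
#'   keyed `"target<-input"`).
#' @examples
#' default_parameters(parse_boolean_equations("X = X || ~Y\nY = Y || ~X"))
#' @export
default_parameters <- function(model, n = 3, k = 0.5, tau = 1) {
  stopifnot(inherits(model, "boolean_model"))
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  tau_vec <- rep(as.numeric(tau), n_species(model))
  names(tau_vec) <- model$species
  hill_list <- list()
  for (s in names(model$rules)) {
    for (i in model$rules[[s]]$inputs) {
      hill_list[[hill_key(s, i)]] <- hill_parameters(n, k)
    }
  }
  structure(list(tau = tau_vec, hill = hill_list), class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("Parameter set: %d life-times, %d interactions\n",
              length(x$tau), length(x$hill)))
  invisible(x)
}

#' Override parameters of individual interactions or species
#'
#' `set_hill` replaces the (n, k) pair of the interaction `target <- input`;
#' `set_tau` replaces the life-time of one or more species. All other
#' entries are left untouched.
#'
#' @param params A `parameter_set`.
#' @param target,input Species names identifying the interaction.
#' @param n,k New Hill parameters (either may be omitted to keep the
#'   current value).
#' @param species Species name(s) for `set_tau`.
#' @param tau New life-time (> 0).
#' @return The modified `parameter_set`.
#' @export
set_hill <- function(params, target, input, n = NULL, k = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  key <- hill_key(target, input)
  cur <- params$hill[[key]]
  if (is.null(cur)) {
    stop("no interaction '", key, "' in this parameter set", call. = FALSE)
  }
  params$hill[[key]] <- hill_parameters(if (is.null(n)) cur$n else n,
                                        if (is.null(k)) cur$k else k)
  params
}

#' @rdname set_hill
#' @export
set_tau <- function(params, species, tau) {
  stopifnot(inherits(params, "parameter_set"))
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  missing_sp <- setdiff(species, names(params$tau))
  if (length(missing_sp)) {
    stop("unknown species: ", paste(sQuote(missing_sp), collapse = ", "),
         call. = FALSE)
  }
  params$tau[species] <- as.numeric(tau)
  params
}

# Fill missing tau / hill entries with defaults (warn once per call).
complete_parameters <- function(model, params, method) {
  defaults <- default_parameters(model)
  filled <- character(0)
  for (s in model$species) {
    if (is.null(params$tau[s]) || is.na(params$tau[s])) {
      params$tau[s] <- defaults$tau[s]
      filled <- c(filled, paste0("tau:", s))
    }
  }
  if (method != "boolecube") {
    for (key in names(defaults$hill)) {
      if (is.null(params$hill[[key]])) {
        params$hill[[key]] <- defaults$hill[[key]]
        filled <- c(filled, key)
      }
    }
  }
  if (length(filled)) {
    warning("missing parameters filled with defaults (n=3, k=0.5, tau=1): ",
            paste(filled, collapse = ", "), call. = FALSE)
  }
  params
}

#' Build the continuous vector field of a Boolean model
#'
#' Assembles the autonomous ODE system
#' `dx_i/dt = (C_i(x_inputs) - x_i) / tau_i`, where `C_i` is the
#' BooleCube, HillCube or normalized HillCube of species i's update rule.
#' Species without a rule are constant model inputs: their derivative is
#' pinned to 0 unless `decay_inputs = TRUE`, in which case they decay as
#' `-x_i/tau_i`.
#'
#' @param model A [boolean_model].
#' @param method Conversion method: `"hillcubenorm"` (default),
#'   `"hillcube"` or `"boolecube"`.
#' @param params A `parameter_set`; missing entries are completed from the
#'   defaults with a warning.
#' @param decay_inputs Should rule-less species decay to 0 instead of
#'   staying constant?
#' @param .identity_hill Internal consistency hook: replace every Hill
#'   transform by the identity map (the Hill-based methods then coincide
#'   with the plain BooleCube field). Testing only.
#' @return An object of class `vector_field`: a list with `species`,
#'   `method`, `tau`, and functions `f(x)` (derivative vector) and
#'   `activation(x)` (the C_i values).
#' @examples
#' m <- parse_boolean_equations("X = X || ~Y\nY = Y || ~X")
#' vf <- build_vector_field(m, "hillcubenorm")
#' vf$f(c(0.2, 0.8))
#' @export
build_vector_field <- function(model,
                               method = c("hillcubenorm", "hillcube", "boolecube"),
                               params = default_parameters(model),
                               decay_inputs = FALSE,
                               .identity_hill = FALSE) {
  stopifnot(inherits(model, "boolean_model"), inherits(params, "parameter_set"))
  method <- match.arg(method)
  params <- complete_parameters(model, params, method)
  n <- n_species(model)
  species <- model$species
  tau <- params$tau[species]

  # Precompute per-species evaluation data.
  comp <- vector("list", n)
  for (i in seq_len(n)) {
    s <- species[[i]]
    rule <- model$rules[[s]]
    if (is.null(rule)) { comp[[i]] <- list(kind = "input"); next }
    d <- rule_indegree(rule)
    entry <- list(kind = "rule",
                  idx = match(rule$inputs, species),
                  table = rule$table,
                  cm = corner_matrix(d))
    if (method != "boolecube" && d > 0L) {
      ps <- lapply(rule$inputs, function(inp) params$hill[[hill_key(s, inp)]])
      entry$n <- vapply(ps, `[[`, numeric(1), "n")
      entry$k <- vapply(ps, `[[`, numeric(1), "k")
      entry$norm <- if (method == "hillcubenorm") {
        1 / (1 / (1 + entry$k^entry$n))   # 1 / hill(1) = 1 + k^n
      } else {
        rep(1, d)
      }
    }
    comp[[i]] <- entry
  }

  activation <- function(x) {
    act <- numeric(n)
    for (i in seq_len(n)) {
      e <- comp[[i]]
      if (e$kind == "input") { act[[i]] <- x[[i]]; next }
      u <- x[e$idx]
      if (method != "boolecube" && length(u) > 0L && !.identity_hill) {
        un <- u^e$n
        u <- un / (un + e$k^e$n) * e$norm
      }
      act[[i]] <- corner_sum(e$table, e$cm, u)
    }
    names(act) <- species
    act
  }

  has_rule <- vapply(comp, function(e) e$kind == "rule", logical(1))
  f <- function(x) {
    act <- activation(x)
    deriv <- (act - x) / tau
    if (!decay_inputs) {
      deriv[!has_rule] <- 0
    } else {
      deriv[!has_rule] <- -x[!has_rule] / tau[!has_rule]
    }
    names(deriv) <- species
    deriv
  }

  structure(list(species = species, method = method, tau = tau,
                 f = f, activation = activation, has_rule = has_rule,
                 model = model, params = params,
                 decay_inputs = decay_inputs),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("Vector field (%s): %d species, %d dynamic, %d constant input(s)\n",
              x$method, length(x$species), sum(x$has_rule), sum(!x$has_rule)))
  invisible(x)
}

#' Numerical Jacobian of a vector field
#'
#' Central-difference Jacobian of `vf$f` at `x`, used for local stability
#' classification of equilibria.
#'
#' @param vf A `vector_field`.
#' @param x State vector.
#' @param h Step size.
#' @return N x N Jacobian matrix.
#' @export
vector_field_jacobian <- function(vf, x, h = 1e-6) {
  stopifnot(inherits(vf, "vector_field"))
  n <- length(vf$species)
  J <- matrix(0, n, n, dimnames = list(vf$species, vf$species))
  for (j in seq_len(n)) {
    hi <- min(x[[j]] + h, 1)
    lo <- max(x[[j]] - h, 0)
    xp <- x; xp[[j]] <- hi
    xm <- x; xm[[j]] <- lo
    J[, j] <- (vf$f(xp) - vf$f(xm)) / (hi - lo)
  }
  J
}
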