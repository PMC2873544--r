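# Continuous homologues of Boolean update functions.
#
# boolecube:           multilinear interpolation of the truth table over
#                      the unit hypercube, exact at all corners.
# hillcube:            the interpolation evaluated on Hill-transformed
#                      inputs (switch-like, but hill(1) < 1 so corners are
#                      only approached).
# normalized_hillcube: Hill terms rescaled by their value at 1, restoring
#                      exact corner agreement with the Boolean function.

#' Hill function parameters
#'
#' @param n Hill coefficient (cooperativity of the interaction, slope of
#'   the sigmoid); dimensionless, >= 1.
#' @param k Activation threshold in (0,1); the input level at which
#'   activation is half-maximal. Corresponds to the on/off threshold of
#'   the Boolean abstraction.
#' @return An object of class `hill_parameters`.
#' @export
hill_parameters <- function(n = 3, k = 0.5) {
  n <- as.numeric(n); k <- as.numeric(k)
  stopifnot(length(n) == 1L, length(k) == 1L)
  if (is.na(n) || n < 1) stop("Hill coefficient n must be >= 1", call. = FALSE)
  if (is.na(k) || k <= 0 || k >= 1) stop("threshold k must lie in (0,1)", call. = FALSE)
  structure(list(n = n, k = k), class = "hill_parameters")
}

#' Sigmoidal Hill activation
#'
#' `hill(x) = x^n / (x^n + k^n)`, the classic sigmoid of gene-regulatory
#' kinetics; `hill(k) = 0.5` exactly and `hill(0) = 0`. Note
#' `hill(1) = 1/(1+k^n) < 1`: the function approaches 1 only
#' asymptotically.
#'
#' @param x Input level(s) in \[0,1\] (vectorized).
#' @param p [hill_parameters], or `n`/`k` given directly.
#' @param n,k Alternative to `p`.
#' @return Activation value(s) in \[0,1).
#' @examples
#' hill(0.5, n = 2, k = 0.5)  # 0.5: half-maximal at x = k
#' @export
hill <- function(x, p = NULL, n = NULL, k = NULL) {
  if (!is.null(p)) {
    stopifnot(inherits(p, "hill_parameters"))
    n <- p$n; k <- p$k
  } else {
    p <- hill_parameters(n, k)
    n <- p$n; k <- p$k
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("hill input must lie in [0,1]", call. = FALSE)
  }
  xn <- x^n
  xn / (xn + k^n)
}

check_xbar <- function(rule, xbar) {
  d <- rule_indegree(rule)
  if (length(xbar) != d) {
    stop(sprintf("rule for '%s' has %d inputs but %d values were supplied",
                 rule$target, d, length(xbar)), call. = FALSE)
  }
  if (anyNA(xbar) || any(xbar < 0) || any(xbar > 1)) {
    stop("state values must lie in [0,1]", call. = FALSE)
  }
  invisible(xbar)
}

# Core corner sum: table and corner matrix are precomputable, u in [0,1]^d.
corner_sum <- function(table, cm, u) {
  if (ncol(cm) == 0L) return(as.numeric(table[[1L]]))
  on <- which(table == 1L)
  if (length(on) == 0L) return(0)
  # weight of corner c: prod_j (c_j u_j + (1-c_j)(1-u_j))
  acc <- 0
  for (r in on) {
    c <- cm[r, ]
    acc <- acc + prod(ifelse(c == 1L, u, 1 - u))
  }
  acc
}

#' Multilinear interpolation of a Boolean update function (BooleCube)
#'
#' Evaluates the unique multilinear polynomial agreeing with the rule's
#' truth table at every corner of the unit hypercube:
#' `sum over corners c of B(c) * prod_j (c_j x_j + (1-c_j)(1-x_j))`.
#'
#' @param rule An [update_rule].
#' @param xbar Numeric vector in \[0,1\]^d, ordered as `rule$inputs`.
#' @return Activation value in \[0,1\].
#' @examples
#' or_rule <- expression_to_rule(parse_boolean_expression("A || B"), c("A", "B"))
#' boolecube(or_rule, c(0.5, 0.5))  # 0.75
#' @export
boolecube <- function(rule, xbar = numeric(0)) {
  stopifnot(inherits(rule, "update_rule"))
  check_xbar(rule, xbar)
  corner_sum(rule$table, corner_matrix(rule_indegree(rule)), as.numeric(xbar))
}

#' Attach Hill parameters to an update rule
#'
#' Bundles an [update_rule] with one [hill_parameters] per input and a
#' conversion method tag, ready for evaluation with [hillcube] or
#' [normalized_hillcube].
#'
#' @param rule An [update_rule].
#' @param params List of [hill_parameters], one per rule input (recycled
#'   if a single set is given). Ignored for method `"boolecube"`.
#' @param method One of `"boolecube"`, `"hillcube"`, `"hillcubenorm"`.
#' @return An object of class `continuous_rule`.
#' @export
continuous_rule <- function(rule, params = hill_parameters(),
                            method = c("hillcubenorm", "hillcube", "boolecube")) {
  stopifnot(inherits(rule, "update_rule"))
  method <- match.arg(method)
  d <- rule_indegree(rule)
  if (inherits(params, "hill_parameters")) params <- rep(list(params), d)
  if (method != "boolecube") {
    if (length(params) != d) {
      stop(sprintf("need %d Hill parameter sets for rule '%s', got %d",
                   d, rule$target, length(params)), call. = FALSE)
    }
    for (p in params) stopifnot(inherits(p, "hill_parameters"))
  }
  structure(list(rule = rule, params = params, method = method),
            class = "continuous_rule")
}

#' HillCube: interpolation composed with Hill kinetics
#'
#' Evaluates the BooleCube of the rule on Hill-transformed inputs,
#' `boolecube(rule, (f_1(x_1), ..., f_d(x_d)))` with
#' `f_j(x) = x^n_j / (x^n_j + k_j^n_j)`. Because `f_j(1) < 1`, the result
#' only approaches the Boolean values at the corners.
#'
#' @param crule A [continuous_rule] with method `"hillcube"`.
#' @param xbar Numeric vector in \[0,1\]^d.
#' @return Activation value in \[0,1).
#' @export
hillcube <- function(crule, xbar = numeric(0)) {
  stopifnot(inherits(crule, "continuous_rule"))
  if (crule$method != "hillcube") {
    stop("continuous_rule method is '", crule$method, "', expected 'hillcube'",
         call. = FALSE)
  }
  check_xbar(crule$rule, xbar)
  u <- vapply(seq_along(xbar), function(j) hill(xbar[[j]], crule$params[[j]]),
              numeric(1))
  corner_sum(crule$rule$table, corner_matrix(length(u)), u)
}

#' Normalized HillCube: a perfect continuous homologue
#'
#' As [hillcube], but each Hill term is divided by its value at 1
#' (`f_j(x)/f_j(1)`), so the result agrees exactly with the Boolean
#' function at every corner of the hypercube.
#'
#' @param crule A [continuous_rule] with method `"hillcubenorm"`.
#' @param xbar Numeric vector in \[0,1\]^d.
#' @return Activation value in \[0,1\].
#' @export
normalized_hillcube <- function(crule, xbar = numeric(0)) {
  stopifnot(inherits(crule, "continuous_rule"))
  if (crule$method != "hillcubenorm") {
    stop("continuous_rule method is '", crule$method, "', expected 'hillcubenorm'",
         call. = FALSE)
  }
  check_xbar(crule$rule, xbar)
  u <- vapply(seq_along(xbar), function(j) {
    p <- crule$params[[j]]
    hill(xbar[[j]], p) / hill(1, p)
  }, numeric(1))
  corner_sum(crule$rule$table, corner_matrix(length(u)), u)
}
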