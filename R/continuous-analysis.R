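# Numerical integration of the converted ODE systems, stable steady-state
# discovery with basin labelling, activity patterns and the ensemble
# pattern-maintenance predicate used for model selection.

#' Integrate a vector field
#'
#' Solves the autonomous system with an adaptive-step solver
#' (deSolve::ode, default `lsoda`) and returns the trajectory sampled on a
#' time grid that includes t = 0 and t = t_end.
#'
#' @param vf A `vector_field` from [build_vector_field].
#' @param x0 Initial state in \[0,1\]^N.
#' @param t_end End time (> 0), in units of the life-times tau.
#' @param times Optional explicit output grid (must start at 0); default
#'   201 equispaced points.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method.
#' @return An object of class `trajectory`: list with `time` (vector) and
#'   `states` (time x species matrix).
#' @examples
#' m <- parse_boolean_equations("X = 1")
#' vf <- build_vector_field(m, "boolecube")
#' tr <- integrate_field(vf, 0, t_end = 1)
#' tail(tr$states, 1)  # 1 - exp(-1) = 0.632...
#' @export
integrate_field <- function(vf, x0, t_end, times = NULL,
                            rtol = 1e-6, atol = 1e-8, method = "lsoda") {
  stopifnot(inherits(vf, "vector_field"))
  n <- length(vf$species)
  x0 <- as.numeric(x0)
  if (length(x0) != n) {
    stop(sprintf("x0 has length %d, expected %d", length(x0), n), call. = FALSE)
  }
  if (anyNA(x0) || any(x0 < 0) || any(x0 > 1)) {
    stop("x0 must lie in [0,1]^N", call. = FALSE)
  }
  if (is.null(times)) {
    if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
    times <- seq(0, t_end, length.out = 201L)
  }
  names(x0) <- vf$species
  sol <- try(deSolve::ode(y = x0, times = times,
                          func = function(t, y, parms) list(vf$f(y)),
                          rtol = rtol, atol = atol, method = method),
             silent = TRUE)
  if (inherits(sol, "try-error") || anyNA(sol)) {
    stop("ODE solver failed (method ", method, ", t_end ", max(times), "): ",
         if (inherits(sol, "try-error")) attr(sol, "condition")$message
         else "NA values in solution",
         call. = FALSE)
  }
  states <- unname(sol[, -1L, drop = FALSE])
  colnames(states) <- vf$species
  structure(list(time = sol[, 1L], states = states),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d time points on [%g, %g], %d species\n",
              length(x$time), min(x$time), max(x$time), ncol(x$states)))
  invisible(x)
}

#' Uniform phase-space grid of initial conditions
#'
#' @param n_points Grid points per axis (default 11: steps of 0.1).
#' @param dim State-space dimension.
#' @return Matrix of `n_points^dim` initial conditions (rows).
#' @export
phase_grid <- function(n_points = 11L, dim = 2L) {
  axes <- rep(list(seq(0, 1, length.out = n_points)), dim)
  as.matrix(do.call(expand.grid, axes))
}

#' Discover stable steady states from a set of initial conditions
#'
#' Integrates each initial condition to `t_end`; endpoints whose
#' derivative infinity-norm is below `deriv_tol` count as converged and
#' are pooled by single-linkage clustering in the L-infinity metric at
#' `cluster_tol`. Cluster means are the representative steady states. Each
#' representative is classified as stable or unstable from the eigenvalues
#' of the numerical Jacobian: trajectories started exactly on a basin
#' boundary (e.g. the symmetry axis of a toggle switch) converge to saddle
#' points, which are equilibria but not stable states.
#'
#' @param vf A `vector_field`.
#' @param initials Matrix of initial conditions (one per row), e.g. from
#'   [phase_grid].
#' @param t_end Integration horizon.
#' @param cluster_tol L-infinity single-linkage merge tolerance.
#' @param deriv_tol Convergence criterion on the derivative norm.
#' @param stability_tol Eigenvalue tolerance: a representative is stable
#'   iff every Jacobian eigenvalue has real part <= `stability_tol`
#'   (neutral directions count as stable).
#' @param rtol,atol Solver tolerances; tighter than the [integrate_field]
#'   defaults so that the endpoint residual stays well below `deriv_tol`.
#' @return Object of class `stable_state_set`: `representatives` (matrix),
#'   `stable` (logical per representative), `labels` (per initial
#'   condition: representative index, or NA if not converged),
#'   `converged` (logical), plus the tolerances used.
#' @examples
#' m <- parse_boolean_equations("X = X || ~Y\nY = Y || ~X")
#' vf <- build_vector_field(m, "hillcubenorm")
#' find_stable_states(vf, phase_grid(5))
#' @export
find_stable_states <- function(vf, initials, t_end = 50,
                               cluster_tol = 1e-2, deriv_tol = 1e-6,
                               stability_tol = 1e-6,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(vf, "vector_field"))
  initials <- as.matrix(initials)
  if (nrow(initials) == 0L) stop("no initial conditions supplied", call. = FALSE)
  n <- length(vf$species)
  stopifnot(ncol(initials) == n)

  endpoints <- matrix(NA_real_, nrow(initials), n)
  converged <- logical(nrow(initials))
  for (r in seq_len(nrow(initials))) {
    tr <- integrate_field(vf, initials[r, ], t_end, times = c(0, t_end),
                          rtol = rtol, atol = atol)
    xe <- tr$states[nrow(tr$states), ]
    xe <- pmin(pmax(xe, 0), 1)          # clip solver jitter at the boundary
    endpoints[r, ] <- xe
    converged[[r]] <- max(abs(vf$f(xe))) < deriv_tol
  }

  labels <- rep(NA_integer_, nrow(initials))
  conv_idx <- which(converged)
  if (length(conv_idx) == 0L) {
    return(structure(list(representatives = matrix(numeric(0), 0L, n,
                                                   dimnames = list(NULL, vf$species)),
                          stable = logical(0), labels = labels,
                          converged = converged, endpoints = endpoints,
                          cluster_tol = cluster_tol, deriv_tol = deriv_tol),
                     class = "stable_state_set"))
  }

  pts <- endpoints[conv_idx, , drop = FALSE]
  if (nrow(pts) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(pts, method = "maximum"), method = "single")
    cl <- stats::cutree(hc, h = cluster_tol)
  }
  k <- max(cl)
  reps <- matrix(0, k, n, dimnames = list(NULL, vf$species))
  for (g in seq_len(k)) {
    reps[g, ] <- colMeans(pts[cl == g, , drop = FALSE])
  }
  # order representatives lexicographically for deterministic output
  ord <- do.call(order, as.data.frame(reps))
  reps <- reps[ord, , drop = FALSE]
  remap <- integer(k); remap[ord] <- seq_len(k)
  labels[conv_idx] <- remap[cl]

  stable <- vapply(seq_len(k), function(g) {
    ev <- eigen(vector_field_jacobian(vf, reps[g, ]), only.values = TRUE)$values
    max(Re(ev)) <= stability_tol
  }, logical(1))

  structure(list(representatives = reps, stable = stable, labels = labels,
                 converged = converged, endpoints = endpoints,
                 cluster_tol = cluster_tol, deriv_tol = deriv_tol),
            class = "stable_state_set")
}

#' @export
print.stable_state_set <- function(x, ...) {
  cat(sprintf("Stable-state analysis: %d initial conditions, %d equilibria (%d stable)\n",
              length(x$labels), nrow(x$representatives), sum(x$stable)))
  if (nrow(x$representatives)) {
    tagged <- cbind(round(x$representatives, 4),
                    stable = as.integer(x$stable),
                    basin_size = as.vector(table(factor(x$labels,
                                                        levels = seq_len(nrow(x$representatives))))))
    print(tagged)
  }
  if (any(!x$converged)) {
    cat(sprintf("  %d initial condition(s) did not converge\n", sum(!x$converged)))
  }
  invisible(x)
}

#' Stable representatives of a stable-state set
#'
#' @param sss A `stable_state_set`.
#' @return Matrix of the representatives classified as stable.
#' @export
stable_states <- function(sss) {
  stopifnot(inherits(sss, "stable_state_set"))
  sss$representatives[sss$stable, , drop = FALSE]
}

#' Threshold a continuous state into Boolean activity
#'
#' A species counts as active iff its level strictly exceeds its
#' threshold (the Hill threshold k of the conversion).
#'
#' @param state Numeric state vector.
#' @param threshold Scalar threshold in (0,1), or one per species.
#' @return Integer 0/1 vector.
#' @examples
#' activity_pattern(c(0.9, 0.1), 0.5)
#' @export
activity_pattern <- function(state, threshold = 0.5) {
  if (any(threshold <= 0) || any(threshold >= 1)) {
    stop("threshold must lie in (0,1)", call. = FALSE)
  }
  if (!(length(threshold) %in% c(1L, length(state)))) {
    stop("threshold must be scalar or one per species", call. = FALSE)
  }
  out <- as.integer(state > threshold)
  names(out) <- names(state)
  out
}

#' Per-species activity thresholds from a parameter set
#'
#' The threshold of a species is the mean Hill k over its incoming
#' interactions; species without incoming interactions fall back to
#' `default_k`. With all k equal this reproduces the single global
#' threshold.
#'
#' @param model A [boolean_model].
#' @param params A `parameter_set`.
#' @param default_k Fallback threshold.
#' @return Named numeric vector of thresholds per species.
#' @export
species_thresholds <- function(model, params, default_k = 0.5) {
  stopifnot(inherits(model, "boolean_model"), inherits(params, "parameter_set"))
  out <- vapply(model$species, function(s) {
    rule <- model$rules[[s]]
    if (is.null(rule) || rule_indegree(rule) == 0L) return(default_k)
    ks <- vapply(rule$inputs, function(i) params$hill[[hill_key(s, i)]]$k,
                 numeric(1))
    mean(ks)
  }, numeric(1))
  names(out) <- model$species
  out
}

#' Does a converted model maintain a Boolean activity pattern?
#'
#' Embeds the target on/off pattern as a continuous state (on = 1,
#' off = 0), integrates the converted system to `t_end`, and checks
#' whether the thresholded activity of every species still matches the
#' pattern. This is the validity predicate of the ensemble
#' model-selection screen: a candidate regulatory network is kept iff the
#' known expression pattern is a maintained state of its continuous
#' dynamics.
#'
#' @param model A [boolean_model] (possibly multicompartment-expanded).
#' @param pattern 0/1 vector over `model$species`, or a compartments x
#'   species matrix for an expanded model (row c = compartment c, columns
#'   in single-cell species order).
#' @param method Conversion method tag.
#' @param params A `parameter_set` (defaults used if omitted).
#' @param t_end Integration horizon (in units of tau); long enough for
#'   the system to settle.
#' @param threshold Activity threshold(s), as in [activity_pattern].
#' @return `TRUE` iff the pattern is maintained.
#' @export
pattern_is_maintained <- function(model, pattern,
                                  method = c("hillcubenorm", "hillcube", "boolecube"),
                                  params = default_parameters(model),
                                  t_end = 20, threshold = 0.5) {
  stopifnot(inherits(model, "boolean_model"))
  method <- match.arg(method)
  if (is.matrix(pattern)) pattern <- as.vector(t(pattern))  # compartment-major
  pattern <- as.integer(pattern)
  n <- n_species(model)
  if (length(pattern) != n) {
    stop(sprintf("pattern has %d entries, model has %d species",
                 length(pattern), n), call. = FALSE)
  }
  if (anyNA(pattern) || !all(pattern %in% c(0L, 1L))) {
    stop("pattern entries must be 0 or 1", call. = FALSE)
  }
  vf <- build_vector_field(model, method, params)
  tr <- integrate_field(vf, as.numeric(pattern), t_end, times = c(0, t_end))
  xe <- pmin(pmax(tr$states[nrow(tr$states), ], 0), 1)
  all(activity_pattern(xe, threshold) == pattern)
}

#' Screen an ensemble of candidate models for pattern maintenance
#'
#' Applies [pattern_is_maintained] to each candidate model, optionally
#' expanding each to a multicompartment system first.
#'
#' @param models List of [boolean_model] objects.
#' @param pattern Target pattern (vector, or compartments x species
#'   matrix when `spec` is given).
#' @param spec Optional [compartment_spec] applied to every candidate
#'   before conversion.
#' @param ... Passed to [pattern_is_maintained].
#' @return Logical vector, one verdict per candidate.
#' @export
screen_models <- function(models, pattern, spec = NULL, ...) {
  vapply(models, function(m) {
    if (!is.null(spec)) m <- expand_multicompartment(m, spec)
    pattern_is_maintained(m, pattern, ...)
  }, logical(1))
}

#' Write a trajectory to CSV
#'
#' @param trajectory A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
trajectory_to_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(time = trajectory$time, trajectory$states,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a stable-state analysis to CSV
#'
#' Two tables are written: `<path>` with the representatives (state
#' coordinates, stability flag, basin size) and, if `basins_path` is
#' given, one row per initial condition with its basin label.
#'
#' @param sss A `stable_state_set`.
#' @param path Output file for the representatives.
#' @param initials Matrix of initial conditions (for the basin table).
#' @param basins_path Optional output file for basin labels.
#' @return `path`, invisibly.
#' @export
stable_states_to_csv <- function(sss, path, initials = NULL, basins_path = NULL) {
  stopifnot(inherits(sss, "stable_state_set"))
  reps <- as.data.frame(sss$representatives)
  reps$stable <- sss$stable
  reps$basin_size <- as.vector(table(factor(sss$labels,
                                            levels = seq_len(nrow(sss$representatives)))))
  utils::write.csv(reps, path, row.names = FALSE)
  if (!is.null(basins_path)) {
    if (is.null(initials)) stop("initials required for the basin table", call. = FALSE)
    df <- as.data.frame(initials)
    names(df) <- paste0("x0_", colnames(sss$representatives))
    df$basin <- sss$labels
    df$converged <- sss$converged
    utils::write.csv(df, basins_path, row.names = FALSE)
  }
  invisible(path)
}
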