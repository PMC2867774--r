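# Independent reference solvers over the full reachable space, and
# distribution comparison metrics.

#' Reference transient solution over the full reachable space
#'
#' Solves the master equation globally (no windows) by one of three routes:
#' uniformization at tolerance `eps`, the dense matrix exponential (memory
#' guarded to 4000 states), or the Krylov-subspace propagator. Intended as
#' the validation reference for [sw_solve()]; only applicable when the
#' reachable space is finite and below `cap`.
#'
#' @param network a `cme_network`.
#' @param t time at which the distribution is required.
#' @param init initial condition (`cme_dist`, state vector, or `NULL` for
#'   the network's initial state).
#' @param eps solver tolerance.
#' @param method `"uniformization"`, `"dense_exp"` or `"krylov"`.
#' @param space optional precomputed `state_set` (e.g. a truncation of an
#'   infinite space); defaults to the reachable space.
#' @param cap reachability cap.
#' @return a `cme_dist` over the space.
#' @export
global_solve <- function(network, t, init = NULL, eps = 1e-8,
                         method = c("uniformization", "dense_exp", "krylov"),
                         space = NULL, cap = 5e6) {
  method <- match.arg(method)
  stopifnot(t >= 0)
  if (is.null(space)) space <- reachable_states(network, cap = cap)
  p <- if (is.null(init)) point_mass(network$init)
       else if (inherits(init, "cme_dist")) init
       else point_mass(init)
  p0 <- numeric(space$N)
  idx <- state_index(space, p$states)
  if (anyNA(idx)) stop("initial distribution has support outside the state space")
  p0[idx] <- p$p
  if (t == 0) return(cme_dist(space$states, p0))
  Q <- build_generator(space, network)
  pt <- switch(method,
    uniformization = uniformize(Q, p0, t, eps = eps),
    dense_exp = {
      if (space$N > 4000)
        stop("dense exponential reference is limited to 4000 states")
      as.numeric(small_matrix_exp(as.matrix(Matrix::t(Q)) * t) %*% p0)
    },
    krylov = pmax(krylov_expv(Matrix::t(Q), p0, t, tol = eps), 0))
  cme_dist(space$states, pmax(pt, 0))
}

#' Compare two distributions
#'
#' Total variation distance over the union of supports, and the maximal
#' relative error over states whose reference probability exceeds `floor`.
#'
#' @param reference,candidate `cme_dist` objects.
#' @param floor relative errors are evaluated only where the reference
#'   probability exceeds this level (default `1e-5`).
#' @return object of class `cme_comparison` with fields `total_variation`,
#'   `max_relative_error`, `states_compared`, `floor`.
#' @export
compare_dist <- function(reference, candidate, floor = 1e-5) {
  keys <- union(reference$keys, candidate$keys)
  r <- numeric(length(keys)); names(r) <- keys
  r[reference$keys] <- reference$p
  cc <- numeric(length(keys)); names(cc) <- keys
  cc[candidate$keys] <- candidate$p
  tv <- 0.5 * sum(abs(r - cc))
  sig <- r > floor
  mre <- if (any(sig)) max(abs(r[sig] - cc[sig]) / r[sig]) else 0
  structure(list(total_variation = tv, max_relative_error = mre,
                 states_compared = sum(sig), floor = floor),
            class = "cme_comparison")
}

#' @export
print.cme_comparison <- function(x, ...) {
  cat(sprintf("<comparison: total variation %.3g; max relative error %.3g over %d states with reference > %g>\n",
              x$total_variation, x$max_relative_error, x$states_compared, x$floor))
  invisible(x)
}
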