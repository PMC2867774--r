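# Window construction: worst-case continuous deterministic branch iterations
# that predict per-species population bounds, and the adaptive time-step rule
# built on top of them.

BRANCH_MODES <- c("MORE", "FEWER", "AVG")

#' Branch specification for the window iteration
#'
#' A branch fixes, for every reaction, whether the deterministic bound
#' iteration assumes more firings than on average (`"MORE"`), fewer
#' (`"FEWER"`), or exactly the average (`"AVG"`). One branch drives one
#' worst-case trajectory; the window bounds are the envelope over all
#' branches.
#'
#' @param modes character vector over `MORE`/`FEWER`/`AVG`, one per reaction.
#' @param label descriptive label, e.g. `"max ES"`.
#' @export
branch_spec <- function(modes, label = "") {
  modes <- toupper(as.character(modes))
  if (!all(modes %in% BRANCH_MODES))
    stop("branch modes must be MORE, FEWER or AVG")
  structure(list(modes = modes, label = label), class = "branch_spec")
}

#' @export
print.branch_spec <- function(x, ...) {
  cat(sprintf("<branch %s: %s>\n", x$label, paste(x$modes, collapse = " ")))
  invisible(x)
}

#' Assumed reaction count for one bound-iteration step
#'
#' Given the expected number of firings \eqn{\alpha\Delta} of a reaction in a
#' short interval, returns the count the branch assumes: the Poisson mean
#' plus one standard deviation for `MORE`
#' (\eqn{\alpha\Delta + \sqrt{\alpha\Delta}}), minus one for `FEWER`
#' (clamped at 0), or the mean itself for `AVG`. For a mean of 1 the
#' one-standard-deviation interval [0, 2] carries 91.97 percent of the
#' Poisson mass.
#'
#' @param expected non-negative expected count(s) \eqn{\alpha\Delta}.
#' @param mode `"MORE"`, `"FEWER"` or `"AVG"`.
#' @return non-negative real count(s).
#' @export
kappa_count <- function(expected, mode = c("MORE", "FEWER", "AVG")) {
  mode <- match.arg(mode)
  s <- sqrt(expected)
  switch(mode,
         MORE = expected + s,
         FEWER = pmax(expected - s, 0),
         AVG = expected)
}

# fraction of Poisson(e) mass inside [e - sqrt(e), e + sqrt(e)]
interval_coverage <- function(e) {
  lo <- ceiling(pmax(e - sqrt(e), 0)) - 1
  hi <- floor(e + sqrt(e))
  stats::ppois(hi, e) - stats::ppois(lo, e)
}

# one vectorised iteration step for T trajectories:
# X (T x n), per-row step length d (length T or 1), logical masks (T x k)
branch_step <- function(network, X, more, fewer, d) {
  A <- propensities(network, X)
  if (!is.matrix(A)) A <- matrix(A, nrow = nrow(X))
  E <- A * d
  S <- sqrt(E)
  K <- E + more * S - fewer * S
  K[K < 0] <- 0
  V <- do.call(rbind, lapply(network$reactions, `[[`, "change"))
  X <- X + K %*% V
  X[X < 0] <- 0
  X
}

# per-trajectory step length under a Delta policy, given propensity rows
policy_delta <- function(A, policy) {
  if (is.numeric(policy)) return(rep_len(policy, nrow(A)))
  lam <- rowSums(A)
  d <- ifelse(lam > 0, 1 / lam, Inf)
  if (identical(policy, "coverage")) {
    for (i in seq_len(nrow(A))) {
      if (!is.finite(d[i])) next
      act <- A[i, ] > 0
      for (rep_ in 1:60) {
        if (min(interval_coverage(A[i, act] * d[i])) >= 0.8) break
        d[i] <- d[i] / 2
      }
    }
  }
  d
}

#' Worst-case deterministic update of a state
#'
#' One step of the continuous deterministic bound iteration: each reaction
#' fires [kappa_count()] times according to the branch's mode, and the state
#' moves by the weighted sum of change vectors (negative components are
#' clamped at 0). States are real-valued throughout the iteration.
#'
#' @param network a `cme_network`.
#' @param x current (real-valued) state.
#' @param delta step length.
#' @param branch a [branch_spec()].
#' @return the updated state.
#' @export
step_deterministic <- function(network, x, delta, branch) {
  stopifnot(delta > 0, all(x >= 0))
  X <- matrix(as.numeric(x), nrow = 1L)
  drop(branch_step(network, X,
                   more = matrix(branch$modes == "MORE", 1L),
                   fewer = matrix(branch$modes == "FEWER", 1L),
                   d = delta))
}

#' Default branch set of a network
#'
#' If the network carries a curated branch list (as the packaged enzyme and
#' gene-expression models do), that list is returned. Otherwise branches are
#' derived by a sign rule: for each species dimension `d`, the maximising
#' branch assumes `MORE` firings of every reaction that increases `d`,
#' `FEWER` of every reaction that decreases it, and `AVG` otherwise; the
#' minimising branch is the reverse. Duplicate mode vectors are removed.
#' The sign rule cannot discover indirect effects (a reaction that consumes
#' a species may still be needed to produce it downstream); curated lists
#' are the mechanism for those cases.
#'
#' @param network a `cme_network`.
#' @return list of [branch_spec()] objects.
#' @export
default_branches <- function(network) {
  if (!is.null(network$branches)) brs <- network$branches
  else {
    V <- do.call(rbind, lapply(network$reactions, `[[`, "change"))
    brs <- list()
    for (d in seq_len(network$n)) {
      up <- ifelse(V[, d] > 0, "MORE", ifelse(V[, d] < 0, "FEWER", "AVG"))
      dn <- ifelse(V[, d] > 0, "FEWER", ifelse(V[, d] < 0, "MORE", "AVG"))
      brs <- c(brs, list(branch_spec(up, paste("max", network$species[d])),
                         branch_spec(dn, paste("min", network$species[d]))))
    }
  }
  sig <- vapply(brs, function(b) paste(b$modes, collapse = "|"), character(1))
  brs[!duplicated(sig)]
}

new_bounds <- function(n) list(lower = rep(Inf, n), upper = rep(-Inf, n), elapsed = 0)

merge_bounds <- function(b, X) {
  b$lower <- pmin(b$lower, apply(X, 2, min))
  b$upper <- pmax(b$upper, apply(X, 2, max))
  b
}

finalize_bounds <- function(b) {
  b$lower <- pmax(floor(b$lower), 0)
  b$upper <- pmax(ceiling(b$upper), 0)
  b
}

#' Population bounds from the branch iterations
#'
#' Runs every branch from the start state `z` for `tau` time units and
#' returns the per-dimension envelope (running minima and maxima over all
#' branches and all intermediate states, including `z`), rounded outward to
#' integers and merged with `prior` bounds if given.
#'
#' @param network a `cme_network`.
#' @param z start state.
#' @param tau length of the look-ahead interval.
#' @param branches list of [branch_spec()]; defaults to
#'   [default_branches()].
#' @param prior optional bounds (list with `lower`, `upper`) to widen.
#' @param delta step-length policy: `"exit"` (the default) takes
#'   \eqn{\Delta = 1/\lambda_x} at the branch's current state, so each step
#'   carries one expected transition; `"coverage"` shrinks \eqn{\Delta} until
#'   every reaction's one-standard-deviation interval covers at least 80
#'   percent of its Poisson mass; a number fixes \eqn{\Delta}.
#' @return a bounds pair: list with integer `lower`, `upper` and `elapsed`.
#' @export
cont_det_approx <- function(network, z, tau, branches = default_branches(network),
                            prior = NULL, delta = "exit") {
  stopifnot(tau > 0, all(z >= 0))
  nb <- length(branches)
  X <- matrix(as.numeric(z), nb, network$n, byrow = TRUE)
  modes <- do.call(rbind, lapply(branches, `[[`, "modes"))
  more <- modes == "MORE"; fewer <- modes == "FEWER"
  b <- new_bounds(network$n)
  b <- merge_bounds(b, X)
  time <- numeric(nb)
  active <- rep(TRUE, nb)
  while (any(active)) {
    A <- propensities(network, X[active, , drop = FALSE])
    if (!is.matrix(A)) A <- matrix(A, nrow = sum(active))
    d <- policy_delta(A, delta)
    d <- pmin(d, tau - time[active])       # last step is the remainder
    halt <- !is.finite(d)                  # absorbing state: nothing moves
    if (any(!halt)) {
      sub <- which(active)[!halt]
      X[sub, ] <- branch_step(network, X[sub, , drop = FALSE],
                              more[sub, , drop = FALSE], fewer[sub, , drop = FALSE],
                              d[!halt])
      time[sub] <- time[sub] + d[!halt]
      b <- merge_bounds(b, X[sub, , drop = FALSE])
    }
    active[which(active)[halt]] <- FALSE
    active <- active & time < tau * (1 - 1e-12)
  }
  b$elapsed <- tau
  b <- finalize_bounds(b)
  if (!is.null(prior)) {
    b$lower <- pmin(b$lower, prior$lower)
    b$upper <- pmax(b$upper, prior$upper)
  }
  b
}

#' Look-ahead with an adaptively chosen time step
#'
#' Advances the branch iterations from all seed states in lockstep,
#' extending the elapsed time until the predicted window (the bounds box
#' intersected with the conservation laws) holds at least
#' `max(min_window, 2 * n_significant)` states, or the remaining horizon is
#' exhausted. The doubling condition ensures the window is just big enough
#' for the probability mass to move beyond the currently significant states;
#' the floor keeps very small windows from forcing many tiny steps.
#'
#' @param network a `cme_network`.
#' @param seed_states matrix of start states (rows), typically a random
#'   sample of the significant set.
#' @param branches list of [branch_spec()].
#' @param min_window minimum window size (default 500 states).
#' @param horizon cap on the returned time step (remaining time to the final
#'   output instant).
#' @param n_significant size of the full significant set (condition 2).
#' @param laws conservation laws used in the window-size estimate.
#' @param delta step-length policy, as in [cont_det_approx()].
#' @return list with `tau` (chosen step length) and integer bounds
#'   `lower`, `upper`.
#' @export
adaptive_horizon <- function(network, seed_states, branches = default_branches(network),
                             min_window = 500, horizon = Inf,
                             n_significant = nrow(seed_states),
                             laws = list(), delta = "exit") {
  seed_states <- as.matrix(seed_states)
  stopifnot(nrow(seed_states) > 0)
  target <- max(min_window, 2 * n_significant)
  nb <- length(branches); ns <- nrow(seed_states)
  X <- seed_states[rep(seq_len(ns), each = nb), , drop = FALSE]
  modes <- do.call(rbind, lapply(branches, `[[`, "modes"))[rep(seq_len(nb), ns), , drop = FALSE]
  more <- modes == "MORE"; fewer <- modes == "FEWER"
  b <- new_bounds(network$n)
  b <- merge_bounds(b, seed_states)
  elapsed <- 0
  # compiled fast path for pure mass-action kinetics under the default policy
  fast <- identical(delta, "exit") &&
    all(vapply(network$reactions, function(r) is.null(r$propensity), logical(1)))
  if (fast) {
    V <- do.call(rbind, lapply(network$reactions, `[[`, "change"))
    Lm <- do.call(rbind, lapply(network$reactions, function(r) as.integer(r$reactants)))
    rates <- vapply(network$reactions, `[[`, numeric(1), "rate")
  }
  # the size condition is checked in geometrically growing chunks of rounds,
  # so the per-round cost stays flat while the check stays cheap
  rounds <- 4L
  repeat {
    if (elapsed >= horizon) break
    if (fast) {
      res <- branch_rounds_ma(X, more, fewer, V, rates, Lm,
                              horizon - elapsed, rounds)
      if (res$all_absorbing && res$elapsed == 0) { elapsed <- horizon; break }
      X <- res$X
      b$lower <- pmin(b$lower, res$lower)
      b$upper <- pmax(b$upper, res$upper)
      elapsed <- elapsed + res$elapsed
      stalled <- res$all_absorbing
    } else {
      stalled <- FALSE
      for (rr in seq_len(rounds)) {
        A <- propensities(network, X)
        if (!is.matrix(A)) A <- matrix(A, nrow = nrow(X))
        d <- min(policy_delta(A, delta))
        if (!is.finite(d)) { stalled <- TRUE; break }
        d <- min(d, horizon - elapsed)
        X <- branch_step(network, X, more, fewer, d)
        b <- merge_bounds(b, X)
        elapsed <- elapsed + d
        if (elapsed >= horizon) break
      }
      if (stalled && elapsed == 0) { elapsed <- horizon; break }
    }
    fb <- finalize_bounds(b)
    if (window_size_estimate(fb$lower, fb$upper, laws) >= target) break
    if (stalled) { elapsed <- horizon; break }
    rounds <- min(rounds * 2L, 256L)
  }
  fb <- finalize_bounds(b)
  list(tau = min(elapsed, horizon), lower = fb$lower, upper = fb$upper)
}
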