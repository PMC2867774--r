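# Finite state sets (reachable spaces, windows) and sparse window-restricted
# generator matrices.

# canonical string key of each state row; used for hashing/joining state sets
state_key <- function(X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  do.call(paste, c(lapply(seq_len(ncol(X)), function(j) X[, j]), sep = ","))
}

lex_order <- function(X) do.call(order, lapply(seq_len(ncol(X)), function(j) X[, j]))

new_state_set <- function(states, class = "state_set", extra = list()) {
  if (nrow(states) > 0) {
    states <- states[lex_order(states), , drop = FALSE]
    storage.mode(states) <- "double"
  }
  obj <- c(list(states = states, keys = state_key(states), N = nrow(states)), extra)
  structure(obj, class = class)
}

#' @export
print.state_set <- function(x, ...) {
  cat(sprintf("<state set: %d states in %d dimensions>\n", x$N, ncol(x$states)))
  invisible(x)
}

#' Position of states in a state set
#'
#' @param set a `state_set` or `cme_window`.
#' @param states matrix of query states (rows).
#' @return integer positions (NA where absent).
#' @export
state_index <- function(set, states) match(state_key(states), set$keys)

#' Reachable state space of a network
#'
#' Breadth-first closure of the start state under all reactions with positive
#' propensity. Aborts when more than `cap` states are discovered, which is
#' the expected outcome for networks with an infinite reachable space.
#'
#' @param network a `cme_network`.
#' @param start start state (defaults to the network's initial state).
#' @param cap abort threshold on the number of states.
#' @return a `state_set` with states in lexicographic order.
#' @export
reachable_states <- function(network, start = network$init, cap = 5e6) {
  stopifnot(cap > 0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  frontier <- matrix(as.numeric(start), nrow = 1L)
  assign(state_key(frontier), TRUE, envir = seen)
  chunks <- list(frontier)
  total <- 1L
  while (nrow(frontier) > 0L) {
    succ <- vector("list", network$k)
    for (m in seq_len(network$k)) {
      r <- network$reactions[[m]]
      a <- eval_propensity(r, frontier)
      act <- which(a > 0)
      if (length(act))
        succ[[m]] <- frontier[act, , drop = FALSE] +
          matrix(r$change, length(act), network$n, byrow = TRUE)
    }
    succ <- do.call(rbind, succ)
    if (is.null(succ) || nrow(succ) == 0L) break
    keys <- state_key(succ)
    first <- !duplicated(keys)
    succ <- succ[first, , drop = FALSE]; keys <- keys[first]
    new <- !vapply(keys, exists, logical(1), envir = seen, inherits = FALSE)
    if (!any(new)) break
    succ <- succ[new, , drop = FALSE]; keys <- keys[new]
    for (kk in keys) assign(kk, TRUE, envir = seen)
    total <- total + nrow(succ)
    if (total > cap) {
      cond <- structure(
        class = c("swcme_unbounded", "error", "condition"),
        list(message = sprintf(
          "state space exploration exceeded cap (%g); %d states found so far (space may be infinite)",
          cap, total),
          call = sys.call(-1), count = total))
      stop(cond)
    }
    chunks[[length(chunks) + 1L]] <- succ
    frontier <- succ
  }
  new_state_set(do.call(rbind, chunks))
}

# count integer lattice points of [lower, upper] intersected with the
# conservation-law hyperplanes, without materialising them when possible.
# Exact via free-dimension enumeration when laws are present (the enumeration
# itself is over the free dimensions only); plain box volume without laws.
window_size_estimate <- function(lower, upper, laws, cap = Inf) {
  lower <- pmax(ceiling(lower), 0); upper <- floor(upper)
  if (any(upper < lower)) return(0)
  if (!length(laws)) return(prod(upper - lower + 1))
  sol <- law_solutions(lower, upper, laws, cap = cap, count_only = TRUE)
  sol$count
}

# enumerate (or just count) lattice points in the box satisfying all laws.
# Laws are eliminated by solving for "pivot" dimensions (chosen greedily to
# have the widest ranges, keeping the enumerated free grid small).
law_solutions <- function(lower, upper, laws, cap = Inf, count_only = FALSE) {
  n <- length(lower)
  L <- do.call(rbind, lapply(laws, `[[`, "coefficients"))
  const <- vapply(laws, `[[`, numeric(1), "constant")
  r <- qr(L)$rank
  ranges <- upper - lower
  ord <- order(ranges, decreasing = TRUE)
  piv <- integer(0)
  for (col in ord) {
    if (length(piv) == r) break
    cand <- c(piv, col)
    if (qr(L[, cand, drop = FALSE])$rank > length(piv)) piv <- cand
  }
  free <- setdiff(seq_len(n), piv)
  grid_size <- prod(ranges[free] + 1)
  if (grid_size > cap)
    stop(sprintf("window enumeration would exceed the state cap (%g free-grid points)", grid_size))
  Fg <- as.matrix(expand.grid(lapply(free, function(d) seq(lower[d], upper[d])),
                              KEEP.OUT.ATTRS = FALSE))
  Lp <- L[, piv, drop = FALSE]
  rhs <- matrix(const, r, nrow(Fg)) -
    (if (length(free)) L[, free, drop = FALSE] %*% t(Fg) else matrix(0, r, nrow(Fg)))
  Xp <- solve(Lp, rhs)                      # r x m
  Xp_round <- round(Xp)
  ok <- colSums(abs(Xp - Xp_round) > 1e-8) == 0
  for (i in seq_len(r)) ok <- ok & Xp_round[i, ] >= lower[piv[i]] & Xp_round[i, ] <= upper[piv[i]]
  if (count_only) return(list(count = sum(ok)))
  m <- sum(ok)
  X <- matrix(0, m, n)
  if (m > 0) {
    if (length(free)) X[, free] <- Fg[ok, , drop = FALSE]
    X[, piv] <- t(Xp_round[, ok, drop = FALSE])
    # exact integer verification of every law
    keep <- rep(TRUE, m)
    for (j in seq_along(laws))
      keep <- keep & (X %*% laws[[j]]$coefficients == const[j])
    X <- X[keep, , drop = FALSE]
  }
  list(states = X, count = nrow(X))
}

#' Enumerate a window of the state space
#'
#' A window is the union of a seed set of states and every lattice point of
#' the box `[lower, upper]` that satisfies all conservation laws. Enforcing
#' the laws generalises a hand-built parallelogram-shaped window: without
#' them a box may contain many states that are unreachable.
#'
#' @param lower,upper integer per-dimension bounds, `lower <= upper`
#'   componentwise (lower is clipped at 0).
#' @param laws list of `conservation_law` objects (possibly empty).
#' @param seed optional matrix of states (rows) always included.
#' @param cap guard on the number of enumerated states.
#' @return a `cme_window` (a `state_set` with bounds and law metadata).
#' @export
enumerate_window <- function(lower, upper, laws = list(), seed = NULL, cap = 5e6) {
  lower <- pmax(ceiling(lower), 0); upper <- floor(upper)
  if (any(upper < lower) && is.null(seed)) {
    return(new_state_set(matrix(numeric(0), 0, length(lower)),
                         class = c("cme_window", "state_set"),
                         extra = list(lower = lower, upper = upper, laws = laws, seed_count = 0L)))
  }
  if (all(upper >= lower)) {
    if (length(laws)) {
      X <- law_solutions(lower, upper, laws, cap = cap)$states
    } else {
      if (prod(upper - lower + 1) > cap)
        stop(sprintf("window enumeration would exceed the state cap (%g box points)",
                     prod(upper - lower + 1)))
      X <- as.matrix(expand.grid(lapply(seq_along(lower), function(d) seq(lower[d], upper[d])),
                                 KEEP.OUT.ATTRS = FALSE))
      colnames(X) <- NULL
    }
  } else X <- matrix(numeric(0), 0, length(lower))
  nseed <- 0L
  if (!is.null(seed) && nrow(seed) > 0) {
    seed <- as.matrix(seed)
    miss <- !(state_key(seed) %in% state_key(X))
    nseed <- nrow(seed)
    if (any(miss)) X <- rbind(X, seed[miss, , drop = FALSE])
  }
  if (nrow(X) > cap)
    stop(sprintf("window size %d exceeds the state cap (%g)", nrow(X), cap))
  new_state_set(X, class = c("cme_window", "state_set"),
                extra = list(lower = lower, upper = upper, laws = laws, seed_count = nseed))
}

#' @export
print.cme_window <- function(x, ...) {
  cat(sprintf("<window: %d states; bounds [%s] .. [%s]; %d law(s)>\n",
              x$N, paste(x$lower, collapse = ","), paste(x$upper, collapse = ","),
              length(x$laws)))
  invisible(x)
}

#' Window-restricted generator matrix
#'
#' Builds the sparse rate matrix of the Markov process restricted to a
#' window: off-diagonal entries are the reaction rates between window
#' members, and each diagonal entry is the negated *full* exit rate of the
#' state (including rates into states outside the window). Rows whose
#' reactions all stay inside the window therefore sum to zero, while rows
#' with outbound reactions sum to a negative number -- the matrix is
#' substochastic and the missing row mass is exactly the rate of leaking out
#' of the window.
#'
#' @param window a `cme_window` or `state_set`.
#' @param network a `cme_network`.
#' @return a sparse `dgCMatrix` of dimension N x N (N = window size), with
#'   row/column order matching `window$states`.
#' @export
build_generator <- function(window, network) {
  N <- window$N
  if (N == 0L) stop("cannot build a generator for an empty window")
  X <- window$states
  ii <- jj <- integer(0); xx <- numeric(0)
  diagv <- numeric(N)
  for (m in seq_len(network$k)) {
    r <- network$reactions[[m]]
    a <- eval_propensity(r, X)
    act <- which(a > 0)
    if (!length(act)) next
    diagv[act] <- diagv[act] - a[act]
    succ <- X[act, , drop = FALSE] + matrix(r$change, length(act), network$n, byrow = TRUE)
    j <- match(state_key(succ), window$keys)
    keep <- !is.na(j)
    if (any(keep)) {
      ii <- c(ii, act[keep]); jj <- c(jj, j[keep]); xx <- c(xx, a[act[keep]])
    }
  }
  Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                       x = c(xx, diagv), dims = c(N, N))
}
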