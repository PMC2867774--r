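# Sparse probability distributions over population states.

#' Sparse distribution over population states
#'
#' @param states matrix of states (one row each).
#' @param p probabilities, same length as `nrow(states)`; zeros are dropped;
#'   states are stored in lexicographic order.
#' @return object of class `cme_dist` with fields `states`, `keys`, `p`.
#' @export
cme_dist <- function(states, p) {
  states <- as.matrix(states)
  storage.mode(states) <- "double"
  dimnames(states) <- NULL
  p <- as.numeric(p)
  stopifnot(nrow(states) == length(p), all(p >= 0))
  keep <- p > 0
  states <- states[keep, , drop = FALSE]; p <- p[keep]
  if (nrow(states)) {
    o <- lex_order(states)
    states <- states[o, , drop = FALSE]; p <- p[o]
  }
  if (sum(p) > 1 + 1e-12) stop("distribution mass exceeds 1")
  structure(list(states = states, keys = state_key(states), p = p),
            class = "cme_dist")
}

#' Point mass at a single state
#' @param state integer state vector.
#' @export
point_mass <- function(state) cme_dist(matrix(as.numeric(state), 1L), 1)

#' Total probability mass
#' @param d a `cme_dist`.
#' @export
dist_mass <- function(d) sum(d$p)

#' @export
print.cme_dist <- function(x, ...) {
  cat(sprintf("<distribution: %d states, mass %.6g>\n", length(x$p), dist_mass(x)))
  invisible(x)
}

#' @export
as.data.frame.cme_dist <- function(x, row.names = NULL, optional = FALSE,
                                   species = NULL, ...) {
  df <- as.data.frame(x$states)
  names(df) <- if (!is.null(species)) species else paste0("x", seq_len(ncol(x$states)))
  df$probability <- x$p
  df
}

#' Expected population vector of a distribution
#' @param d a `cme_dist`.
#' @export
dist_mean <- function(d) as.numeric(colSums(d$states * d$p) / dist_mass(d))

#' Marginal distribution of one species
#'
#' @param d a `cme_dist`.
#' @param dim species index.
#' @return data frame with columns `count` and `probability` (sorted by
#'   count; mass not renormalized).
#' @export
dist_marginal <- function(d, dim) {
  agg <- tapply(d$p, d$states[, dim], sum)
  data.frame(count = as.numeric(names(agg)), probability = as.numeric(agg))
}

#' States above a probability threshold
#'
#' The significant set: all states whose probability strictly exceeds
#' `delta`.
#'
#' @param d a `cme_dist`.
#' @param delta non-negative threshold.
#' @return matrix of significant states (rows).
#' @export
significant_set <- function(d, delta) d$states[d$p > delta, , drop = FALSE]

#' Largest usable significance threshold
#'
#' Walks the decade schedule \eqn{10^{-5}, 10^{-6}, \ldots} and returns the
#' largest threshold whose discarded mass (states at or below it) does not
#' exceed `budget`; 0 if even the smallest schedule value discards too much.
#'
#' @param d a `cme_dist`.
#' @param budget positive mass budget for thresholding in this step.
#' @export
dynamic_delta <- function(d, budget) {
  stopifnot(budget > 0)
  delta <- 1e-5
  pmin_pos <- if (length(d$p)) min(d$p) else 1
  repeat {
    if (sum(d$p[d$p <= delta]) <= budget) return(delta)
    delta <- delta / 10
    if (delta < pmin_pos * 1e-3 || delta < 1e-300) return(0)
  }
}

#' Restrict a distribution to a window
#'
#' Drops every entry outside the window and reports the removed mass (the
#' thresholding loss of the sliding-window step).
#'
#' @param d a `cme_dist`.
#' @param window a `cme_window` or `state_set`.
#' @return list with the restricted `dist` and the `lost` mass.
#' @export
mask_to_window <- function(d, window) {
  inside <- d$keys %in% window$keys
  lost <- sum(d$p[!inside])
  list(dist = cme_dist(d$states[inside, , drop = FALSE], d$p[inside]),
       lost = lost)
}

#' Discretized truncated Gaussian initial distribution
#'
#' Product of independent normal densities evaluated at the non-negative
#' integer lattice points within `truncation` standard deviations of the
#' mean, renormalized to total mass one. Used e.g. to seed the bistable
#' toggle switch.
#'
#' @param mean numeric vector of means.
#' @param variance positive variances (recycled).
#' @param truncation half-width of the lattice in standard deviations.
#' @return a `cme_dist`.
#' @export
discretize_gaussian <- function(mean, variance, truncation = 6) {
  stopifnot(all(variance > 0), truncation > 0)
  n <- length(mean)
  variance <- rep_len(variance, n)
  sd <- sqrt(variance)
  ranges <- lapply(seq_len(n), function(d) {
    lo <- max(0, floor(mean[d] - truncation * sd[d]))
    hi <- max(0, ceiling(mean[d] + truncation * sd[d]))
    seq(lo, hi)
  })
  if (any(!vapply(ranges, length, 1L)))
    stop("contract violation: truncation produced an empty lattice")
  X <- as.matrix(expand.grid(ranges, KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- NULL
  dens <- rep_len(1, nrow(X))
  for (d in seq_len(n)) dens <- dens * stats::dnorm(X[, d], mean[d], sd[d])
  if (sum(dens) == 0) stop("contract violation: truncation produced an empty lattice")
  cme_dist(X, dens / sum(dens))
}
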