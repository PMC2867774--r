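# The sliding-window driver: thresholding, window construction, masked
# restart, window-restricted transient solve, and loss accounting.

# run expr under a private RNG stream, leaving the caller's RNG untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

all_avg_branch <- function(network) list(branch_spec(rep("AVG", network$k), "average"))

#' Solve the chemical master equation with a sliding window
#'
#' Tracks the transient distribution of a reaction network's Markov process
#' through a sequence of window-restricted solves. Each step (i) thresholds
#' the current distribution at a dynamically chosen significance level
#' \eqn{\delta}, (ii) predicts per-species population bounds by worst-case
#' deterministic branch iterations started from a random sample of the
#' significant states, (iii) enumerates the window (bounds box intersected
#' with the conservation laws, united with the significant set), (iv) drops
#' probability mass outside the window, and (v) propagates inside the window
#' with uniformization or a Krylov-subspace exponential. All discarded mass
#' is audited: the result's total loss \eqn{\eta_r = 1 - } final mass bounds
#' the approximation error, split per step into thresholding loss and
#' window-leak loss.
#'
#' @param network a `cme_network`.
#' @param times strictly increasing output time points (the first entry is
#'   the start time); alternatively give `t_end` for `times = c(0, t_end)`.
#' @param t_end convenience horizon.
#' @param init initial condition: a `cme_dist`, a state vector, or `NULL`
#'   for a point mass at the network's initial state.
#' @param eps total error budget for the transient solves, distributed over
#'   steps proportionally to their length.
#' @param solver `"uniformization"` or `"krylov"`.
#' @param stepping `"adaptive"` chooses each step length so the predicted
#'   window just outgrows the significant set (at least `min_window` states
#'   and twice the significant count); `"equidistant"` uses
#'   `(t_r - t_0)/n_steps`.
#' @param n_steps number of steps for equidistant stepping.
#' @param seed integer seed for the significant-state sampling (a dedicated
#'   stream; the solver choice does not perturb it).
#' @param min_window minimum window size for adaptive stepping.
#' @param branches branch list for the bound iteration; defaults to
#'   [default_branches()].
#' @param delta_policy step-length policy of the bound iteration (see
#'   [cont_det_approx()]).
#' @param state_cap refuse windows larger than this many states.
#' @param use_laws enforce conservation laws in window membership (disable
#'   only for debugging).
#' @param window_shrink fraction by which each dimension of the bounds box
#'   is shrunk before enumeration (an ablation knob; 0 in normal use).
#' @param avg_only replace every branch mode by `AVG` and widen bounds over
#'   a doubled look-ahead interval (an ablation knob).
#' @param full_space ignore windows and solve on the full reachable space
#'   (finite models only; for validation).
#' @param krylov_m Krylov subspace dimension.
#' @param alert warn if the total loss exceeds this level.
#' @param retry_scale widen all window bounds by this factor about their
#'   midpoint (manual remedy when the audited loss is too large).
#' @return an object of class `sw_solution`; see [summary.sw_solution()].
#' @export
sw_solve <- function(network, times = NULL, t_end = NULL, init = NULL,
                     eps = 1e-8,
                     solver = c("uniformization", "krylov"),
                     stepping = c("adaptive", "equidistant"),
                     n_steps = 20, seed = 1L, min_window = 500,
                     branches = default_branches(network),
                     delta_policy = "exit", state_cap = 5e6,
                     use_laws = TRUE, window_shrink = 0, avg_only = FALSE,
                     full_space = FALSE, krylov_m = 30, alert = 1e-3,
                     retry_scale = 1) {
  solver <- match.arg(solver)
  stepping <- match.arg(stepping)
  if (is.null(times)) {
    if (is.null(t_end)) stop("give 'times' or 't_end'")
    times <- c(0, t_end)
  }
  stopifnot(length(times) >= 1, !is.unsorted(times, strictly = TRUE), eps > 0)
  p <- if (is.null(init)) point_mass(network$init)
       else if (inherits(init, "cme_dist")) init
       else point_mass(init)
  if (dist_mass(p) > 1 + 1e-12) stop("initial mass exceeds 1")

  t0 <- times[1L]; tr <- times[length(times)]
  out <- vector("list", length(times)); out[[1L]] <- p
  eta <- numeric(length(times)); eta[1L] <- 1 - dist_mass(p)
  if (length(times) == 1L || tr == t0)
    return(new_sw_solution(network, times, out, eta, empty_step_log(),
                           seed, solver, stepping))

  total_T <- tr - t0
  laws <- if (use_laws) conservation_laws(network) else list()
  if (avg_only) branches <- all_avg_branch(network)

  space <- NULL; Qfull <- NULL
  if (full_space) {
    space <- reachable_states(network, cap = state_cap)
    Qfull <- build_generator(space, network)
  }

  tau_fixed <- total_T / n_steps
  tau_prev <- if (stepping == "adaptive") total_T / 100 else tau_fixed
  t_cur <- t0
  out_ptr <- 2L
  j <- 0L
  log_rows <- list()
  tol_t <- 1e-9 * total_T

  while (t_cur < tr - tol_t) {
    if (length(p$p) == 0L) {    # all mass lost (possible under ablation knobs)
      for (ti in which(times > t_cur + tol_t)) { out[[ti]] <- p; eta[ti] <- 1 }
      break
    }
    j <- j + 1L
    # --- significance thresholding -------------------------------------
    budget <- 1e-5 * tau_prev / total_T
    delta <- dynamic_delta(p, budget)
    S <- significant_set(p, delta)
    if (nrow(S) == 0L) S <- p$states[which.max(p$p), , drop = FALSE]
    nsig <- nrow(S)
    nA <- min(10L, nsig)
    A <- S[with_seed(seed + j * 104729L, sample.int(nsig, nA)), , drop = FALSE]

    # --- window construction and step length ---------------------------
    if (full_space) {
      W <- space; Q <- Qfull
      tau_j <- times[which(times > t_cur + tol_t)[1L]] - t_cur
    } else {
      if (stepping == "adaptive") {
        ah <- adaptive_horizon(network, A, branches, min_window = min_window,
                               horizon = tr - t_cur, n_significant = nsig,
                               laws = laws, delta = delta_policy)
        tau_j <- ah$tau
        bl <- ah$lower; bu <- ah$upper
      } else {
        tau_j <- min(tau_fixed, tr - t_cur)
        b <- NULL
        look <- if (avg_only) 2 * tau_j else tau_j
        for (z in seq_len(nrow(A)))
          b <- cont_det_approx(network, A[z, ], look, branches,
                               prior = b, delta = delta_policy)
        bl <- b$lower; bu <- b$upper
      }
      if (tau_j <= tol_t) tau_j <- min(tau_prev, tr - t_cur)
      if (avg_only && stepping == "adaptive") {
        b <- list(lower = bl, upper = bu)
        for (z in seq_len(nrow(A)))
          b <- cont_det_approx(network, A[z, ], 2 * tau_j, branches,
                               prior = b, delta = delta_policy)
        bl <- b$lower; bu <- b$upper
      }
      if (window_shrink > 0) {
        cut <- (bu - bl) * window_shrink / 2
        bl <- ceiling(bl + cut); bu <- floor(bu - cut)
      }
      if (retry_scale != 1) {
        mid <- (bu + bl) / 2; half <- (bu - bl) / 2 * retry_scale
        bl <- floor(mid - half); bu <- ceiling(mid + half)
      }
      W <- tryCatch(
        enumerate_window(bl, bu, laws, seed = S, cap = state_cap),
        error = function(e) stop(sprintf("step %d (t = %g): %s", j, t_cur,
                                         conditionMessage(e)), call. = FALSE))
      Q <- build_generator(W, network)
    }

    # --- masked restart -------------------------------------------------
    mk <- mask_to_window(p, W)
    loss_thresh <- mk$lost
    p_vec <- numeric(W$N)
    p_vec[state_index(W, mk$dist$states)] <- mk$dist$p
    mass_before <- sum(p_vec)

    # --- window-restricted solve, hitting requested times exactly -------
    step_eps <- eps * tau_j / total_T
    t_end_step <- t_cur + tau_j
    hits <- which(times > t_cur + tol_t & times <= t_end_step + tol_t)
    seg_ends <- unique(c(times[hits], t_end_step))
    seg_ends <- seg_ends[seg_ends > t_cur + tol_t]
    At <- NULL
    seg_start <- t_cur
    for (se in seg_ends) {
      seg_tau <- se - seg_start
      if (seg_tau > 0) {
        if (solver == "uniformization") {
          p_vec <- tryCatch(
            uniformize(Q, p_vec, seg_tau, eps = step_eps * seg_tau / tau_j),
            error = function(e) stop(sprintf("step %d solver failure: %s", j,
                                             conditionMessage(e)), call. = FALSE))
        } else {
          if (is.null(At)) At <- Matrix::t(Q)
          p_vec <- tryCatch(
            krylov_expv(At, p_vec, seg_tau, tol = step_eps * seg_tau / tau_j,
                        m = krylov_m),
            error = function(e) stop(sprintf("step %d solver failure: %s", j,
                                             conditionMessage(e)), call. = FALSE))
          p_vec <- pmax(p_vec, 0)
          if (sum(p_vec) > mass_before)    # round-off guard: mass must not grow
            p_vec <- p_vec * (mass_before / sum(p_vec))
        }
      }
      if (any(abs(times - se) <= tol_t)) {
        ti <- which.min(abs(times - se))
        keep <- p_vec > 0
        out[[ti]] <- cme_dist(W$states[keep, , drop = FALSE], p_vec[keep])
        eta[ti] <- 1 - sum(p_vec)
        out_ptr <- max(out_ptr, ti + 1L)
      }
      seg_start <- se
    }
    loss_leak <- max(mass_before - sum(p_vec), 0)
    keep <- p_vec > 0
    p <- cme_dist(W$states[keep, , drop = FALSE], p_vec[keep])

    log_rows[[j]] <- data.frame(
      step = j, t_start = t_cur, tau = tau_j, window_size = W$N,
      n_significant = nsig, delta = delta,
      loss_threshold = loss_thresh, loss_leak = loss_leak,
      mass = sum(p_vec))
    t_cur <- t_end_step
    tau_prev <- tau_j
  }

  steps <- do.call(rbind, log_rows)
  sol <- new_sw_solution(network, times, out, eta, steps, seed, solver, stepping)
  if (sol$eta_r > alert)
    warning(sprintf("total probability loss %.3g exceeds the alert level %.3g; consider retry_scale > 1",
                    sol$eta_r, alert))
  sol
}

empty_step_log <- function() data.frame(
  step = integer(), t_start = numeric(), tau = numeric(),
  window_size = integer(), n_significant = integer(), delta = numeric(),
  loss_threshold = numeric(), loss_leak = numeric(), mass = numeric())

new_sw_solution <- function(network, times, dists, eta, steps, seed, solver, stepping) {
  structure(list(network = network, times = times, dist = dists, eta = eta,
                 steps = steps, eta_r = eta[length(eta)],
                 seed = seed, solver = solver, stepping = stepping),
            class = "sw_solution")
}

#' @export
print.sw_solution <- function(x, ...) {
  cat(sprintf("Sliding-window CME solution: %s, t in [%g, %g]\n",
              if (nzchar(x$network$name)) x$network$name else "network",
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  solver %s, %s stepping, %d window step(s), seed %d\n",
              x$solver, x$stepping, nrow(x$steps), x$seed))
  cat(sprintf("  final support %d states; total probability loss eta_r = %.3g\n",
              length(x$dist[[length(x$dist)]]$p), x$eta_r))
  invisible(x)
}

#' Summary of a sliding-window solution
#'
#' @param object an `sw_solution`.
#' @param ... unused.
#' @return the object, invisibly, after printing the per-step ledger
#'   (step length, window size, thresholding and leak losses, running mass).
#' @export
summary.sw_solution <- function(object, ...) {
  print(object)
  if (nrow(object$steps)) {
    cat("\nPer-step ledger:\n")
    df <- object$steps
    df$tau <- signif(df$tau, 4); df$delta <- signif(df$delta, 2)
    df$loss_threshold <- signif(df$loss_threshold, 3)
    df$loss_leak <- signif(df$loss_leak, 3); df$mass <- signif(df$mass, 8)
    print(df, row.names = FALSE)
  }
  invisible(object)
}

#' Plot a marginal distribution from a solution
#'
#' @param x an `sw_solution`.
#' @param species species name or index.
#' @param time which output time to show (defaults to the last).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sw_solution <- function(x, species = 1L, time = NULL, ...) {
  if (is.character(species)) species <- match(species, x$network$species)
  ti <- if (is.null(time)) length(x$times) else which.min(abs(x$times - time))
  mg <- dist_marginal(x$dist[[ti]], species)
  graphics::plot(mg$count, mg$probability, type = "h",
                 xlab = x$network$species[species], ylab = "probability",
                 main = sprintf("t = %g", x$times[ti]), ...)
  invisible(x)
}

#' @export
as.data.frame.sw_solution <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$times), function(i) {
    df <- as.data.frame(x$dist[[i]], species = x$network$species)
    cbind(time = x$times[i], df)
  }))
}
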