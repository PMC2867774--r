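# Transient propagators: uniformization with Poisson truncation, and an
# adaptive Krylov-subspace approximation of the matrix exponential action.

#' Truncated Poisson weights
#'
#' Left/right truncation points and probabilities of a Poisson distribution
#' such that the retained mass is at least `1 - eps` (each discarded tail
#' holds at most `eps/2`). These weight the powers of the uniformized
#' transition matrix, so the truncation error of [uniformize()] is bounded a
#' priori by `eps`.
#'
#' @param mean non-negative Poisson mean (\eqn{\lambda\tau}).
#' @param eps tail tolerance in (0, 1).
#' @return list with integer `L`, `U` and numeric `weights` for `L:U`.
#' @export
poisson_truncation <- function(mean, eps = 1e-8) {
  stopifnot(mean >= 0, eps > 0, eps < 1)
  if (mean == 0) return(list(L = 0L, U = 0L, weights = 1))
  L <- stats::qpois(eps / 2, mean)
  U <- stats::qpois(1 - eps / 2, mean)
  # qpois guarantees tail bounds per side; widen defensively until the
  # retained mass covers 1 - eps
  repeat {
    mass <- stats::ppois(U, mean) - (if (L > 0) stats::ppois(L - 1L, mean) else 0)
    if (mass >= 1 - eps) break
    L <- max(0L, L - 1L); U <- U + 1L
  }
  list(L = L, U = U, weights = stats::dpois(L:U, mean))
}

as_dgc <- function(M) methods::as(methods::as(methods::as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")

#' Propagate a distribution by uniformization
#'
#' Computes \eqn{p_0 e^{Q\tau}} as the Poisson-weighted sum
#' \eqn{\sum_k \mathrm{Pois}(\lambda\tau; k)\, p_0 P^k} with
#' \eqn{P = I + Q/\lambda} and \eqn{\lambda} the maximal exit rate, keeping
#' only the significant Poisson terms. For a window-restricted
#' (substochastic) generator the result is substochastic and the missing
#' mass is exactly the probability of having left the window. The weighted
#' sum is accumulated on the fly (no intermediate vectors are stored), with
#' iterate entries below `prune` dropped.
#'
#' @param Q generator matrix (sparse `dgCMatrix`; diagonal carries the full
#'   negated exit rates).
#' @param p0 initial probability row vector over the generator's states.
#' @param tau time step, `tau >= 0`.
#' @param eps Poisson truncation tolerance.
#' @param prune drop threshold for iterate entries.
#' @return the propagated (possibly substochastic) probability vector.
#' @export
uniformize <- function(Q, p0, tau, eps = 1e-8, prune = 1e-20) {
  if (tau < 0) stop("contract violation: tau must be non-negative")
  p0 <- as.numeric(p0)
  if (tau == 0) return(p0)
  lam <- max(-Matrix::diag(Q))
  if (lam <= 0) return(p0)          # zero generator: identity semigroup
  N <- nrow(Q)
  P <- as_dgc(Matrix::Diagonal(N) + Q / lam)
  tr <- poisson_truncation(lam * tau, eps)
  unif_core(P@p, P@i, P@x, p0, tr$weights, tr$L, prune)
}

#' Arnoldi factorization
#'
#' Builds an orthonormal basis \eqn{V_m} of the Krylov subspace
#' \eqn{\mathrm{span}\{v, Av, \ldots, A^{m-1}v\}} and the projected upper
#' Hessenberg matrix \eqn{H_m}, satisfying
#' \eqn{A V_m = V_m H_m + h_{m+1,m} v_{m+1} e_m^T}. Modified Gram-Schmidt
#' with one reorthogonalization pass. If the subspace becomes invariant
#' before `m` steps ("happy breakdown"), a smaller exact factorization is
#' returned.
#'
#' @param A square matrix (anything `%*%` handles) or a function
#'   implementing `x -> A x`.
#' @param v start vector (nonzero).
#' @param m subspace dimension.
#' @param tol breakdown threshold relative to the start vector norm.
#' @return object of class `krylov_state`: `basis` (n x j), `hessenberg`
#'   (j x j), `next_norm` (\eqn{h_{j+1,j}}), `next_vector`, `dim` (j),
#'   `beta` (norm of `v`), `breakdown` flag.
#' @export
arnoldi <- function(A, v, m = 30, tol = 1e-12) {
  matvec <- if (is.function(A)) A else function(x) as.numeric(A %*% x)
  n <- length(v)
  m <- min(m, n)
  beta <- sqrt(sum(v^2))
  if (beta == 0) stop("contract violation: Arnoldi start vector is zero")
  V <- matrix(0, n, m + 1L)
  H <- matrix(0, m + 1L, m)
  V[, 1L] <- v / beta
  breakdown <- FALSE
  j <- 0L
  for (jj in seq_len(m)) {
    w <- matvec(V[, jj])
    for (i in seq_len(jj)) {
      h <- sum(V[, i] * w)
      H[i, jj] <- H[i, jj] + h
      w <- w - h * V[, i]
    }
    for (i in seq_len(jj)) {        # reorthogonalization pass
      c2 <- sum(V[, i] * w)
      H[i, jj] <- H[i, jj] + c2
      w <- w - c2 * V[, i]
    }
    hn <- sqrt(sum(w^2))
    H[jj + 1L, jj] <- hn
    j <- jj
    if (hn <= tol * beta) { breakdown <- TRUE; break }
    V[, jj + 1L] <- w / hn
  }
  structure(list(basis = V[, seq_len(j), drop = FALSE],
                 hessenberg = H[seq_len(j), seq_len(j), drop = FALSE],
                 next_norm = if (breakdown) 0 else H[j + 1L, j],
                 next_vector = if (breakdown) NULL else V[, j + 1L],
                 dim = j, beta = beta, breakdown = breakdown),
            class = "krylov_state")
}

#' Matrix exponential of a small dense matrix
#'
#' Scaling-and-squaring with the degree-13 irreducible Pade approximant;
#' intended for the small projected Hessenberg matrices arising in
#' [krylov_expv()] and for dense reference solves on modest state spaces.
#'
#' @param H square numeric matrix.
#' @return \eqn{e^H}.
#' @export
small_matrix_exp <- function(H) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (n == 0L) return(H)
  nrm <- max(rowSums(abs(H)))
  s <- if (nrm > 5.37) ceiling(log2(nrm / 5.37)) else 0
  A <- H / 2^s
  b <- c(64764752532480000, 32382376266240000, 7771770303897600, 1187353796428800,
         129060195264000, 10559470521600, 670442572800, 33522128640, 1323241920,
         40840800, 960960, 16380, 182, 1)
  I <- diag(1, n)
  A2 <- A %*% A; A4 <- A2 %*% A2; A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  FF <- solve(V - U, V + U)
  for (i in seq_len(s)) FF <- FF %*% FF
  FF
}

#' Krylov-subspace approximation of \eqn{e^{tA} v}
#'
#' Steps forward in time with dynamically chosen substeps: each substep
#' projects the propagator onto an m-dimensional Krylov subspace
#' (\eqn{e^{\tau A} u \approx \|u\| V_m e^{\tau H_m} e_1}), estimates the
#' local error a posteriori from the \eqn{h_{m+1,m}} correction terms, and
#' rejects the substep when the estimate exceeds 1.2 times its share of the
#' error budget. Step sizes update as
#' \eqn{\tau_{i+1} = 0.9\,\tau_i (\mathrm{budget}_i/\epsilon_i)^{1/m}},
#' clipped to \eqn{[0.2\tau_i, 5\tau_i]}. A happy breakdown makes the
#' substep exact up to round-off.
#'
#' @param A square matrix or matvec function (supply `anorm` for functions).
#' @param v start vector.
#' @param t time, `t >= 0`.
#' @param tol total error budget, distributed over substeps proportionally
#'   to their length.
#' @param m Krylov dimension (default 30).
#' @param anorm estimate of a matrix norm of `A` (defaults to the infinity
#'   norm when `A` is a matrix); sets the initial step size.
#' @return approximation of \eqn{e^{tA} v}.
#' @export
krylov_expv <- function(A, v, t, tol = 1e-8, m = 30, anorm = NULL) {
  stopifnot(t >= 0, tol > 0)
  if (t == 0) return(v)
  matvec <- if (is.function(A)) A else function(x) as.numeric(A %*% x)
  if (is.null(anorm)) {
    if (is.function(A)) stop("'anorm' is required when A is a function")
    anorm <- max(Matrix::rowSums(abs(A)))
  }
  n <- length(v)
  m <- min(m, n)
  u <- v
  if (sqrt(sum(u^2)) == 0) return(u)
  # initial substep from the truncation bound: (rho tau)^m e^{rho tau}/m! ~ tol
  fact <- ((m + 1) / exp(1))^(m + 1) * sqrt(2 * pi * (m + 1))
  tau <- if (anorm > 0) min(t, (1 / anorm) * ((fact * tol) / (4 * anorm))^(1 / m)) else t
  t_done <- 0
  while (t_done < t * (1 - 1e-14)) {
    tau <- min(tau, t - t_done)
    arn <- arnoldi(matvec, u, m)
    jdim <- arn$dim
    if (arn$breakdown) {
      FF <- small_matrix_exp(tau * arn$hessenberg)
      u <- arn$beta * as.numeric(arn$basis %*% FF[, 1L])
      err <- 0; xm <- 1 / max(jdim, 1)
    } else {
      avnorm <- sqrt(sum(matvec(arn$next_vector)^2))
      Hbar <- matrix(0, jdim + 2L, jdim + 2L)
      Hbar[seq_len(jdim), seq_len(jdim)] <- arn$hessenberg
      Hbar[jdim + 1L, jdim] <- arn$next_norm
      Hbar[jdim + 2L, jdim + 1L] <- 1
      repeat {
        FF <- small_matrix_exp(tau * Hbar)
        phi1 <- abs(arn$beta * FF[jdim + 1L, 1L])
        phi2 <- abs(arn$beta * FF[jdim + 2L, 1L] * avnorm)
        if (phi1 > 10 * phi2) { err <- phi2; xm <- 1 / jdim }
        else if (phi1 > phi2) { err <- phi1 * phi2 / (phi1 - phi2); xm <- 1 / jdim }
        else { err <- phi1; xm <- 1 / max(jdim - 1L, 1L) }
        budget <- tol * tau / t
        if (err <= 1.2 * budget) break
        tau <- max(0.2 * tau, 0.9 * tau * (budget / err)^xm)
        if (tau < 1e-14 * t)
          stop("stiffness failure: Krylov substep size underflow")
      }
      u <- arn$beta * as.numeric(cbind(arn$basis, arn$next_vector) %*%
                                   FF[seq_len(jdim + 1L), 1L])
    }
    t_done <- t_done + tau
    growth <- if (err > 0) 0.9 * (tol * tau / t / err)^xm else 5
    tau <- tau * min(5, max(0.2, growth))
  }
  u
}
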