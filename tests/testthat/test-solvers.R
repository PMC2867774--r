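test_that("poisson_truncation retains 1 - eps mass with stable weights", {
  tr0 <- poisson_truncation(0, 1e-8)
  expect_equal(tr0$L, 0L); expect_equal(tr0$U, 0L); expect_equal(tr0$weights, 1)

  # one-standard-deviation interval at mean 1: [0, 2] holds 91.97 percent,
  # so a 9 percent tail tolerance forces the upper truncation point past 2
  expect_equal(sum(dpois(0:2, 1)), 0.9197, tolerance = 1e-4)
  tr1 <- poisson_truncation(1, 0.09)
  expect_gte(tr1$U, 2)
  expect_gte(sum(tr1$weights), 1 - 0.09)

  tr <- poisson_truncation(100, 1e-8)
  expect_gte(sum(tr$weights), 1 - 1e-8)
  expect_lt(tr$U - tr$L, 20 * sqrt(100))
  expect_equal(tr$weights, dpois(tr$L:tr$U, 100))   # matches direct pmf summation

  trbig <- poisson_truncation(1e6, 1e-10)
  expect_true(all(is.finite(trbig$weights)) && all(trbig$weights > 0))
  expect_gte(sum(trbig$weights), 1 - 1e-10)
})

test_that("uniformize matches closed forms and conserves mass", {
  # zero generator: identity
  Z <- Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(2, 2))
  expect_equal(uniformize(Z, c(0.3, 0.7), 5), c(0.3, 0.7))

  dec <- decay_net()
  rs <- reachable_states(dec)
  Q <- build_generator(rs, dec)
  p0 <- numeric(2); p0[state_index(rs, matrix(1, 1, 1))] <- 1
  pt <- uniformize(Q, p0, 1, 1e-12)
  want <- numeric(2)
  want[state_index(rs, matrix(0, 1, 1))] <- 1 - exp(-1)
  want[state_index(rs, matrix(1, 1, 1))] <- exp(-1)
  expect_equal(pt, want, tolerance = 1e-10)

  # substochastic window {1}: survival probability e^{-tau}
  w <- enumerate_window(1, 1, seed = matrix(1, 1, 1))
  Qw <- build_generator(w, dec)
  expect_equal(uniformize(Qw, 1, 1, 1e-12), exp(-1), tolerance = 1e-10)

  # mass is non-increasing in tau for substochastic generators
  masses <- vapply(c(0.1, 0.5, 1, 2, 4), function(tau)
    sum(uniformize(Qw, 1, tau, 1e-12)), numeric(1))
  expect_true(all(diff(masses) < 0))

  # and conserved (within eps) for conservative generators
  toy <- toy_enzyme(10, 4)
  Qt <- build_generator(reachable_states(toy), toy)
  p <- numeric(nrow(Qt)); p[1] <- 1
  expect_equal(sum(uniformize(Qt, p, 0.5, 1e-10)), 1, tolerance = 1e-9)

  expect_error(uniformize(Q, p0, -1), "contract violation")
})

test_that("arnoldi produces an orthonormal factorization with happy breakdown", {
  # start vector is an eigenvector: breakdown at step 1
  A <- diag(c(3, 5))
  ar <- arnoldi(A, c(1, 0), 2)
  expect_true(ar$breakdown)
  expect_equal(ar$dim, 1L)
  expect_equal(as.numeric(ar$hessenberg), 3)

  # full-dimension factorization is a similarity transform
  ar2 <- arnoldi(diag(c(1, 2)), c(1, 1) / sqrt(2), 2)
  expect_equal(sort(eigen(ar2$hessenberg)$values), c(1, 2))

  set.seed(7)
  A <- matrix(rnorm(400), 20)
  v <- rnorm(20)
  ar3 <- arnoldi(A, v, 10)
  em <- c(rep(0, 9), 1)
  res <- A %*% ar3$basis - ar3$basis %*% ar3$hessenberg -
    ar3$next_norm * ar3$next_vector %*% t(em)
  expect_lt(max(abs(res)), 1e-10)
  expect_lt(max(abs(crossprod(ar3$basis) - diag(10))), 1e-10)
  expect_error(arnoldi(A, rep(0, 20), 5), "contract violation")
})

test_that("small_matrix_exp is accurate", {
  expect_equal(small_matrix_exp(matrix(0, 3, 3)), diag(1, 3))
  expect_equal(small_matrix_exp(diag(c(-2, 3))), diag(c(exp(-2), exp(3))))
  N <- matrix(c(0, 1, 0, 0), 2, 2)   # nilpotent: series terminates
  expect_equal(small_matrix_exp(N), matrix(c(1, 1, 0, 1), 2, 2))
  set.seed(11)
  for (scale in c(1, 50)) {
    A <- matrix(rnorm(225), 15) * scale / 15
    expect_equal(small_matrix_exp(A), as.matrix(Matrix::expm(A)),
                 tolerance = 1e-9)
  }
})

test_that("krylov_expv approximates the exponential action", {
  # A = aI is exact for any subspace dimension
  A <- Matrix::Diagonal(8, -0.7)
  v <- as.numeric(1:8)
  expect_equal(krylov_expv(A, v, 2, tol = 1e-12, m = 1), exp(-1.4) * v,
               tolerance = 1e-10)

  dec <- decay_net()
  rs <- reachable_states(dec)
  Q <- build_generator(rs, dec)
  p0 <- numeric(2); p0[state_index(rs, matrix(1, 1, 1))] <- 1
  u <- krylov_expv(Matrix::t(Q), p0, 1, tol = 1e-10)
  expect_equal(sort(u), sort(c(exp(-1), 1 - exp(-1))), tolerance = 1e-9)

  # ~50-state mass-action generator vs the dense exponential
  net <- toy_enzyme(10, 8, rates = c(1, 1, 0.5))
  rs <- reachable_states(net)
  expect_gte(rs$N, 40)
  Q <- build_generator(rs, net)
  p0 <- numeric(rs$N); p0[state_index(rs, matrix(net$init, 1))] <- 1
  u <- krylov_expv(Matrix::t(Q), p0, 1, tol = 1e-8)
  dense <- as.numeric(small_matrix_exp(as.matrix(Matrix::t(Q))) %*% p0)
  expect_lt(max(abs(u - dense)), 1e-7)

  # with m >= N the solve is exact in the N-th Krylov subspace
  net2 <- toy_enzyme(6, 3)
  rs2 <- reachable_states(net2)
  expect_lte(rs2$N, 30)
  Q2 <- build_generator(rs2, net2)
  p02 <- numeric(rs2$N); p02[state_index(rs2, matrix(net2$init, 1))] <- 1
  u2 <- krylov_expv(Matrix::t(Q2), p02, 1, tol = 1e-6, m = rs2$N)
  dense2 <- as.numeric(small_matrix_exp(as.matrix(Matrix::t(Q2))) %*% p02)
  expect_lt(max(abs(u2 - dense2)), 1e-12)
})

test_that("uniformization and Krylov agree on finite fixtures", {
  nets <- list(toy_enzyme(10, 4), toy_enzyme(8, 8, rates = c(2, 1, 1)),
               birth_death_net(5, 1))
  for (net in nets) {
    rs <- tryCatch(reachable_states(net, cap = 3000), error = function(e) NULL)
    if (is.null(rs)) {
      rs <- enumerate_window(0, 40, seed = matrix(net$init, 1))  # truncate
    }
    Q <- build_generator(rs, net)
    p0 <- numeric(rs$N); p0[state_index(rs, matrix(net$init, 1))] <- 1
    for (t in c(0.3, 2)) {
      a <- uniformize(Q, p0, t, 1e-10)
      b <- krylov_expv(Matrix::t(Q), p0, t, tol = 1e-10)
      expect_lt(max(abs(a - b)), 10 * (1e-10 + 1e-10) + 1e-12)
    }
  }
})
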