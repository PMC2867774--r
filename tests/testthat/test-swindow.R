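test_that("a single output time returns the initial distribution unchanged", {
  net <- toy_enzyme(5, 2)
  sol <- sw_solve(net, times = 0)
  expect_equal(sol$eta_r, 0)
  expect_equal(sol$dist[[1]]$keys, "5,2,0,0")
})

test_that("forcing the full reachable space reproduces the dense exponential", {
  net <- toy_enzyme(50, 20)          # 231 states
  rs <- reachable_states(net)
  expect_lte(rs$N, 4000)
  ref <- global_solve(net, 2, method = "dense_exp")
  sol <- sw_solve(net, times = c(0, 2), eps = 1e-10, full_space = TRUE)
  expect_lt(compare_dist(ref, sol$dist[[2]])$total_variation, 1e-8)
})

test_that("the windowed solve matches the dense oracle within the audited loss", {
  net <- toy_enzyme(50, 20)
  ref <- global_solve(net, 2, method = "dense_exp")
  sol <- sw_solve(net, times = c(0, 1, 2), eps = 1e-10, seed = 5, min_window = 100)
  cmp <- compare_dist(ref, sol$dist[[3]])
  expect_lt(cmp$total_variation, sol$eta_r + 1e-8)
  expect_lt(sol$eta_r, 1e-5)
})

test_that("losses are non-negative, additive, and eta is non-decreasing", {
  net <- toy_enzyme(30, 12)
  sol <- sw_solve(net, times = c(0, 0.5, 1, 2), eps = 1e-8, seed = 2, min_window = 60)
  s <- sol$steps
  expect_true(all(s$loss_threshold >= 0))
  expect_true(all(s$loss_leak >= 0))
  expect_true(all(diff(c(1, s$mass)) <= 1e-12))       # mass never grows
  # per-step losses explain the mass decrements exactly
  expect_lt(max(abs((c(1, s$mass[-nrow(s)]) - s$mass) -
                      (s$loss_threshold + s$loss_leak))), 1e-12)
  expect_true(all(diff(sol$eta) >= -1e-12))
  expect_equal(sol$eta_r, 1 - dist_mass(sol$dist[[4]]), tolerance = 1e-14)
})

test_that("identical seeds give identical runs; the solver does not perturb sampling", {
  net <- toy_enzyme(30, 12)
  a <- sw_solve(net, times = c(0, 1), seed = 9, min_window = 60)
  b <- sw_solve(net, times = c(0, 1), seed = 9, min_window = 60)
  expect_identical(a$steps, b$steps)
  expect_identical(a$dist[[2]]$keys, b$dist[[2]]$keys)
  k <- sw_solve(net, times = c(0, 1), seed = 9, min_window = 60, solver = "krylov")
  expect_identical(a$steps$window_size, k$steps$window_size)
  expect_identical(a$steps$tau, k$steps$tau)
})

test_that("equidistant and adaptive stepping agree at shared output times", {
  net <- toy_enzyme(30, 12)
  ad <- sw_solve(net, times = c(0, 1, 2), eps = 1e-9, seed = 3, min_window = 60)
  eq <- sw_solve(net, times = c(0, 1, 2), eps = 1e-9, seed = 3, min_window = 60,
                 stepping = "equidistant", n_steps = 10)
  tol <- 10 * (ad$eta_r + eq$eta_r + 2e-9)
  for (i in 2:3)
    expect_lt(compare_dist(ad$dist[[i]], eq$dist[[i]])$total_variation, tol)
})

test_that("the window slides through an infinite state space", {
  ge <- cme_example("gene_expression", "a")
  sol <- sw_solve(ge, times = c(0, 20, 50), eps = 1e-8, seed = 1)
  expect_lt(sol$eta_r, 1e-5)
  # mRNA settles towards c1/c3 with immigration-death dynamics
  mexp <- 0.5 / 0.0029 * (1 - exp(-0.0029 * 50))
  expect_equal(dist_mean(sol$dist[[3]])[1], mexp, tolerance = 0.01)
})

test_that("a Gaussian-seeded bistable switch run keeps its mass", {
  ts <- cme_example("toggle_switch")
  init <- discretize_gaussian(c(133, 133), c(25, 25), truncation = 5)
  sol <- sw_solve(ts, times = c(0, 5), init = init, eps = 1e-8, seed = 4,
                  min_window = 200)
  expect_lt(sol$eta_r, 1e-5)
  expect_equal(dist_mean(sol$dist[[2]])[1], dist_mean(sol$dist[[2]])[2],
               tolerance = 0.05)
})

test_that("solutions print, summarize, plot and convert", {
  net <- toy_enzyme(10, 4)
  sol <- sw_solve(net, times = c(0, 0.5), seed = 1, min_window = 30)
  expect_output(print(sol), "Sliding-window CME solution")
  expect_output(summary(sol), "Per-step ledger")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(sol, species = "P"))
  df <- as.data.frame(sol)
  expect_true(all(c("time", "E", "S", "ES", "P", "probability") %in% names(df)))
  expect_equal(sum(df$probability[df$time == 0]), 1)
})
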