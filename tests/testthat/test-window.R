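test_that("kappa_count applies the one-standard-deviation rule", {
  expect_equal(kappa_count(1, "MORE"), 2)
  expect_equal(kappa_count(1, "FEWER"), 0)
  expect_equal(kappa_count(1, "AVG"), 1)
  expect_equal(kappa_count(0, "MORE"), 0)
  expect_equal(kappa_count(0, "FEWER"), 0)
  expect_equal(kappa_count(0.25, "MORE"), 0.75)
  expect_equal(kappa_count(0.25, "FEWER"), 0)   # clamped
})

test_that("one worst-case deterministic step reproduces the enzyme worked example", {
  net <- enzyme_net(1000, 100, rates = c(1, 1, 1))
  x1 <- step_deterministic(net, c(10, 10, 100, 0), 0.01,
                           branch_spec(c("FEWER", "MORE", "MORE")))
  expect_equal(x1, c(14, 12, 96, 2))
  # absorbing states do not move
  dec <- decay_net()
  expect_equal(step_deterministic(dec, 0, 0.5, branch_spec("MORE")), 0)
  # pure birth, one step
  expect_equal(step_deterministic(birth_net(), 0, 0.1, branch_spec("MORE")),
               0.1 + sqrt(0.1))
})

test_that("default branches honor curated lists and the sign rule", {
  enz <- default_branches(cme_example("enzyme", "a"))
  expect_length(enz, 4)
  expect_equal(enz[[1]]$modes, c("MORE", "FEWER", "FEWER"))
  expect_equal(enz[[4]]$modes, c("MORE", "FEWER", "MORE"))

  ge <- default_branches(cme_example("gene_expression", "a"))
  expect_length(ge, 4)
  # translation and protein decay are irrelevant for the mRNA branches
  expect_equal(ge[[1]]$modes[c(2, 4)], c("AVG", "AVG"))
  expect_equal(ge[[2]]$modes[c(2, 4)], c("AVG", "AVG"))

  bd <- default_branches(birth_death_net())
  expect_length(bd, 2)
  expect_setequal(vapply(bd, function(b) paste(b$modes, collapse = ","), ""),
                  c("MORE,FEWER", "FEWER,MORE"))
})

test_that("cont_det_approx envelopes the branch trajectories", {
  # absorbing start: bounds collapse to the state itself
  dec <- decay_net()
  b <- cont_det_approx(dec, 0, 1)
  expect_equal(b$lower, 0); expect_equal(b$upper, 0)

  # pure birth with fixed step: ten accumulations of 0.1 + sqrt(0.1)
  bb <- cont_det_approx(birth_net(), 0, 1, list(branch_spec("MORE")), delta = 0.1)
  expect_equal(bb$upper, ceiling(10 * (0.1 + sqrt(0.1))))  # = 5
  expect_equal(bb$lower, 0)

  # single-branch single-step enzyme worked example
  net <- enzyme_net(1000, 100, rates = c(1, 1, 1))
  b1 <- cont_det_approx(net, c(10, 10, 100, 0), 0.01,
                        list(branch_spec(c("FEWER", "MORE", "MORE"))), delta = 0.01)
  expect_equal(b1$lower[3], 96)   # fewest complexes
  expect_equal(b1$upper[1], 14)   # most enzymes
})

test_that("bounds are monotone in tau and in the branch set, and well ordered", {
  net <- toy_enzyme(20, 5)
  z <- c(15, 2, 3, 2)
  brs <- default_branches(net)
  prev <- NULL
  for (tau in c(0.01, 0.05, 0.1, 0.5)) {
    b <- cont_det_approx(net, z, tau, brs)
    expect_true(all(b$lower >= 0))
    expect_true(all(b$lower <= b$upper))
    if (!is.null(prev)) {
      expect_true(all(b$lower <= prev$lower))
      expect_true(all(b$upper >= prev$upper))
    }
    prev <- b
  }
  b1 <- cont_det_approx(net, z, 0.1, brs[1])
  b4 <- cont_det_approx(net, z, 0.1, brs)
  expect_true(all(b4$lower <= b1$lower) && all(b4$upper >= b1$upper))
})

test_that("adaptive_horizon meets the window-size conditions", {
  # absorbing seed: cannot grow, step is capped at the horizon
  dec <- decay_net()
  ah <- adaptive_horizon(dec, matrix(0, 1, 1), horizon = 2.5)
  expect_equal(ah$tau, 2.5)
  expect_equal(ah$lower, 0); expect_equal(ah$upper, 0)

  # growing system reaches the minimum window size
  ge <- cme_example("gene_expression", "a")
  ah2 <- adaptive_horizon(ge, matrix(c(0, 0), 1), min_window = 500, horizon = 1e4)
  expect_gte(enumerate_window(ah2$lower, ah2$upper)$N, 500)
  expect_lte(ah2$tau, 1e4)

  # condition (2): with many significant states the target doubles
  seeds <- as.matrix(expand.grid(M = 140:159, P = 350:364))  # 300 states
  ah3 <- adaptive_horizon(ge, seeds, min_window = 1, horizon = 1e4,
                          n_significant = 300)
  expect_gte(enumerate_window(ah3$lower, ah3$upper)$N, 600)
})

test_that("branch bounds contain the sampled jump process", {
  cases <- list(
    list(net = toy_enzyme(20, 10), z = c(20, 10, 0, 0), tau = 0.1, n = 10000),
    list(net = cme_example("gene_expression", "a"), z = c(0, 0), tau = 20, n = 2000),
    list(net = cme_example("toggle_switch"), z = c(10, 10), tau = 50, n = 2000))
  for (cs in cases) {
    b <- cont_det_approx(cs$net, cs$z, cs$tau)
    esc <- ssa_escape(cs$net, cs$z, cs$tau, cs$n, b$lower, b$upper, seed = 42)
    expect_lt(esc[["outside"]] / esc[["total"]], 0.05)
  }
})
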