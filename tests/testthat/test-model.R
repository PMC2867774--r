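test_that("mass-action propensities count reactant combinations", {
  net <- cme_example("enzyme", "a")
  expect_equal(mass_action_propensity(net$reactions[[1]], c(10, 10, 100, 0)), 100)
  # dimerization: c * C(x, 2)
  dim2 <- cme_network(c("M", "D"), c(4, 0),
                      list(mass_action_reaction("2 M", "D", 2, c("M", "D"))))
  expect_equal(mass_action_propensity(dim2$reactions[[1]], c(4, 0)), 12)
  # no reactant present
  expect_equal(mass_action_propensity(net$reactions[[2]], c(10, 10, 0, 0)), 0)
  # falling-factorial extension at real states, clamped at 0
  expect_equal(mass_action_propensity(dim2$reactions[[1]], c(0.5, 0)), 0)
  expect_equal(mass_action_propensity(dim2$reactions[[1]], c(2.5, 0)),
               2 * 2.5 * 1.5 / 2)
  expect_error(reaction(c(-1, 1), rate = -2), "invalid model")
})

test_that("propensity is zero whenever a reactant count is zero, in every packaged model", {
  for (nm in c("enzyme", "gene_expression", "toggle_switch")) {
    net <- cme_example(nm, "a")
    for (m in seq_len(net$k)) {
      r <- net$reactions[[m]]
      consumed <- which(r$change < 0)
      for (d in consumed) {
        x <- pmax(net$init, 5)
        x[d] <- 0
        a <- propensities(net, x)[m]
        # a reaction lacking one of its consumed species cannot fire
        expect_equal(a * (is.null(r$propensity)), 0)
        expect_true(x[d] + r$change[d] < 0 || a >= 0)
      }
    }
  }
})

test_that("mass-action propensity is monotone in each reactant count", {
  net <- cme_example("enzyme", "b")
  for (m in seq_len(net$k)) {
    r <- net$reactions[[m]]
    for (d in seq_len(net$n)) {
      x <- c(3, 4, 5, 6)
      vals <- vapply(0:10, function(v) { x[d] <- v; mass_action_propensity(r, x) },
                     numeric(1))
      expect_true(all(diff(vals) >= 0))
    }
  }
})

test_that("exit rate sums all propensities", {
  net <- enzyme_net(1000, 100, rates = c(1, 1, 1))
  expect_equal(exit_rate(net, c(10, 10, 100, 0)), 300)
  ge <- cme_example("gene_expression", "a")
  expect_equal(exit_rate(ge, c(0, 0)), 0.5)
  dec <- decay_net()
  expect_equal(exit_rate(dec, 0), 0)   # absorbing
})

test_that("apply_reaction adds the change vector and enforces positivity", {
  net <- cme_example("enzyme", "a")
  expect_equal(apply_reaction(c(10, 10, 100, 0), net$reactions[[3]]), c(11, 10, 99, 1))
  expect_equal(apply_reaction(c(1, 1, 0, 0), net$reactions[[1]]), c(0, 0, 1, 0))
  ge <- cme_example("gene_expression", "a")
  expect_equal(apply_reaction(c(0, 0), ge$reactions[[1]]), c(1, 0))
  expect_error(apply_reaction(c(0, 0, 0, 0), net$reactions[[1]]), "contract violation")
})

test_that("conservation laws span the integer left null space", {
  laws <- conservation_laws(cme_example("enzyme", "a"))
  expect_length(laws, 2)
  B <- do.call(cbind, lapply(laws, `[[`, "coefficients"))
  # same span as {x1+x3, x2+x3+x4}
  ref <- cbind(c(1, 0, 1, 0), c(0, 1, 1, 1))
  expect_equal(qr(cbind(B, ref))$rank, 2)
  expect_equal(vapply(laws, `[[`, numeric(1), "constant"),
               as.numeric(crossprod(B, c(1000, 100, 0, 0))))

  expect_length(conservation_laws(cme_example("gene_expression", "a")), 0)

  n2 <- cme_network(c("A", "B"), c(4, 0),
                    list(mass_action_reaction("2 A", "B", 1, c("A", "B"))))
  expect_equal(conservation_laws(n2)[[1]]$coefficients, c(1, 2))
})

test_that("law coefficients are orthogonal to every change vector (all packaged models)", {
  nets <- list(cme_example("enzyme", "a"), cme_example("enzyme", "b"),
               cme_example("gene_expression", "b"), cme_example("toggle_switch"),
               cme_example("goutsias", rates = rep(1, 10), init = c(2, 6, 0, 2, 0, 0)))
  for (net in nets) {
    laws <- conservation_laws(net)
    for (l in laws)
      for (r in net$reactions)
        expect_identical(sum(l$coefficients * r$change), 0)
  }
  # the transcription-regulation structure conserves total promoter copies
  gout <- nets[[5]]
  laws <- gout |> conservation_laws()
  expect_length(laws, 1)
  expect_equal(abs(laws[[1]]$coefficients), c(0, 0, 0, 1, 1, 1))
})

test_that("packaged examples carry the printed parameters", {
  a <- cme_example("enzyme", "a")
  expect_equal(a$k, 3); expect_equal(a$n, 4)
  expect_equal(a$init, c(1000, 100, 0, 0))
  expect_equal(vapply(a$reactions, `[[`, numeric(1), "rate"), c(1, 1, 0.1))
  expect_equal(cme_example("enzyme", "b")$init, c(100, 1000, 0, 0))
  expect_equal(cme_example("enzyme", "c")$init, c(500, 500, 0, 0))

  ga <- cme_example("gene_expression", "a")
  expect_equal(ga$init, c(0, 0))
  expect_equal(ga$reactions[[1]]$rate, 0.5)
  expect_equal(cme_example("gene_expression", "b")$init, c(100, 1000))

  ts <- cme_example("toggle_switch")
  expect_equal(propensities(ts, c(0, 0))[1], 3000 / 11000)
  expect_equal(propensities(ts, c(0, 10))[1], 3000 / (11000 + 100))

  expect_error(cme_example("nonexistent"), "arg")
  expect_error(cme_example("goutsias"), "missing parameter")
  expect_equal(cme_example("goutsias", rates = rep(1, 10),
                           init = c(2, 6, 0, 2, 0, 0))$k, 10)
})
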