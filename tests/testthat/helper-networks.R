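# Small fixture networks and a direct jump-process sampler, built in code.

enzyme_species <- c("E", "S", "ES", "P")

enzyme_net <- function(E, S, rates = c(1, 1, 0.1), branches = NULL) {
  cme_network(enzyme_species, c(E, S, 0, 0),
              list(mass_action_reaction("E + S", "ES", rates[1], enzyme_species, "R1"),
                   mass_action_reaction("ES", "E + S", rates[2], enzyme_species, "R2"),
                   mass_action_reaction("ES", "E + P", rates[3], enzyme_species, "R3")),
              branches = branches, name = sprintf("enzyme_%d_%d", E, S))
}

# toy enzyme with the curated branch list of the packaged model
toy_enzyme <- function(E = 20, S = 5, rates = c(1, 1, 0.1))
  enzyme_net(E, S, rates, branches = cme_example("enzyme", "a")$branches)

decay_net <- function(rate = 1)
  cme_network("A", 1, list(mass_action_reaction("A", "0", rate, "A")), name = "decay")

birth_net <- function(rate = 1)
  cme_network("A", 0, list(mass_action_reaction("0", "A", rate, "A")), name = "birth")

birth_death_net <- function(b = 1, d = 1)
  cme_network("A", 0, list(mass_action_reaction("0", "A", b, "A"),
                           mass_action_reaction("A", "0", d, "A")), name = "bd")

# direct sampling of the jump process (test oracle only): simulates n
# trajectories from z over [0, tau] and counts visited states that fall
# outside the box [lower, upper]
ssa_escape <- function(network, z, tau, n, lower, upper, seed = 1) {
  set.seed(seed)
  V <- do.call(rbind, lapply(network$reactions, `[[`, "change"))
  X <- matrix(rep(as.numeric(z), each = n), n)
  tcur <- numeric(n)
  active <- rep(TRUE, n)
  outside <- 0L; total <- n
  while (any(active)) {
    idx <- which(active)
    A <- propensities(network, X[idx, , drop = FALSE])
    if (!is.matrix(A)) A <- matrix(A, nrow = length(idx))
    lam <- rowSums(A)
    dead <- lam <= 0
    active[idx[dead]] <- FALSE
    idx <- idx[!dead]
    if (!length(idx)) break
    A <- A[!dead, , drop = FALSE]; lam <- lam[!dead]
    tcur[idx] <- tcur[idx] + stats::rexp(length(idx), lam)
    fin <- tcur[idx] > tau
    active[idx[fin]] <- FALSE
    idx <- idx[!fin]
    if (!length(idx)) next
    A <- A[!fin, , drop = FALSE]; lam <- lam[!fin]
    u <- stats::runif(length(idx)) * lam
    pick <- max.col((t(apply(A, 1L, cumsum)) >= u) * 1, "first")
    X[idx, ] <- X[idx, , drop = FALSE] + V[pick, , drop = FALSE]
    esc <- rowSums(t(t(X[idx, , drop = FALSE]) < lower) |
                     t(t(X[idx, , drop = FALSE]) > upper)) > 0
    outside <- outside + sum(esc)
    total <- total + length(idx)
  }
  c(outside = outside, total = total)
}
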