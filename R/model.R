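# Reaction-network model objects: reactions with change vectors and
# propensity functions, mass-action kinetics, conservation laws, and the
# packaged example networks.

#' Create a reaction
#'
#' A reaction is described by its net change vector \eqn{v} (one entry per
#' species) and a propensity function \eqn{\alpha(x)} giving its firing rate
#' in population state \eqn{x}. Mass-action reactions are specified by a rate
#' constant and reactant multiplicities, in which case
#' \eqn{\alpha(x) = c \prod_i \binom{x_i}{l_i}} (the number of distinct
#' reactant combinations times the constant). Non-mass-action kinetics
#' (e.g. Hill functions) are supplied as an R function or expression.
#'
#' @param change integer vector, net change per species caused by one firing.
#' @param rate positive rate constant (mass-action only).
#' @param reactants non-negative integer vector of reactant multiplicities
#'   \eqn{l_i} (mass-action only). Defaults to the negative part of `change`,
#'   which is correct for elementary reactions without catalysts.
#' @param propensity custom propensity: a function taking a numeric matrix of
#'   states (one row per state) and returning a vector of non-negative rates,
#'   or an expression/quoted call over species names.
#' @param species character vector of species names (needed to evaluate
#'   expression propensities).
#' @param name optional label.
#' @return an object of class `cme_reaction`.
#' @export
reaction <- function(change, rate = NULL, reactants = NULL, propensity = NULL,
                     species = NULL, name = "") {
  change <- as.numeric(change)
  n <- length(change)
  if (is.null(propensity)) {
    if (is.null(rate)) stop("either 'rate' (mass action) or 'propensity' must be given")
    if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
      stop("invalid model: mass-action rate constant must be a non-negative number")
    if (is.null(reactants)) reactants <- pmax(-change, 0)
    reactants <- as.numeric(reactants)
    if (length(reactants) != n || any(reactants < 0) || any(reactants != floor(reactants)))
      stop("invalid model: reactant multiplicities must be non-negative integers")
    r <- structure(list(change = change, rate = rate, reactants = reactants,
                        propensity = NULL, expr = NULL, name = name),
                   class = "cme_reaction")
  } else {
    expr <- NULL
    if (is.language(propensity)) {
      expr <- propensity
      if (is.null(species)) stop("'species' names are required for expression propensities")
      fun <- local({
        e <- expr; sp <- species
        function(X) {
          env <- as.list(as.data.frame(X, col.names = sp))
          names(env) <- sp
          val <- eval(e, envir = env, enclos = baseenv())
          rep_len(as.numeric(val), nrow(X))
        }
      })
    } else if (is.function(propensity)) {
      fun <- propensity
    } else stop("'propensity' must be a function or an expression")
    r <- structure(list(change = change, rate = rate, reactants = NULL,
                        propensity = fun, expr = expr, name = name),
                   class = "cme_reaction")
  }
  r
}

#' @export
print.cme_reaction <- function(x, ...) {
  kind <- if (is.null(x$propensity)) sprintf("mass action, c = %g", x$rate) else "custom propensity"
  cat(sprintf("<reaction %s: change (%s); %s>\n", x$name,
              paste(x$change, collapse = ", "), kind))
  invisible(x)
}

# falling-factorial binomial C(x, l) extended to real x:
# x(x-1)...(x-l+1)/l!, clamped to 0 when negative. Vectorised in x.
falling_binomial <- function(x, l) {
  if (l == 0) return(rep_len(1, length(x)))
  out <- rep_len(1, length(x))
  for (i in seq_len(l) - 1L) out <- out * (x - i)
  out <- out / factorial(l)
  pmax(out, 0)
}

#' Mass-action propensity of a reaction
#'
#' Evaluates \eqn{\alpha(x) = c \prod_i \binom{x_i}{l_i}} at one state or at a
#' matrix of states (one row each). Real-valued states are allowed: the
#' binomial coefficient is extended as the falling-factorial polynomial
#' \eqn{x(x-1)\cdots(x-l+1)/l!} clamped to zero when negative, which is what
#' the continuous deterministic window iteration evaluates.
#'
#' @param reaction a `cme_reaction` (mass-action).
#' @param state numeric vector (one state) or matrix (one state per row).
#' @return non-negative rate(s).
#' @export
mass_action_propensity <- function(reaction, state) {
  if (is.null(reaction$rate)) stop("reaction has a custom propensity, not mass action")
  X <- if (is.matrix(state)) state else matrix(state, nrow = 1L)
  out <- rep_len(reaction$rate, nrow(X))
  l <- reaction$reactants
  for (i in seq_along(l)) if (l[i] > 0) out <- out * falling_binomial(X[, i], l[i])
  if (is.matrix(state)) out else out[[1L]]
}

eval_propensity <- function(reaction, X) {
  if (is.null(reaction$propensity)) mass_action_propensity(reaction, X)
  else {
    v <- reaction$propensity(X)
    if (any(v < 0)) stop("custom propensity evaluated to a negative rate")
    v
  }
}

#' Create a reaction network
#'
#' @param species character vector of species names; all state vectors use
#'   this declaration order.
#' @param init non-negative integer vector of initial molecule counts.
#' @param reactions list of [reaction()] objects, all with change vectors of
#'   length `length(species)`.
#' @param branches optional list of [branch_spec()] objects attached to the
#'   model (used by the window construction in place of the automatic rule).
#' @param name optional model name.
#' @return an object of class `cme_network`.
#' @export
cme_network <- function(species, init, reactions, branches = NULL, name = "") {
  species <- as.character(species)
  n <- length(species)
  if (n == 0L) stop("invalid model: no species")
  init <- as.numeric(init)
  if (length(init) != n || any(init < 0) || any(init != floor(init)))
    stop("invalid model: initial state must be non-negative integers, one per species")
  if (!length(reactions)) stop("invalid model: no reactions")
  for (r in reactions) {
    if (!inherits(r, "cme_reaction")) stop("'reactions' must be a list of reaction() objects")
    if (length(r$change) != n) stop("invalid model: change vector length != number of species")
  }
  structure(list(species = species, n = n, init = init,
                 reactions = reactions, k = length(reactions),
                 branches = branches, name = name),
            class = "cme_network")
}

#' @export
print.cme_network <- function(x, ...) {
  cat(sprintf("Reaction network%s: %d species (%s), %d reactions\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              x$n, paste(x$species, collapse = ", "), x$k))
  cat("initial state:", paste(x$init, collapse = " "), "\n")
  laws <- conservation_laws(x)
  if (length(laws))
    for (l in laws)
      cat("conservation law:",
          paste(sprintf("%+d*%s", l$coefficients[l$coefficients != 0],
                        x$species[l$coefficients != 0]), collapse = " "),
          "=", l$constant, "\n")
  invisible(x)
}

#' Propensities of all reactions at one or more states
#'
#' @param network a `cme_network`.
#' @param state numeric vector or matrix of states (rows).
#' @return a vector of length `k` (single state) or an m-by-k matrix.
#' @export
propensities <- function(network, state) {
  X <- if (is.matrix(state)) state else matrix(state, nrow = 1L)
  A <- vapply(network$reactions, function(r) eval_propensity(r, X), numeric(nrow(X)))
  A <- matrix(A, nrow = nrow(X))
  if (is.matrix(state)) A else A[1L, ]
}

#' Exit rate of a state
#'
#' The total rate \eqn{\lambda_x = \sum_m \alpha_m(x)} of leaving state x;
#' its reciprocal is the mean residence time. Zero exit rate marks an
#' absorbing state.
#'
#' @inheritParams propensities
#' @return non-negative rate(s).
#' @export
exit_rate <- function(network, state) {
  A <- propensities(network, if (is.matrix(state)) state else matrix(state, nrow = 1L))
  s <- rowSums(A)
  if (is.matrix(state)) s else s[[1L]]
}

#' Apply one reaction to a state
#'
#' @param state integer state vector.
#' @param reaction a `cme_reaction` with positive propensity at `state`.
#' @return the successor state `state + change`.
#' @export
apply_reaction <- function(state, reaction) {
  a <- eval_propensity(reaction, matrix(state, nrow = 1L))
  if (a <= 0) stop("contract violation: reaction propensity is zero at this state")
  state + reaction$change
}

# exact integer null space of {a : M a = 0} for a small integer matrix M
# (rows are change vectors). Fraction-free Gauss-Jordan elimination; columns
# of the returned matrix are primitive integer basis vectors.
int_nullspace <- function(M) {
  n <- ncol(M)
  M <- M[rowSums(abs(M)) > 0, , drop = FALSE]
  if (nrow(M) == 0L) return(diag(1, n))
  A <- M
  pivot_rows <- integer(0); pivot_cols <- integer(0)
  row <- 1L
  gcd2 <- function(a, b) { a <- abs(a); b <- abs(b); while (b > 0) { t <- a %% b; a <- b; b <- t }; a }
  vgcd <- function(v) { g <- 0; for (x in v) g <- gcd2(g, x); if (g == 0) 1 else g }
  for (col in seq_len(n)) {
    if (row > nrow(A)) break
    p <- which(A[row:nrow(A), col] != 0)
    if (!length(p)) next
    p <- p[1L] + row - 1L
    if (p != row) A[c(row, p), ] <- A[c(p, row), ]
    # eliminate this column from every other row, staying in integers
    for (i in seq_len(nrow(A))) {
      if (i == row || A[i, col] == 0) next
      A[i, ] <- A[i, ] * A[row, col] - A[row, ] * A[i, col]
      g <- vgcd(A[i, ])
      A[i, ] <- A[i, ] / g
    }
    pivot_rows <- c(pivot_rows, row); pivot_cols <- c(pivot_cols, col)
    row <- row + 1L
  }
  free_cols <- setdiff(seq_len(n), pivot_cols)
  if (!length(free_cols)) return(matrix(0, n, 0))
  basis <- matrix(0, n, length(free_cols))
  for (j in seq_along(free_cols)) {
    f <- free_cols[j]
    x <- numeric(n)
    # scale the free variable so all pivot solutions are integral
    L <- 1
    for (r in pivot_rows) L <- L * A[r, pivot_cols[match(r, pivot_rows)]] / gcd2(L, A[r, pivot_cols[match(r, pivot_rows)]])
    L <- abs(L)
    x[f] <- L
    for (idx in seq_along(pivot_rows)) {
      r <- pivot_rows[idx]; pc <- pivot_cols[idx]
      x[pc] <- -A[r, f] * L / A[r, pc]
    }
    g <- vgcd(x)
    x <- x / g
    fz <- which(x != 0)[1L]
    if (x[fz] < 0) x <- -x
    basis[, j] <- x
  }
  basis
}

#' Conservation laws of a network
#'
#' Finds an integer basis of the left null space of the stoichiometric
#' matrix: vectors \eqn{a} with \eqn{a \cdot v^{(m)} = 0} for every reaction,
#' so \eqn{a \cdot x} is invariant along every trajectory. Each law is paired
#' with its value at the initial state. Conservation laws make otherwise
#' box-shaped windows consistent with reachability (e.g. the enzyme system's
#' total-enzyme and total-substrate invariants).
#'
#' @param network a `cme_network`.
#' @return a list of objects of class `conservation_law`, each with fields
#'   `coefficients` (integer vector) and `constant` (its value at the initial
#'   state); empty list if the null space is trivial.
#' @export
conservation_laws <- function(network) {
  V <- do.call(rbind, lapply(network$reactions, `[[`, "change"))
  B <- int_nullspace(V)
  lapply(seq_len(ncol(B)), function(j) {
    coef <- B[, j]
    structure(list(coefficients = coef,
                   constant = sum(coef * network$init)),
              class = "conservation_law")
  })
}

# parse "E + S", "2 M", "0" into a multiplicity vector over species
parse_side <- function(txt, species, where = "") {
  counts <- stats::setNames(numeric(length(species)), species)
  txt <- trimws(txt)
  if (txt == "" || txt == "0") return(counts)
  for (term in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
    m <- regmatches(term, regexec("^([0-9]+)?\\s*([A-Za-z_.][A-Za-z0-9_.]*)$", term))[[1]]
    if (length(m) == 0L) stop(sprintf("parse error%s: cannot read reactant term '%s'", where, term))
    cnt <- if (m[2] == "") 1 else as.numeric(m[2])
    sp <- m[3]
    if (!sp %in% species) stop(sprintf("parse error%s: undeclared species '%s'", where, sp))
    counts[sp] <- counts[sp] + cnt
  }
  counts
}

#' Build a mass-action reaction from reactant and product strings
#'
#' @param lhs,rhs strings like `"E + S"`, `"2 M"`, or `"0"` for nothing.
#' @param rate rate constant.
#' @param species character vector of species names.
#' @param name optional label.
#' @export
mass_action_reaction <- function(lhs, rhs, rate, species, name = "") {
  l <- parse_side(lhs, species)
  p <- parse_side(rhs, species)
  reaction(change = unname(p - l), rate = rate, reactants = unname(l), name = name)
}

#' Packaged example networks
#'
#' Returns one of four stochastic-kinetics models used throughout the
#' package's tests and documentation:
#' \describe{
#'   \item{`enzyme`}{Enzyme-catalysed substrate conversion
#'     \eqn{E+S \to ES \to E+S | E+P} (4 species, 3 reactions, finite state
#'     space via two conservation laws). Parameter sets: `"a"` has
#'     \eqn{c = (1, 1, 0.1)} and initial state (1000, 100, 0, 0); `"b"` has
#'     \eqn{c = (1,1,1)} with (100, 1000, 0, 0); `"c"` has \eqn{c=(1,1,1)}
#'     with (500, 500, 0, 0).}
#'   \item{`gene_expression`}{Transcription/translation with degradation
#'     (mRNA M and protein P; infinite state space). Rates
#'     \eqn{c = (0.5, 0.0058, 0.0029, 10^{-4})}; set `"a"` starts empty,
#'     `"b"` at (100, 1000).}
#'   \item{`toggle_switch`}{Bistable switch of two mutually repressing
#'     proteins with Hill-type production propensities
#'     \eqn{\alpha_1(x) = c_1/(c_2 + x_2^\beta)},
#'     \eqn{\alpha_3(x) = c_4/(c_5 + x_1^\gamma)},
#'     \eqn{c_1=c_4=3\times 10^3}, \eqn{c_2=c_5=1.1\times 10^4},
#'     \eqn{c_3=c_6=10^{-3}}, \eqn{\beta=\gamma=2}.}
#'   \item{`goutsias`}{The 10-reaction transcription-regulation network
#'     structure (6 species). Kinetic constants and the initial state are not
#'     part of the fixture and must be supplied via `rates` and `init`.}
#' }
#' The enzyme and gene-expression models carry curated window-construction
#' branch lists; the toggle switch uses the automatic sign rule (which
#' coincides with the obvious four branches).
#'
#' @param name one of `"enzyme"`, `"gene_expression"`, `"toggle_switch"`,
#'   `"goutsias"`.
#' @param pset parameter set label (`"a"`, `"b"`, `"c"` where applicable).
#' @param rates,init kinetic constants and initial state, required for
#'   `"goutsias"` only.
#' @return a `cme_network`.
#' @export
cme_example <- function(name = c("enzyme", "gene_expression", "toggle_switch", "goutsias"),
                        pset = "a", rates = NULL, init = NULL) {
  name <- match.arg(name)
  switch(name,
    enzyme = {
      sp <- c("E", "S", "ES", "P")
      par <- switch(pset,
        a = list(c = c(1, 1, 0.1), y = c(1000, 100, 0, 0)),
        b = list(c = c(1, 1, 1),   y = c(100, 1000, 0, 0)),
        c = list(c = c(1, 1, 1),   y = c(500, 500, 0, 0)),
        stop(sprintf("unknown parameter set '%s' for enzyme (use a, b or c)", pset)))
      rx <- list(
        mass_action_reaction("E + S", "ES", par$c[1], sp, "R1"),
        mass_action_reaction("ES", "E + S", par$c[2], sp, "R2"),
        mass_action_reaction("ES", "E + P", par$c[3], sp, "R3"))
      br <- list(
        branch_spec(c("MORE", "FEWER", "FEWER"), "max ES / min E"),
        branch_spec(c("FEWER", "MORE", "MORE"), "min ES / max E"),
        branch_spec(c("FEWER", "MORE", "FEWER"), "min P / max S"),
        branch_spec(c("MORE", "FEWER", "MORE"), "max P / min S"))
      cme_network(sp, par$y, rx, branches = br, name = paste0("enzyme_", pset))
    },
    gene_expression = {
      sp <- c("M", "P")
      y <- switch(pset, a = c(0, 0), b = c(100, 1000),
                  stop(sprintf("unknown parameter set '%s' for gene_expression (use a or b)", pset)))
      cc <- c(0.5, 0.0058, 0.0029, 1e-4)
      rx <- list(
        mass_action_reaction("0", "M", cc[1], sp, "R1"),
        mass_action_reaction("M", "M + P", cc[2], sp, "R2"),
        mass_action_reaction("M", "0", cc[3], sp, "R3"),
        mass_action_reaction("P", "0", cc[4], sp, "R4"))
      br <- list(
        branch_spec(c("MORE", "AVG", "FEWER", "AVG"), "max M"),
        branch_spec(c("FEWER", "AVG", "MORE", "AVG"), "min M"),
        branch_spec(c("MORE", "MORE", "FEWER", "FEWER"), "max P"),
        branch_spec(c("FEWER", "FEWER", "MORE", "MORE"), "min P"))
      cme_network(sp, y, rx, branches = br, name = paste0("gene_expression_", pset))
    },
    toggle_switch = {
      sp <- c("A", "B")
      c1 <- 3e3; c2 <- 1.1e4; c3 <- 1e-3; c4 <- 3e3; c5 <- 1.1e4; c6 <- 1e-3
      rx <- list(
        reaction(c(1, 0), propensity = bquote(.(c1) / (.(c2) + B^2)), species = sp, name = "R1"),
        mass_action_reaction("A", "0", c3, sp, "R2"),
        reaction(c(0, 1), propensity = bquote(.(c4) / (.(c5) + A^2)), species = sp, name = "R3"),
        mass_action_reaction("B", "0", c6, sp, "R4"))
      cme_network(sp, c(0, 0), rx, name = "toggle_switch")
    },
    goutsias = {
      sp <- c("M", "D", "RNA", "DNA", "DNA.D", "DNA.2D")
      if (is.null(rates) || is.null(init))
        stop("missing parameters: the Goutsias fixture ships structure only; ",
             "kinetic constants ('rates', length 10) and an initial state ('init') are required")
      if (length(rates) != 10L) stop("missing parameters: 'rates' must have length 10")
      rx <- list(
        mass_action_reaction("RNA", "RNA + M", rates[1], sp, "R1"),
        mass_action_reaction("M", "0", rates[2], sp, "R2"),
        mass_action_reaction("DNA.D", "RNA + DNA.D", rates[3], sp, "R3"),
        mass_action_reaction("RNA", "0", rates[4], sp, "R4"),
        mass_action_reaction("DNA + D", "DNA.D", rates[5], sp, "R5"),
        mass_action_reaction("DNA.D", "DNA + D", rates[6], sp, "R6"),
        mass_action_reaction("DNA.D + D", "DNA.2D", rates[7], sp, "R7"),
        mass_action_reaction("DNA.2D", "DNA.D + D", rates[8], sp, "R8"),
        mass_action_reaction("2 M", "D", rates[9], sp, "R9"),
        mass_action_reaction("D", "2 M", rates[10], sp, "R10"))
      cme_network(sp, init, rx, name = "goutsias")
    })
}

#' Names of the packaged example networks
#' @export
cme_examples <- function() c("enzyme", "gene_expression", "toggle_switch", "goutsias")
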