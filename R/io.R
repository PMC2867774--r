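# Model configuration files and distribution tables.
#
# Model grammar (one directive per line, '#' starts a comment):
#   name <label>                          optional
#   species <name> <initial count>        declaration order = vector order
#   reaction <lhs> -> <rhs> @ <rate>      mass action
#   reaction <lhs> -> <rhs> ; propensity = <expression>
#   branch <label> <mode> ... <mode>      one mode (MORE/FEWER/AVG) per reaction
# Sides are '+'-separated terms like "E + S", "2 M", or "0" for nothing.
# Expressions may use species names and arithmetic.

#' Read a reaction network from a model configuration file
#'
#' @param path file path.
#' @return a `cme_network`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  species <- character(0); init <- numeric(0)
  rx <- list(); brs <- list(); name <- ""
  rx_lines <- integer(0)
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    where <- sprintf(" at line %d", ln)
    parts <- strsplit(line, "\\s+")[[1]]
    key <- parts[1]
    if (key == "name") {
      name <- paste(parts[-1], collapse = " ")
    } else if (key == "species") {
      if (length(parts) != 3) stop(sprintf("parse error%s: expected 'species <name> <count>'", where))
      cnt <- suppressWarnings(as.numeric(parts[3]))
      if (is.na(cnt)) stop(sprintf("parse error%s: non-numeric initial count '%s'", where, parts[3]))
      species <- c(species, parts[2]); init <- c(init, cnt)
    } else if (key == "reaction") {
      body <- sub("^reaction\\s+", "", line)
      custom <- NULL
      if (grepl(";", body, fixed = TRUE)) {
        halves <- strsplit(body, ";", fixed = TRUE)[[1]]
        body <- trimws(halves[1])
        propdef <- trimws(paste(halves[-1], collapse = ";"))
        if (!grepl("^propensity\\s*=", propdef))
          stop(sprintf("parse error%s: expected 'propensity = <expression>'", where))
        custom <- sub("^propensity\\s*=\\s*", "", propdef)
      }
      arrow <- regmatches(body, regexec("^(.*)->(.*?)(@(.*))?$", body))[[1]]
      if (length(arrow) == 0) stop(sprintf("parse error%s: expected '<lhs> -> <rhs>'", where))
      lhs <- trimws(arrow[2]); rhs <- trimws(arrow[3]); rate_txt <- trimws(arrow[5])
      l <- parse_side(lhs, species, where); pr <- parse_side(rhs, species, where)
      if (!is.null(custom)) {
        expr <- tryCatch(str2lang(custom), error = function(e)
          stop(sprintf("parse error%s: bad expression '%s'", where, custom)))
        bad <- setdiff(all.vars(expr), species)
        if (length(bad))
          stop(sprintf("parse error%s: undeclared species '%s' in propensity", where, bad[1]))
        rx[[length(rx) + 1L]] <- reaction(unname(pr - l), propensity = expr,
                                          species = species,
                                          name = paste0("R", length(rx) + 1L))
      } else {
        if (!nzchar(rate_txt))
          stop(sprintf("parse error%s: mass-action reaction needs '@ <rate>'", where))
        rate <- suppressWarnings(as.numeric(rate_txt))
        if (is.na(rate)) stop(sprintf("parse error%s: non-numeric constant '%s'", where, rate_txt))
        rx[[length(rx) + 1L]] <- reaction(unname(pr - l), rate = rate, reactants = unname(l),
                                          name = paste0("R", length(rx) + 1L))
      }
      rx_lines <- c(rx_lines, ln)
    } else if (key == "branch") {
      if (length(parts) < 3) stop(sprintf("parse error%s: expected 'branch <label> <modes...>'", where))
      brs[[length(brs) + 1L]] <- branch_spec(parts[-(1:2)], parts[2])
    } else stop(sprintf("parse error%s: unknown directive '%s'", where, key))
  }
  if (!length(species)) stop("parse error: no species declared")
  if (!length(rx)) stop("parse error: no reactions declared")
  for (b in brs)
    if (length(b$modes) != length(rx))
      stop(sprintf("parse error: branch '%s' lists %d modes for %d reactions",
                   b$label, length(b$modes), length(rx)))
  net <- cme_network(species, init, rx, branches = if (length(brs)) brs else NULL,
                     name = name)
  # probe custom propensities for non-negativity on a grid around the start
  probes <- t(vapply(seq_len(100), function(i)
    pmax(round(net$init + (i - 50) / 10 * pmax(net$init, 10)), 0), numeric(net$n)))
  for (m in seq_len(net$k)) {
    r <- net$reactions[[m]]
    if (!is.null(r$propensity)) {
      vals <- r$propensity(probes)
      if (any(!is.finite(vals)) || any(vals < 0))
        stop(sprintf("parse error at line %d: propensity is negative or non-finite on probe states",
                     rx_lines[m]))
    }
  }
  net
}

#' Write a reaction network to a model configuration file
#'
#' @param network a `cme_network` (custom propensities must carry their
#'   defining expression, as parsed models and packaged examples do).
#' @param path file path.
#' @export
write_model <- function(network, path) {
  fmt_side <- function(counts) {
    nz <- which(counts > 0)
    if (!length(nz)) return("0")
    paste(vapply(nz, function(i)
      if (counts[i] == 1) network$species[i]
      else paste(counts[i], network$species[i]), character(1)), collapse = " + ")
  }
  lines <- character(0)
  if (nzchar(network$name)) lines <- c(lines, paste("name", network$name))
  lines <- c(lines, sprintf("species %s %.17g", network$species, network$init))
  for (r in network$reactions) {
    if (is.null(r$propensity)) {
      l <- r$reactants
      p <- r$change + l
      lines <- c(lines, sprintf("reaction %s -> %s @ %.17g",
                                fmt_side(l), fmt_side(p), r$rate))
    } else {
      if (is.null(r$expr))
        stop("cannot serialize a function propensity without its expression")
      l <- pmax(-r$change, 0); p <- r$change + l
      lines <- c(lines, sprintf("reaction %s -> %s ; propensity = %s",
                                fmt_side(l), fmt_side(p),
                                paste(deparse(r$expr), collapse = " ")))
    }
  }
  for (b in if (is.null(network$branches)) list() else network$branches)
    lines <- c(lines, paste("branch", gsub("\\s+", "_", b$label),
                            paste(b$modes, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a distribution as a tab-separated table
#'
#' One row per state in lexicographic order, one column per species plus a
#' `probability` column in full (17 significant digit) precision; the output
#' is byte-identical across runs with the same inputs.
#'
#' @param dist a `cme_dist`.
#' @param species column names for the state dimensions.
#' @param path file path.
#' @export
write_distribution <- function(dist, species, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(species, "probability"), collapse = "\t"), con)
  if (length(dist$p)) {
    rows <- apply(dist$states, 1L, function(s) paste(format(s, scientific = FALSE, trim = TRUE), collapse = "\t"))
    writeLines(paste(rows, sprintf("%.17g", dist$p), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a distribution written by [write_distribution()]
#' @param path file path.
#' @return a `cme_dist`; species names are attached as an attribute.
#' @export
read_distribution <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"probability" %in% names(df)) stop("not a distribution table: no 'probability' column")
  p <- df$probability
  X <- as.matrix(df[setdiff(names(df), "probability")])
  d <- cme_dist(X, p)
  attr(d, "species") <- setdiff(names(df), "probability")
  d
}
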