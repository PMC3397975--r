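#' Parse a reaction formula string
#'
#' Converts a chemical formula of the form `"<substrates> -> <products>"` into a
#' named vector of signed stoichiometric coefficients. Substrates (left-hand
#' side) receive negative coefficients, products positive ones, following the
#' convention that negative coefficients identify species consumed in the
#' forward direction of the reaction. Terms are separated by `+`; an optional
#' numeric coefficient may precede each species id (default 1). A species
#' appearing on both sides has its coefficients summed; if the sum is zero the
#' species is dropped with a warning. One side may be empty (pure sink or
#' source reactions, `"A -> "`), but a dangling `+` is a parse error.
#'
#' @param text A single formula string, e.g. `"GLC + ATP -> G6P + ADP"`.
#' @return A named numeric vector mapping species ids to signed coefficients.
#' @examples
#' parse_reaction_formula("GLC + ATP -> G6P + ADP")
#' parse_reaction_formula("2 H2O2 -> 2 H2O + O2")
#' @export
parse_reaction_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n_arrows <- lengths(regmatches(text, gregexpr("->", text, fixed = TRUE)))
  if (n_arrows != 1L) {
    abort(sprintf("malformed formula (expected exactly one '->'): '%s'", text),
          class = "fluxness_parse_error")
  }
  pos <- regexpr("->", text, fixed = TRUE)
  sides <- c(substr(text, 1, pos - 1), substr(text, pos + 2, nchar(text)))
  coef <- numeric(0)
  for (s in c(1L, 2L)) {
    side_sign <- if (s == 1L) -1 else 1
    # an entirely empty side is allowed: pure sink/source reactions are
    # written "A -> " / " -> B"; a dangling '+' term is still an error
    if (trimws(sides[s]) == "") next
    terms <- trimws(strsplit(sides[s], "+", fixed = TRUE)[[1]])
    for (term in terms) {
      if (term == "") {
        abort(sprintf("malformed formula (empty term near '+'): '%s'", text),
              class = "fluxness_parse_error")
      }
      m <- regmatches(term, regexec(
        "^(?:([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)[ \t]+)?([A-Za-z][A-Za-z0-9_]*)$",
        term))[[1]]
      if (length(m) == 0L) {
        abort(sprintf("malformed term '%s' in formula '%s'", term, text),
              class = "fluxness_parse_error")
      }
      k <- if (m[2] == "") 1 else as.numeric(m[2])
      id <- m[3]
      coef[id] <- (if (id %in% names(coef)) coef[[id]] else 0) + side_sign * k
    }
  }
  zero <- abs(coef) < .Machine$double.eps
  if (any(zero)) {
    warn(sprintf("species with net zero coefficient dropped: %s",
                 paste(names(coef)[zero], collapse = ", ")))
    coef <- coef[!zero]
  }
  coef
}

#' Render a stoichiometry map back to a formula string
#'
#' Inverse of [parse_reaction_formula()]: negative coefficients become the
#' substrate side, positive ones the product side. Coefficients equal to 1 are
#' omitted. `species_order`, when given, fixes the ordering of terms so that
#' write/read round trips are exact.
#'
#' @param stoich Named numeric vector of signed coefficients.
#' @param species_order Optional character vector used to order the terms.
#' @return A formula string.
#' @export
deparse_reaction_formula <- function(stoich, species_order = NULL) {
  if (!is.null(species_order)) {
    stoich <- stoich[order(match(names(stoich), species_order))]
  }
  fmt <- function(v) {
    paste(vapply(names(v), function(id) {
      k <- abs(v[[id]])
      if (isTRUE(all.equal(k, 1))) id else paste(format(k, digits = 15), id)
    }, character(1)), collapse = " + ")
  }
  paste(fmt(stoich[stoich < 0]), "->", fmt(stoich[stoich > 0]))
}

#' Construct a reaction network
#'
#' The central container of the package: an ordered species table (with
#' reference concentrations and boundary exchange rates) plus an ordered
#' reaction table (with sparse stoichiometry and flux bounds), describing an
#' open, well-mixed reactor of volume `volume` evolving in elementary steps of
#' size `dt`. The sign convention for exchange is that `u > 0` means net intake
#' of the species into the reactor, so that exact stationary mass balance for
#' species \eqn{\mu} reads \eqn{\sum_i \xi^\mu_i \nu_i + u^\mu = 0}.
#'
#' @param species Data frame with columns `id` (character), `cbar` (reference
#'   concentration, must be positive), `u` (boundary exchange rate; positive =
#'   intake) and `is_boundary` (logical; `u` must be 0 where `FALSE`).
#' @param reactions Data frame with columns `id`, `stoich` (list column of
#'   named numeric coefficient vectors, or a character column of formula
#'   strings which will be parsed) and `qmax` (positive flux bound).
#' @param volume Reactor volume (default 1; dimensionless mode).
#' @param dt Elementary time step (default 1).
#' @param validate Abort on invalid input? (default `TRUE`).
#' @return An object of class `reaction_network`.
#' @seealso [read_network()], [validate_network()], [stoich_matrix()]
#' @export
reaction_network <- function(species, reactions, volume = 1, dt = 1,
                             validate = TRUE) {
  species <- as_tibble(species)
  reactions <- as_tibble(reactions)
  if (is.character(reactions$stoich)) {
    reactions$stoich <- lapply(reactions$stoich, parse_reaction_formula)
  }
  species$id <- as.character(species$id)
  species$is_boundary <- as.logical(species$is_boundary)
  reactions$id <- as.character(reactions$id)
  net <- structure(
    list(species = species, reactions = reactions,
         volume = volume, dt = dt),
    class = "reaction_network")
  if (validate) {
    bad <- validate_network(net)
    bad <- bad[bad$severity == "error", ]
    if (nrow(bad) > 0L) {
      abort(paste0("invalid reaction network:\n",
                   paste0("  [", bad$code, "] ", bad$message, collapse = "\n")),
            class = "fluxness_validation_error")
    }
  }
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species x %d reactions (V = %g, dt = %g)\n",
              nrow(x$species), nrow(x$reactions), x$volume, x$dt))
  nb <- sum(x$species$is_boundary)
  cat(sprintf("  boundary species: %d; flux bounds in [%g, %g]\n",
              nb, min(x$reactions$qmax), max(x$reactions$qmax)))
  invisible(x)
}

#' Validate a reaction network
#'
#' Checks all type invariants and returns a tibble of diagnostics rather than
#' raising conditions. An empty result (no rows with severity `"error"`) means
#' the network is valid. Species that are not attached to any reaction and have
#' `u = 0` are reported as a `"note"`: they are retained but contribute nothing
#' to the coupling system.
#'
#' @param net A `reaction_network`.
#' @return Tibble with columns `code`, `severity`, `where`, `message`.
#' @export
validate_network <- function(net) {
  d <- list()
  add <- function(code, where, message, severity = "error") {
    d[[length(d) + 1L]] <<- tibble(code = code, severity = severity,
                                   where = where, message = message)
  }
  sp <- net$species; rx <- net$reactions
  if (anyDuplicated(sp$id)) {
    for (id in unique(sp$id[duplicated(sp$id)]))
      add("DUPLICATE_ID", id, sprintf("duplicate species id '%s'", id))
  }
  if (anyDuplicated(rx$id)) {
    for (id in unique(rx$id[duplicated(rx$id)]))
      add("DUPLICATE_ID", id, sprintf("duplicate reaction id '%s'", id))
  }
  for (i in seq_len(nrow(sp))) {
    if (!is.finite(sp$cbar[i]) || sp$cbar[i] <= 0)
      add("NONPOSITIVE_CBAR", sp$id[i],
          sprintf("species '%s' has non-positive reference concentration", sp$id[i]))
    if (!sp$is_boundary[i] && sp$u[i] != 0)
      add("BOUNDARY_FLAG", sp$id[i],
          sprintf("species '%s' has u != 0 but is_boundary is FALSE", sp$id[i]))
  }
  touched <- character(0)
  for (i in seq_len(nrow(rx))) {
    st <- rx$stoich[[i]]
    if (length(st) == 0L) {
      add("EMPTY_STOICH", rx$id[i],
          sprintf("reaction '%s' has empty stoichiometry", rx$id[i]))
      next
    }
    if (any(st == 0))
      add("ZERO_COEFFICIENT", rx$id[i],
          sprintf("reaction '%s' stores a zero coefficient", rx$id[i]))
    unknown <- setdiff(names(st), sp$id)
    for (id in unknown)
      add("UNKNOWN_SPECIES", rx$id[i],
          sprintf("reaction '%s' references undeclared species '%s'", rx$id[i], id))
    if (!is.finite(rx$qmax[i]) || rx$qmax[i] <= 0)
      add("NONPOSITIVE_QMAX", rx$id[i],
          sprintf("reaction '%s' has non-positive flux bound", rx$id[i]))
    touched <- union(touched, names(st))
  }
  idle <- setdiff(sp$id[!sp$is_boundary & sp$u == 0], touched)
  for (id in idle)
    add("ISOLATED_SPECIES", id,
        sprintf("species '%s' is attached to no reaction and has u = 0", id),
        severity = "note")
  if (length(d) == 0L) {
    tibble(code = character(0), severity = character(0),
           where = character(0), message = character(0))
  } else {
    dplyr::bind_rows(d)
  }
}

#' Read a reaction network from plain-text tables
#'
#' The species table is a tab-separated file with header
#' `id  cbar  u  is_boundary`; the reactions table has header
#' `id  formula  qmax`. Lines starting with `#` are comments. Ordering of
#' species and reactions follows file order.
#'
#' @param species_file,reactions_file Paths to the two TSV files.
#' @param volume,dt Reactor volume and elementary time step.
#' @return A validated `reaction_network`.
#' @export
read_network <- function(species_file, reactions_file, volume = 1, dt = 1) {
  sp <- utils::read.delim(species_file, comment.char = "#",
                          colClasses = c(id = "character"),
                          na.strings = character(0),
                          stringsAsFactors = FALSE)
  rx <- utils::read.delim(reactions_file, comment.char = "#",
                          colClasses = c(id = "character", formula = "character"),
                          na.strings = character(0),
                          stringsAsFactors = FALSE)
  need_sp <- c("id", "cbar", "u", "is_boundary")
  need_rx <- c("id", "formula", "qmax")
  if (!all(need_sp %in% names(sp)))
    abort(sprintf("species table must have columns: %s", paste(need_sp, collapse = ", ")))
  if (!all(need_rx %in% names(rx)))
    abort(sprintf("reactions table must have columns: %s", paste(need_rx, collapse = ", ")))
  sp$is_boundary <- as.logical(sp$is_boundary)
  reaction_network(
    species = tibble(id = sp$id, cbar = as.numeric(sp$cbar),
                     u = as.numeric(sp$u), is_boundary = sp$is_boundary),
    reactions = tibble(id = rx$id,
                       stoich = lapply(rx$formula, parse_reaction_formula),
                       qmax = as.numeric(rx$qmax)),
    volume = volume, dt = dt)
}

#' Write a reaction network to plain-text tables
#'
#' @param net A `reaction_network`.
#' @param species_file,reactions_file Output paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, species_file, reactions_file) {
  sp <- net$species
  sp_out <- data.frame(id = sp$id,
                       cbar = format(sp$cbar, digits = 15),
                       u = format(sp$u, digits = 15),
                       is_boundary = sp$is_boundary)
  utils::write.table(sp_out, species_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rx <- net$reactions
  rx_out <- data.frame(
    id = rx$id,
    formula = vapply(rx$stoich, deparse_reaction_formula, character(1),
                     species_order = sp$id),
    qmax = format(rx$qmax, digits = 15))
  utils::write.table(rx_out, reactions_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}

#' Dense stoichiometric matrix
#'
#' Materializes the sparse per-reaction stoichiometry as a dense species-major
#' matrix (rows = species, columns = reactions).
#'
#' @param net A `reaction_network`.
#' @return Numeric matrix of dimension M x N with dimnames.
#' @export
stoich_matrix <- function(net) {
  M <- nrow(net$species); N <- nrow(net$reactions)
  S <- matrix(0, M, N, dimnames = list(net$species$id, net$reactions$id))
  for (j in seq_len(N)) {
    st <- net$reactions$stoich[[j]]
    S[names(st), j] <- st
  }
  S
}

# Coerce a flux argument (bare numeric, named numeric, or a tibble with a
# `flux` column as returned by estimate_fluxes/tidy) to a plain numeric vector
# aligned with the reaction order of `net`.
as_flux_vector <- function(nu, net) {
  if (is.data.frame(nu)) {
    if (!"flux" %in% names(nu)) abort("flux table must have a 'flux' column")
    if ("reaction" %in% names(nu)) {
      nu <- setNames(nu$flux, nu$reaction)[net$reactions$id]
    } else {
      nu <- nu$flux
    }
  }
  nu <- as.numeric(nu)
  if (length(nu) != nrow(net$reactions))
    abort(sprintf("flux vector has length %d, expected %d",
                  length(nu), nrow(net$reactions)))
  nu
}
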