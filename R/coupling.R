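#' Build the Hebbian coupling system of a reaction network
#'
#' Constructs the quadratic form that stationary fluxes minimize. With
#' stoichiometric coefficients \eqn{\xi^\mu_i}, reference concentrations
#' \eqn{\bar c_\mu} and boundary exchange rates \eqn{u^\mu}, the couplings are
#' \deqn{J_{ij} = \sum_\mu \xi^\mu_i \xi^\mu_j / \bar c_\mu, \qquad
#'       h_i = \sum_\mu \xi^\mu_i u^\mu / \bar c_\mu,}
#' with constant term \eqn{\sum_\mu (u^\mu)^2/\bar c_\mu}, so that
#' \deqn{H(\nu) = \nu^T J \nu + 2 h^T \nu + \mathrm{const}
#'             = \sum_\mu \big(\sum_i \xi^\mu_i \nu_i + u^\mu\big)^2 / \bar c_\mu \ge 0.}
#' Two reactions are coupled exactly when they share a species; the coupling is
#' negative (cooperative) when one produces what the other consumes, positive
#' (competitive) when both produce or both consume it, and its magnitude grows
#' as the shared species becomes scarce. `J` is a Gram matrix and therefore
#' symmetric positive semidefinite.
#'
#' @param net A `reaction_network`.
#' @param rescale Optional positive factor multiplying `J`, `h` and the constant
#'   (used by the ensemble dynamics, where couplings are rescaled by `1/M`).
#' @return An object of class `coupling_system` with elements `J`, `h`, `const`,
#'   plus the dense stoichiometric matrix `S`, `cbar` and `u` for the
#'   residual-form evaluation of `H`.
#' @export
build_couplings <- function(net, rescale = 1) {
  S <- stoich_matrix(net)
  cbar <- net$species$cbar
  u <- net$species$u
  Sc <- S / cbar                        # rows scaled by 1/cbar
  J <- crossprod(S, Sc)                 # t(S) %*% (S / cbar)
  J <- (J + t(J)) / 2                   # enforce exact symmetry
  h <- drop(crossprod(Sc, u))
  cst <- sum(u^2 / cbar)
  structure(
    list(J = rescale * J, h = rescale * h, const = rescale * cst,
         S = S, cbar = cbar, u = u, rescale = rescale,
         species_id = net$species$id, reaction_id = net$reactions$id),
    class = "coupling_system")
}

#' @export
print.coupling_system <- function(x, ...) {
  cat(sprintf("<coupling_system> N = %d reactions, M = %d species, const = %g\n",
              nrow(x$J), length(x$cbar), x$const))
  invisible(x)
}

#' Per-species mass-balance residuals
#'
#' Computes \eqn{r_\mu = \sum_i \xi^\mu_i \nu_i + u^\mu} for each species and
#' reports whether the exact balance \eqn{r_\mu = 0} and the net-production
#' inequality \eqn{r_\mu \ge 0} (the Von Neumann-type condition, under which a
#' species may be produced but never over-consumed) hold.
#'
#' @param net A `reaction_network`.
#' @param nu Flux vector (numeric, or a tibble with a `flux` column), one entry
#'   per reaction in network order.
#' @param tol Absolute tolerance used for the `balanced` flag.
#' @return Tibble with columns `species`, `residual`, `balanced`, `nonnegative`.
#' @export
balance_residuals <- function(net, nu, tol = 1e-9) {
  nu <- as_flux_vector(nu, net)
  S <- stoich_matrix(net)
  r <- unname(drop(S %*% nu)) + net$species$u
  tibble(species = net$species$id, residual = r,
         balanced = abs(r) <= tol, nonnegative = r >= -tol)
}

#' Evaluate the variational function H
#'
#' `H` measures the total squared mass imbalance of a flux assignment, each
#' species weighted by its inverse reference concentration. It is zero exactly
#' at flux states satisfying stationary mass balance for every species, and
#' equals (up to units) the rate at which entropy production decays in the
#' corresponding steady state.
#'
#' For a `coupling_system` the explicit quadratic form is used; for a
#' `reaction_network` the concentration-weighted residual sum is used. The two
#' agree to machine precision.
#'
#' @param x A `coupling_system` or a `reaction_network`.
#' @param nu Flux vector (numeric or tibble with `flux` column).
#' @param ... Unused.
#' @return Scalar `H >= 0` (up to roundoff).
#' @export
hamiltonian <- function(x, nu, ...) UseMethod("hamiltonian")

#' @rdname hamiltonian
#' @export
hamiltonian.coupling_system <- function(x, nu, ...) {
  if (is.data.frame(nu)) nu <- nu$flux
  nu <- as.numeric(nu)
  if (length(nu) != nrow(x$J))
    abort(sprintf("flux vector has length %d, expected %d", length(nu), nrow(x$J)))
  drop(crossprod(nu, x$J %*% nu)) + 2 * sum(x$h * nu) + x$const
}

#' @rdname hamiltonian
#' @export
hamiltonian.reaction_network <- function(x, nu, ...) {
  nu <- as_flux_vector(nu, x)
  S <- stoich_matrix(x)
  r <- drop(S %*% nu) + x$species$u
  sum(r^2 / x$species$cbar)
}

#' Gradient of H
#'
#' \eqn{\nabla H(\nu) = 2 (J \nu + h)}; the downhill direction of the
#' stochastic dynamics' mean drift.
#'
#' @param cs A `coupling_system`.
#' @param nu Flux vector.
#' @return Numeric gradient vector of length N.
#' @export
hamiltonian_gradient <- function(cs, nu) {
  if (is.data.frame(nu)) nu <- nu$flux
  2 * (drop(cs$J %*% as.numeric(nu)) + cs$h)
}
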