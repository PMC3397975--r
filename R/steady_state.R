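# Direct characterization of the NESS as minimizers of H over the box of
# admissible fluxes, plus loop removal and the thermodynamic-feasibility
# certificate based on the Gordan alternative.

project_box <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Euclidean projection onto the probability simplex {k >= 0, sum k = 1}
# (sort-and-threshold algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Orthonormal basis of the null space of a matrix (full right singular
# vectors; singular values below rtol * max are treated as zero).
null_basis <- function(S, rtol = 1e-10) {
  N <- ncol(S)
  sv <- svd(S, nu = 0, nv = N)
  d <- sv$d
  rank <- sum(d > rtol * max(d, .Machine$double.eps))
  list(basis = sv$v[, seq_len(N) > rank, drop = FALSE], rank = rank,
       dimension = N - rank)
}

#' Minimize the variational function H over bounded fluxes
#'
#' Solves the box-constrained convex quadratic program
#' \deqn{\min_\nu H(\nu) \quad \text{s.t. } |\nu_i| \le q^{max}_i,}
#' whose solutions are the non-equilibrium steady states of the network.
#' Convexity (the coupling matrix is a Gram matrix) guarantees that any point
#' satisfying the KKT conditions is a global minimum. The solver is an
#' accelerated projected-gradient iteration followed by exact cyclic
#' coordinate-minimization sweeps to polish the active set; it is deterministic
#' given the starting point.
#'
#' @param net A `reaction_network`.
#' @param tol Convergence tolerance on the projected gradient (default
#'   `1e-10 * (1 + max|h|)`).
#' @param start Starting flux vector (default 0).
#' @param max_iter Iteration cap for the projected-gradient phase.
#' @return An object of class `minimization_result`: `nu` (named flux vector),
#'   `H_min`, `active_set` (reactions at a bound), `kkt_residual`,
#'   `iterations`, `converged`.
#' @export
minimize_hamiltonian <- function(net, tol = NULL, start = NULL,
                                 max_iter = 1e5) {
  cs <- build_couplings(net)
  N <- nrow(cs$J)
  q <- net$reactions$qmax
  lo <- -q; hi <- q
  if (is.null(tol)) tol <- 1e-10 * (1 + max(abs(cs$h)))
  stopifnot(tol > 0)
  x <- if (is.null(start)) numeric(N) else project_box(as_flux_vector(start, net), lo, hi)

  grad <- function(v) 2 * (drop(cs$J %*% v) + cs$h)
  kkt <- function(v) max(abs(v - project_box(v - grad(v), lo, hi)))

  L <- 2 * max(eigen(cs$J, symmetric = TRUE, only.values = TRUE)$values, 0)
  it <- 0L
  if (L > 0) {
    # FISTA with restart on objective increase
    z <- x; tk <- 1
    f_prev <- Inf
    for (it in seq_len(max_iter)) {
      x_new <- project_box(z - grad(z) / L, lo, hi)
      f_new <- hamiltonian(cs, x_new)
      if (f_new > f_prev + 1e-15) { z <- x; tk <- 1; next }  # restart
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- x_new + ((tk - 1) / t_new) * (x_new - x)
      x <- x_new; tk <- t_new; f_prev <- f_new
      if (it %% 25L == 0L && kkt(x) <= tol) break
    }
  }
  # exact coordinate-minimization polish (J_ii > 0 since stoich is non-empty)
  Jd <- diag(cs$J)
  for (sweep in seq_len(1000L)) {
    delta <- 0
    for (i in seq_len(N)) {
      gi <- 2 * (sum(cs$J[i, ] * x) + cs$h[i])
      xi <- min(max(x[i] - gi / (2 * Jd[i]), lo[i]), hi[i])
      delta <- max(delta, abs(xi - x[i]))
      x[i] <- xi
    }
    if (delta < 1e-15 || kkt(x) <= tol) break
  }
  res <- kkt(x)
  structure(
    list(nu = setNames(x, net$reactions$id),
         H_min = hamiltonian(cs, x),
         active_set = net$reactions$id[abs(abs(x) - q) <= 1e-9 * pmax(1, q)],
         kkt_residual = res, iterations = it,
         converged = res <= max(tol, 1e-8 * (1 + max(abs(cs$h))))),
    class = "minimization_result")
}

#' @export
print.minimization_result <- function(x, ...) {
  cat(sprintf("<minimization_result> N = %d, H_min = %.6g, kkt = %.2e, %d at bounds\n",
              length(x$nu), x$H_min, x$kkt_residual, length(x$active_set)))
  invisible(x)
}

#' Affine structure of the balanced-solution set
#'
#' When the minimum of H is (numerically) zero the network admits exactly
#' balanced steady states, and the set of balanced flux vectors is the affine
#' space `particular + null(S)` intersected with the flux box. This function
#' returns a particular solution and an orthonormal basis of the stoichiometric
#' null space; its dimension `N - rank(S)` counts the independent flux loops
#' and unconstrained pathway combinations — when it is positive, multiple
#' steady states coexist and ergodicity of the dynamics is lost.
#'
#' @param net A `reaction_network`.
#' @param eps_H Threshold on `H_min` below which the network counts as
#'   balanced (default `1e-9 * (1 + const)` with `const` the constant term of
#'   H).
#' @param result Optional precomputed [minimize_hamiltonian()] result.
#' @param rtol Relative singular-value tolerance for the rank decision.
#' @return An object of class `solution_space`: `balanced` flag, `particular`
#'   (named flux vector), `basis` (N x dimension orthonormal matrix),
#'   `dimension`, `rank`, `H_min`. When `H_min >= eps_H`, `balanced = FALSE`
#'   and no basis is returned.
#' @export
solution_space <- function(net, eps_H = NULL, result = NULL, rtol = 1e-10) {
  result <- result %||% minimize_hamiltonian(net)
  cs_const <- sum(net$species$u^2 / net$species$cbar)
  if (is.null(eps_H)) eps_H <- 1e-9 * (1 + cs_const)
  if (result$H_min >= eps_H) {
    return(structure(list(balanced = FALSE, H_min = result$H_min,
                          eps_H = eps_H, particular = NULL, basis = NULL,
                          dimension = NA_integer_, rank = NA_integer_),
                     class = "solution_space"))
  }
  nb <- null_basis(stoich_matrix(net), rtol = rtol)
  structure(list(balanced = TRUE, H_min = result$H_min, eps_H = eps_H,
                 particular = result$nu, basis = nb$basis,
                 dimension = nb$dimension, rank = nb$rank),
            class = "solution_space")
}

#' @export
print.solution_space <- function(x, ...) {
  if (x$balanced) {
    cat(sprintf("<solution_space> balanced; dimension = %d (rank %d)\n",
                x$dimension, x$rank))
  } else {
    cat(sprintf("<solution_space> no balanced solution (H_min = %.4g >= %.4g)\n",
                x$H_min, x$eps_H))
  }
  invisible(x)
}

#' Minimum-norm steady state (loop removal)
#'
#' Among all minimizers of H, returns the one of smallest Euclidean flux norm.
#' The minimizer set of the box-constrained quadratic is exactly
#' `(nu* + null(S))` intersected with the box (any two minimizers differ by a
#' stoichiometric null vector), so the problem is the projection of the origin
#' onto an affine-set/box intersection, computed by Dykstra's alternating
#' projections. Removing the null-space (loop) component leaves all
#' mass-balance residuals — hence H — unchanged, and the resulting flux vector
#' is free of thermodynamically infeasible cycles: a flux configuration
#' containing a cycle can always be shifted against it to reduce the norm.
#'
#' @param net A `reaction_network`.
#' @param result A [minimize_hamiltonian()] result (computed if missing).
#' @param tol Stopping tolerance on the iterates.
#' @param max_iter Iteration cap.
#' @return A `minimization_result` with the same `H_min` and the additional
#'   element `norm` (Euclidean norm of the returned fluxes).
#' @export
minimize_flux_norm <- function(net, result = NULL, tol = 1e-13,
                               max_iter = 2e5) {
  result <- result %||% minimize_hamiltonian(net)
  nu_star <- unname(result$nu)
  q <- net$reactions$qmax
  nb <- null_basis(stoich_matrix(net))
  if (nb$dimension == 0L) {
    out <- result
    out$norm <- sqrt(sum(nu_star^2))
    return(out)
  }
  Z <- nb$basis
  proj_aff <- function(v) nu_star + drop(Z %*% crossprod(Z, v - nu_star))
  x <- numeric(length(nu_star))
  p <- q_corr <- numeric(length(nu_star))
  for (it in seq_len(max_iter)) {
    y <- proj_aff(x + p)
    p <- x + p - y
    x_new <- project_box(y + q_corr, -q, q)
    q_corr <- y + q_corr - x_new
    if (max(abs(x_new - x)) < tol && max(abs(x_new - y)) < 1e-9) {
      x <- x_new
      break
    }
    x <- x_new
  }
  H_new <- hamiltonian(net, x)
  if (abs(H_new - result$H_min) > 1e-8 * (1 + result$H_min))
    warn("flux-norm minimization changed H beyond tolerance; result may be inaccurate")
  structure(
    list(nu = setNames(x, net$reactions$id), H_min = H_new,
         active_set = net$reactions$id[abs(abs(x) - q) <= 1e-9 * pmax(1, q)],
         kkt_residual = result$kkt_residual, iterations = it,
         converged = TRUE, norm = sqrt(sum(x^2))),
    class = "minimization_result")
}

#' Thermodynamic feasibility of a flux configuration (Gordan alternative)
#'
#' A steady-state flux configuration is thermodynamically feasible when
#' species potentials \eqn{g_\mu} exist that make every active reaction run
#' strictly downhill: \eqn{(\sum_\mu \xi^\mu_i g_\mu)\,\mathrm{sign}(\nu_i) < 0}
#' for every reaction with non-zero flux. By the Gordan theorem of
#' alternatives, exactly one of the following holds: such potentials exist, or
#' the configuration contains a stoichiometrically closed cycle — a flux-space
#' vector `k` with \eqn{\sum_i \xi^\mu_i k_i = 0} for every species and with
#' the signs of `k` matching those of `nu` on its support (an infeasible
#' loop).
#'
#' The search is cast as a minimum-norm-point problem over the convex hull of
#' the signed stoichiometric rows, solved by accelerated projected gradient on
#' the simplex: a strictly positive distance yields the separating potential
#' vector (normalized to unit sup-norm, satisfying the constraints with at
#' least the requested `margin`), a zero distance yields the simplex weights
#' of the cycle, which are then polished by exact projection onto the null
#' space of the supporting stoichiometric columns.
#'
#' @param net A `reaction_network`.
#' @param nu Flux vector; reactions with `|nu|` below `active_tol` are excluded
#'   from the constraints.
#' @param margin Strictness margin for the potential inequalities, relative to
#'   `|g|_inf = 1` (default 1e-6).
#' @param active_tol Threshold below which a flux counts as zero (default
#'   `1e-8 * max(1, |nu|_inf)`).
#' @param max_iter Iteration cap for the simplex solve.
#' @return An object of class `feasibility_certificate`: `feasible`,
#'   `potentials` (named by species; present iff feasible), `cycle` (named by
#'   reaction; present iff infeasible), `distance` (attained min-norm-point
#'   distance), `trivial` (all-zero input flux).
#' @export
check_thermo_feasibility <- function(net, nu, margin = 1e-6,
                                     active_tol = NULL, max_iter = 5e4) {
  stopifnot(margin > 0)
  nu <- as_flux_vector(nu, net)
  S <- stoich_matrix(net)
  if (is.null(active_tol)) active_tol <- 1e-8 * max(1, max(abs(nu)))
  active <- which(abs(nu) > active_tol)
  if (length(active) == 0L) {
    return(structure(list(feasible = TRUE, trivial = TRUE,
                          potentials = setNames(numeric(nrow(S)), rownames(S)),
                          cycle = NULL, distance = 0, active = integer(0)),
                     class = "feasibility_certificate"))
  }
  sgn <- sign(nu[active])
  A <- t(S[, active, drop = FALSE]) * sgn        # n_act x M signed rows
  rn <- sqrt(max(rowSums(A^2)))

  # min-norm point of conv(rows of A) via FISTA on the simplex
  n_act <- nrow(A)
  AAt <- A %*% t(A)
  L <- 2 * max(eigen(AAt, symmetric = TRUE, only.values = TRUE)$values, 1e-30)
  k <- rep(1 / n_act, n_act)
  fval <- function(k) { z <- drop(crossprod(A, k)); sum(z^2) }
  zk <- k; tk <- 1; f_prev <- fval(k)
  for (it in seq_len(max_iter)) {
    gr <- 2 * drop(AAt %*% zk)
    k_new <- project_simplex(zk - gr / L)
    f_new <- fval(k_new)
    if (f_new > f_prev + 1e-18) { zk <- k; tk <- 1; next }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zk <- k_new + ((tk - 1) / t_new) * (k_new - k)
    k <- k_new; tk <- t_new; f_prev <- f_new
    if (f_new < (1e-9 * rn)^2) break
    if (it %% 200L == 0L) {
      pg <- max(abs(k - project_simplex(k - 2 * drop(AAt %*% k) / L)))
      if (pg < 1e-14) break
    }
  }
  d <- sqrt(fval(k))

  if (d < 1e-5 * rn) {
    # cycle certificate: polish the simplex weights by exact projection onto
    # the null space of the supporting columns
    supp <- which(k > 1e-6 * max(k))
    cols <- active[supp]
    k_signed <- numeric(ncol(S))
    k_signed[cols] <- k[supp] * sgn[supp]
    nbs <- null_basis(S[, cols, drop = FALSE])
    if (nbs$dimension > 0L) {
      k_ref_sub <- drop(nbs$basis %*% crossprod(nbs$basis, k_signed[cols]))
      k_ref <- numeric(ncol(S)); k_ref[cols] <- k_ref_sub
      ok <- sqrt(sum((S %*% k_ref)^2)) <= 1e-8 * max(1, sqrt(sum(k_ref^2))) &&
        all(k_ref[cols] * sign(nu[cols]) >= -1e-10) &&
        max(abs(k_ref)) > 1e-10
      if (ok) {
        k_ref[cols][k_ref[cols] * sign(nu[cols]) < 0] <- 0
        k_ref <- k_ref / max(abs(k_ref))
        return(structure(list(feasible = FALSE, trivial = FALSE,
                              potentials = NULL,
                              cycle = setNames(k_ref, colnames(S)),
                              distance = d, active = active),
                         class = "feasibility_certificate"))
      }
    }
    # refinement failed: fall back on the raw weights
    k_raw <- k_signed / max(abs(k_signed))
    return(structure(list(feasible = FALSE, trivial = FALSE, potentials = NULL,
                          cycle = setNames(k_raw, colnames(S)),
                          distance = d, active = active, refined = FALSE),
                     class = "feasibility_certificate"))
  }

  z <- drop(crossprod(A, k))
  g <- -z / max(abs(z))
  # by min-norm-point duality, a_i . z >= |z|^2 > 0 for all rows, so g is
  # strictly separating; the margin is satisfied by a wide factor in practice
  structure(list(feasible = TRUE, trivial = FALSE,
                 potentials = setNames(g, rownames(S)), cycle = NULL,
                 distance = d, active = active,
                 margin_ok = all(drop(A %*% g) <= -margin)),
            class = "feasibility_certificate")
}

#' @export
print.feasibility_certificate <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("<feasibility_certificate> feasible%s (min-norm distance %.3g)\n",
                if (isTRUE(x$trivial)) " (trivial: zero flux)" else "", x$distance))
  } else {
    cat(sprintf("<feasibility_certificate> INFEASIBLE: cycle on %d reactions\n",
                sum(x$cycle != 0)))
  }
  invisible(x)
}
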