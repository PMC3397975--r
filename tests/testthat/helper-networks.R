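# Shared fixture constructors and independent oracles. Everything is built in
# code; no binary fixtures.

# two-species toy reactor: A (cbar 1, intake 2) -> B (cbar 2, outtake 2)
toy2_net <- function(qmax = 3) {
  reaction_network(
    species = tibble::tibble(id = c("A", "B"), cbar = c(1, 2), u = c(2, -2),
                             is_boundary = c(TRUE, TRUE)),
    reactions = tibble::tibble(id = "R1", stoich = "A -> B", qmax = qmax))
}

# closed 3-cycle A -> B -> C -> A (one stoichiometric loop)
cycle3_net <- function(qmax = 1) {
  reaction_network(
    species = tibble::tibble(id = c("A", "B", "C"), cbar = 1, u = 0,
                             is_boundary = FALSE),
    reactions = tibble::tibble(id = c("R1", "R2", "R3"),
                               stoich = c("A -> B", "B -> C", "C -> A"),
                               qmax = qmax))
}

# driven linear chain A -> B -> C with supply of A and drain of C
chain3_net <- function(u0 = 1, qmax = 2) {
  reaction_network(
    species = tibble::tibble(id = c("A", "B", "C"), cbar = 1,
                             u = c(u0, 0, -u0),
                             is_boundary = c(TRUE, FALSE, TRUE)),
    reactions = tibble::tibble(id = c("R1", "R2"),
                               stoich = c("A -> B", "B -> C"), qmax = qmax))
}

# single boundary species consumed by one reaction; mean-field fixed point
# tanh(y*) = u0 when |u0| < 1, frozen otherwise
one_reaction_net <- function(u0) {
  reaction_network(
    species = tibble::tibble(id = "A", cbar = 1, u = u0, is_boundary = TRUE),
    reactions = tibble::tibble(id = "R1", stoich = list(c(A = -1)), qmax = 1))
}

# small random network for property loops (thin wrapper over the ensemble
# sampler with non-default sizes)
small_random_net <- function(seed, M = 6, N = 3, p = 0.6, q = 0.5, b0 = 1,
                             qmax = 1) {
  spec <- ensemble_spec(M = M, p = p, q = q, b0 = b0)
  net <- sample_random_network(spec, seed = seed, n = N / M)
  net$reactions$qmax <- rep(qmax, nrow(net$reactions))
  net
}

# --- independent oracles -----------------------------------------------------

# nested refining grid search for box-constrained minimization of H, N <= 3;
# four refinement rounds of 21 points per axis reach (and pass) 1e-3 final
# resolution for qmax up to ~3, with a bracketing margin of one cell per round
grid_search_min <- function(net, points = 21, rounds = 4) {
  N <- nrow(net$reactions)
  stopifnot(N <= 3)
  lo <- -net$reactions$qmax
  hi <- net$reactions$qmax
  best <- NULL
  for (round in seq_len(rounds)) {
    axes <- lapply(seq_len(N), function(i) seq(lo[i], hi[i], length.out = points))
    grid <- as.matrix(expand.grid(axes))
    H <- apply(grid, 1, function(v) hamiltonian(net, v))
    k <- which.min(H)
    best <- list(nu = grid[k, ], H = H[k])
    step <- (hi - lo) / (points - 1)
    lo <- pmax(best$nu - step, -net$reactions$qmax)
    hi <- pmin(best$nu + step, net$reactions$qmax)
  }
  best
}

# deterministic mean-field iteration for the one-reaction reactor:
# y <- y - eta (tanh y - u0)
meanfield_one_reaction <- function(u0, eta = 0.5, steps = 5000, y0 = 0) {
  y <- y0
  for (t in seq_len(steps)) y <- y - eta * (tanh(y) - u0)
  list(y = y, flux = tanh(y))
}

# numeric 1-D minimizer for the red-cell g6pdh optimum: golden-section search
# polished by one exact parabolic step (H_ext is exactly quadratic in u6, so
# the polish reaches machine precision)
numeric_g6pdh_oracle <- function(u1, u2, env, hb) {
  f <- function(u6) extracellular_H(u1, u2, u6, env, hb)
  x <- optimize(f, interval = c(-10, 10), tol = 1e-10)$minimum
  h <- 1e-3
  f0 <- f(x - h); f1 <- f(x); f2 <- f(x + h)
  x + h * (f0 - f2) / (2 * (f0 - 2 * f1 + f2))
}

# independent linear-feasibility solve (perceptron-style) for the potential
# system (S' g) * sign(nu) <= -margin on active reactions; returns g or NULL
perceptron_potentials <- function(net, nu, margin = 1e-6, max_iter = 2e5) {
  S <- stoich_matrix(net)
  active <- which(abs(nu) > 1e-8 * max(1, max(abs(nu))))
  if (length(active) == 0) return(numeric(nrow(S)))
  A <- t(S[, active, drop = FALSE]) * sign(nu[active])
  g <- -colSums(A)
  for (it in seq_len(max_iter)) {
    v <- drop(A %*% g)
    worst <- which.max(v)
    if (v[worst] <= -margin * max(abs(g), 1e-12)) return(g)
    g <- g - A[worst, ]
  }
  NULL
}

# validate a feasibility certificate directly against its definition
certificate_valid <- function(net, nu, cert) {
  S <- stoich_matrix(net)
  active <- which(abs(nu) > 1e-8 * max(1, max(abs(nu))))
  if (cert$feasible) {
    if (length(active) == 0) return(TRUE)
    A <- t(S[, active, drop = FALSE]) * sign(nu[active])
    all(drop(A %*% cert$potentials) < 0)
  } else {
    k <- cert$cycle
    supp <- which(abs(k) > 1e-9)
    length(supp) > 0 &&
      sqrt(sum((S %*% k)^2)) <= 1e-6 * max(abs(k)) &&
      all(sign(k[supp]) == sign(nu[supp]))
  }
}
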