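test_that("the toy reactor minimizes where expected", {
  # wide box: exact balance attainable at nu = 2
  r1 <- minimize_hamiltonian(toy2_net(qmax = 3))
  expect_equal(unname(r1$nu), 2, tolerance = 1e-8)
  expect_equal(r1$H_min, 0, tolerance = 1e-12)
  # tight box: bound active at nu = 1, residual H = 1.5
  r2 <- minimize_hamiltonian(toy2_net(qmax = 1))
  expect_equal(unname(r2$nu), 1)
  expect_equal(r2$H_min, 1.5)
  expect_equal(r2$active_set, "R1")
  # closed system: zero flux is a minimizer
  net0 <- toy2_net(); net0$species$u <- c(0, 0)
  r3 <- minimize_hamiltonian(net0)
  expect_equal(unname(r3$nu), 0)
  expect_equal(r3$H_min, 0)
})

test_that("minimization matches refining grid search on small networks", {
  # 50 random instances with N <= 3; the nested grid reaches 1e-3 resolution
  for (seed in 1:50) {
    set.seed(seed)
    N <- sample(1:3, 1)
    net <- small_random_net(seed, M = 5, N = N, p = 0.7, q = 0.6,
                            qmax = sample(c(1, 2), 1))
    res <- minimize_hamiltonian(net)
    oracle <- grid_search_min(net)
    expect_lte(res$H_min, oracle$H + 1e-12)
    expect_lt(oracle$H - res$H_min, 1e-4 * (1 + abs(oracle$H)))
    expect_true(res$converged)
  }
})

test_that("KKT structure holds at the reported minimizer", {
  for (seed in 1:10) {
    net <- small_random_net(seed, M = 8, N = 5, p = 0.5, q = 0.5)
    res <- minimize_hamiltonian(net)
    cs <- build_couplings(net)
    g <- hamiltonian_gradient(cs, res$nu)
    q <- net$reactions$qmax
    interior <- abs(res$nu) < q - 1e-9
    expect_true(all(abs(g[interior]) < 1e-6))
    at_hi <- res$nu >= q - 1e-9
    at_lo <- res$nu <= -q + 1e-9
    expect_true(all(g[at_hi] <= 1e-6))
    expect_true(all(g[at_lo] >= -1e-6))
  }
})

test_that("solution space of the closed 3-cycle is the loop direction", {
  ss <- solution_space(cycle3_net())
  expect_true(ss$balanced)
  expect_equal(ss$dimension, 1L)
  b <- ss$basis[, 1]
  expect_equal(abs(b), rep(1 / sqrt(3), 3), tolerance = 1e-10)
  expect_equal(b[1], b[2])
  expect_equal(b[2], b[3])
  # single full-rank reaction: dimension 0
  ss2 <- solution_space(toy2_net())
  expect_true(ss2$balanced)
  expect_equal(ss2$dimension, 0L)
  # unbalanced network: explicit no-balanced-solution result
  ss3 <- solution_space(toy2_net(qmax = 1))
  expect_false(ss3$balanced)
})

test_that("solution-space dimension equals N - rank by an independent rank routine", {
  for (seed in 1:20) {
    net <- small_random_net(seed, M = 4, N = 6, p = 0.6, q = 0)
    ss <- solution_space(net)
    expect_true(ss$balanced)   # closed systems balance at nu = 0
    r_qr <- qr(stoich_matrix(net))$rank
    expect_equal(ss$dimension, ncol(stoich_matrix(net)) - r_qr)
    if (ss$dimension > 0) {
      expect_equal(crossprod(ss$basis), diag(ss$dimension), tolerance = 1e-10)
      expect_lt(max(abs(stoich_matrix(net) %*% ss$basis)), 1e-10)
    }
  }
})

test_that("flux-norm minimization removes pure loops and preserves driven flux", {
  net <- cycle3_net()
  seeded <- structure(list(nu = setNames(c(1, 1, 1), net$reactions$id),
                           H_min = 0, active_set = character(0),
                           kkt_residual = 0, iterations = 0, converged = TRUE),
                      class = "minimization_result")
  out <- minimize_flux_norm(net, seeded)
  expect_equal(unname(out$nu), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(out$H_min, 0, tolerance = 1e-12)

  # loop-free input is unchanged
  chain <- chain3_net()
  r <- minimize_hamiltonian(chain)
  out2 <- minimize_flux_norm(chain, r)
  expect_equal(out2$nu, r$nu, tolerance = 1e-9)

  # cycle superposed on a driven chain: cycle removed, chain flux preserved
  net3 <- reaction_network(
    species = tibble::tibble(id = c("A", "B", "C"), cbar = 1,
                             u = c(1, 0, -1), is_boundary = c(TRUE, FALSE, TRUE)),
    reactions = tibble::tibble(id = c("R1", "R2", "R3"),
                               stoich = c("A -> B", "B -> C", "C -> A"),
                               qmax = 2))
  start <- structure(list(nu = setNames(c(1.5, 1.5, 0.5), net3$reactions$id),
                          H_min = 0, active_set = character(0),
                          kkt_residual = 0, iterations = 0, converged = TRUE),
                     class = "minimization_result")
  expect_equal(hamiltonian(net3, start$nu), 0, tolerance = 1e-12)
  out3 <- minimize_flux_norm(net3, start)
  # orthogonal-decomposition oracle: subtract the mean (loop component)
  expect_equal(unname(out3$nu), c(1.5, 1.5, 0.5) - mean(c(1.5, 1.5, 0.5)),
               tolerance = 1e-8)
  expect_lte(out3$norm, sqrt(sum(start$nu^2)))
})

test_that("norm never increases and H never changes under loop removal", {
  for (seed in 1:20) {
    net <- small_random_net(seed, M = 4, N = 7, p = 0.6, q = 0.3, b0 = 0.3)
    r <- minimize_hamiltonian(net)
    out <- minimize_flux_norm(net, r)
    expect_lte(out$norm, sqrt(sum(r$nu^2)) + 1e-10)
    expect_lt(abs(out$H_min - r$H_min), 1e-8 * (1 + r$H_min))
    expect_true(all(abs(out$nu) <= net$reactions$qmax + 1e-9))
  }
})

test_that("the 3-cycle flux is certified infeasible with a telescoping cycle", {
  net <- cycle3_net()
  cert <- check_thermo_feasibility(net, c(1, 1, 1))
  expect_false(cert$feasible)
  expect_null(cert$potentials)
  k <- cert$cycle
  expect_true(all(k > 0))
  expect_lt(max(abs(stoich_matrix(net) %*% k)), 1e-6)
  expect_true(certificate_valid(net, c(1, 1, 1), cert))
})

test_that("a driven chain is feasible with decreasing potentials", {
  net <- chain3_net()
  cert <- check_thermo_feasibility(net, c(1, 1))
  expect_true(cert$feasible)
  g <- cert$potentials
  expect_gt(g[["A"]], g[["B"]])
  expect_gt(g[["B"]], g[["C"]])
  expect_true(certificate_valid(net, c(1, 1), cert))
  # independent perceptron solve agrees that potentials exist
  expect_false(is.null(perceptron_potentials(net, c(1, 1))))
  # degenerate zero flux: trivially feasible
  cert0 <- check_thermo_feasibility(net, c(0, 0))
  expect_true(cert0$feasible)
  expect_true(cert0$trivial)
})

test_that("exactly one Gordan certificate exists on random instances", {
  for (seed in 1:50) {
    net <- small_random_net(seed, M = 5, N = 6, p = 0.5, q = 0.4, b0 = 0.5)
    set.seed(seed + 900)
    nu <- round(runif(6, -1, 1), 2)
    cert <- check_thermo_feasibility(net, nu)
    expect_true(xor(is.null(cert$potentials), is.null(cert$cycle)))
    expect_true(certificate_valid(net, nu, cert))
  }
})

test_that("loop-removed steady states always pass the feasibility check", {
  for (seed in 1:15) {
    net <- small_random_net(seed, M = 4, N = 7, p = 0.6, q = 0.4, b0 = 0.3)
    out <- minimize_flux_norm(net)
    cert <- check_thermo_feasibility(net, out$nu)
    expect_true(cert$feasible)
    if (!isTRUE(cert$trivial)) {
      expect_false(is.null(perceptron_potentials(net, unname(out$nu))))
    }
  }
})

test_that("dynamics in the ergodic phase reproduces the direct minimizer", {
  spec <- ensemble_spec(M = 30, p = 0.25, q = 0.5)
  net <- sample_random_network(spec, seed = 31, n = 0.5)
  tr <- simulate_dynamics(net, steps = 5e4, eta = 0.1, seed = 32,
                          warn_clip = FALSE)
  nu_dyn <- estimate_fluxes(tr, net)$flux
  nu_min <- unname(minimize_hamiltonian(net)$nu)
  expect_lt(max(abs(nu_dyn - nu_min)), 0.05)
})
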