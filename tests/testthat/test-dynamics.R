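test_that("identical seeds give identical trajectories", {
  net <- small_random_net(1, M = 8, N = 6, p = 0.5, q = 0.5)
  a <- simulate_dynamics(net, steps = 2000, seed = 7)
  b <- simulate_dynamics(net, steps = 2000, seed = 7)
  expect_identical(a$y, b$y)
  expect_identical(a$m_mean, b$m_mean)
  expect_identical(a$msum_post, b$msum_post)
  c <- simulate_dynamics(net, steps = 2000, seed = 8)
  expect_false(identical(a$y, c$y))
})

test_that("sampled directions match the tanh link at (effectively) fixed y", {
  # eta ~ 0 freezes the accumulators; the empirical frequency of m = +1 must
  # match (1 + tanh y)/2 within binomial error
  net <- reaction_network(
    species = tibble::tibble(id = "A", cbar = 1, u = 0, is_boundary = FALSE),
    reactions = tibble::tibble(id = c("R1", "R2", "R3"),
                               stoich = list(c(A = -1), c(A = -1), c(A = 1)),
                               qmax = 1))
  y0 <- c(-1, 0.3, 2)
  Tn <- 1e4
  tr <- simulate_dynamics(net, steps = Tn, eta = 1e-12, y0 = y0, seed = 5,
                          burnin = 0)
  phat <- (estimate_fluxes(tr, net)$flux + 1) / 2
  p <- (1 + tanh(y0)) / 2
  expect_true(all(abs(phat - p) < 4 * sqrt(p * (1 - p) / Tn) + 1e-6))
})

test_that("saturated accumulators give unit flux exactly", {
  net <- one_reaction_net(0)
  tr <- simulate_dynamics(net, steps = 5000, eta = 1e-12, y0 = 50, seed = 1)
  expect_equal(estimate_fluxes(tr, net)$flux, 1)
  # and near-zero flux at y = 0 within 3 sigma Monte-Carlo error
  tr0 <- simulate_dynamics(net, steps = 2e4, eta = 1e-12, y0 = 0, seed = 2)
  expect_lt(abs(estimate_fluxes(tr0, net)$flux),
            3 / sqrt(tr0$steps - tr0$burnin))
})

test_that("one-reaction reactor with moderate intake stays bidirectional at the mean-field fixed point", {
  u0 <- 0.5
  mf <- meanfield_one_reaction(u0)                 # oracle: tanh(y*) = u0
  expect_equal(mf$flux, u0, tolerance = 1e-6)
  net <- one_reaction_net(u0)
  tr <- simulate_dynamics(net, steps = 1e5, eta = 0.5, seed = 3, rescale = 1)
  nu <- estimate_fluxes(tr, net)$flux
  expect_lt(abs(nu - u0), 0.02)
  cls <- classify_reactions(tr)
  expect_equal(cls$label, "bidirectional")
  expect_lt(tail(tr$H_series, 1), 1e-3)
  # mean-field variant reproduces the oracle directly
  trm <- simulate_dynamics(net, steps = 5000, eta = 0.5, rescale = 1,
                           stochastic = FALSE)
  expect_equal(tanh(trm$y_final), u0, tolerance = 1e-6)
})

test_that("super-critical intake freezes the reaction forward with residual H", {
  u0 <- 1.5
  net <- one_reaction_net(u0)
  tr <- suppressWarnings(
    simulate_dynamics(net, steps = 2e4, eta = 0.5, seed = 4, rescale = 1))
  expect_equal(estimate_fluxes(tr, net)$flux, 1)
  cls <- classify_reactions(tr)
  expect_equal(cls$label, "unidirectional_forward")
  expect_equal(tail(tr$H_series, 1), (u0 - 1)^2, tolerance = 0.02)
  # the frozen direction is thermodynamically downhill
  dg <- deltaG_from_y(tr, R = 1, T_abs = 1)
  expect_lt(dg$delta_G, 0)
})

test_that("slope classification thresholds behave as documented", {
  # converged reactor: accumulator flat in the second half, gradient ~ 0
  net <- one_reaction_net(0.2)
  tr <- simulate_dynamics(net, steps = 2e4, eta = 0.5, y0 = atanh(0.2),
                          seed = 6, rescale = 1)
  cls <- classify_reactions(tr)
  expect_equal(cls$label, "bidirectional")
  expect_equal(phi(cls), 0)
  expect_lt(abs(cls$slope), 1e-2)
  # the slope is the mean gradient over the window, in units of eta * rescale:
  # a persistent drive above the threshold flags the reaction as frozen
  trd <- suppressWarnings(
    simulate_dynamics(one_reaction_net(1.2), steps = 2e4, eta = 0.5,
                      seed = 7, rescale = 1))
  expect_equal(classify_reactions(trd)$label, "unidirectional_forward")
  # classification requires enough checkpoints
  tr2 <- simulate_dynamics(net, steps = 2, burnin = 1, n_checkpoints = 2)
  expect_error(classify_reactions(tr2), "checkpoints")
})

test_that("deltaG_from_y applies the detailed-balance link", {
  net <- one_reaction_net(0.5)
  tr <- simulate_dynamics(net, steps = 100, eta = 1e-12, y0 = 1, seed = 1)
  dg <- deltaG_from_y(tr, R = 1, T_abs = 1)
  expect_equal(dg$delta_G, -2, tolerance = 1e-9)
  dg0 <- deltaG_from_y(simulate_dynamics(net, steps = 100, eta = 1e-12,
                                         y0 = 0, seed = 1), R = 1, T_abs = 1)
  expect_equal(dg0$delta_G, 0, tolerance = 1e-9)
})

test_that("closed systems relax to chemical equilibrium", {
  spec <- ensemble_spec(M = 20, p = 0.25, q = 0, b0 = 1)
  net <- sample_random_network(spec, seed = 9, n = 0.5)
  tr <- simulate_dynamics(net, steps = 1e4, eta = 0.1, seed = 10)
  nu <- estimate_fluxes(tr, net)$flux
  n_eff <- tr$steps - tr$burnin
  expect_lt(max(abs(nu)), 3 / sqrt(n_eff))
  expect_lt(hamiltonian(net, nu), 9 * nrow(net$reactions) / n_eff)
})

test_that("H of the running flux decreases on average in the ergodic regime", {
  spec <- ensemble_spec(M = 20, p = 0.25, q = 0.5, b0 = 1)
  first_third <- last_third <- numeric(10)
  for (s in 1:10) {
    net <- sample_random_network(spec, seed = 20 + s, n = 0.5)
    tr <- simulate_dynamics(net, steps = 5000, seed = 40 + s, warn_clip = FALSE)
    K <- length(tr$H_series)
    first_third[s] <- mean(tr$H_series[seq_len(K %/% 3)])
    last_third[s] <- mean(tr$H_series[(K - K %/% 3):K])
  }
  expect_lt(mean(last_third), mean(first_third))
})

test_that("tidy/glance/autoplot views of a trajectory are well-formed", {
  net <- small_random_net(2, M = 6, N = 4, p = 0.6, q = 0.5)
  tr <- simulate_dynamics(net, steps = 500, seed = 1, warn_clip = FALSE)
  td <- tidy(tr)
  expect_true(all(c("step", "reaction", "y", "m_mean") %in% names(td)))
  expect_equal(nrow(td), length(tr$checkpoint_steps) * 4)
  gl <- glance(tr)
  expect_equal(gl$steps, 500)
  expect_s3_class(autoplot(tr), "gg")
})
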