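hn <- load_hrbc_network()
hb <- hrbc_free_flux_basis(hn)

test_that("the packaged red-cell model has the documented shape", {
  expect_equal(nrow(hn$species), 30L)
  expect_equal(nrow(hn$reactions), 23L)
  expect_equal(sum(hn$species$is_boundary), 5L)
  expect_equal(nrow(validate_network(hn)), 0L)
  # two pumps present
  expect_true(all(c("ATPASE", "NADPHASE") %in% hn$reactions$id))
})

test_that("the steady-state flux space is exactly three-dimensional", {
  S_int <- stoich_matrix(hn)[!hn$species$is_boundary, ]
  expect_equal(qr(S_int)$rank, 20L)           # independent rank oracle
  expect_equal(ncol(hb$B), 3L)
  # designated coordinates of the map equal the inputs
  expect_equal(unname(hb$B[c("HK", "DPGM", "G6PDH"), ]), diag(3),
               tolerance = 1e-10)
})

test_that("mapped flux vectors balance every intracellular metabolite", {
  S_int <- stoich_matrix(hn)[!hn$species$is_boundary, ]
  expect_equal(unname(hrbc_fluxes(0, 0, 0, hb)$flux), rep(0, 23))
  set.seed(14)
  for (i in 1:100) {
    u <- runif(3, 0, 2)
    nu <- hrbc_fluxes(u[1], u[2], u[3], hb)$flux
    expect_lt(max(abs(S_int %*% nu)), 1e-12 * max(1, max(abs(nu))))
  }
})

test_that("exchange rates conserve carbon and consume glucose one-to-one", {
  carbons <- c(GLC = 6, LAC = 3, CO2 = 1, K = 0, Na = 0)
  set.seed(15)
  for (i in 1:100) {
    u <- runif(3, 0, 2)
    rates <- hrbc_exchange_rates(u[1], u[2], u[3], hb)
    r <- setNames(rates$rate, rates$species)
    expect_equal(r[["GLC"]], -u[1], tolerance = 1e-12)
    expect_lt(abs(sum(carbons * r[names(carbons)])), 1e-12)
  }
  expect_equal(hrbc_exchange_rates(0, 0, 0, hb)$rate, rep(0, 5))
  # pump direction: K flows out of the medium, Na into it
  r <- hrbc_exchange_rates(1, 0, 0, hb)
  expect_lt(r$rate[r$species == "K"], 0)
  expect_gt(r$rate[r$species == "Na"], 0)
})

test_that("extracellular H matches its term-by-term definition and 1/x scaling", {
  env <- rbc_environment()
  set.seed(16)
  for (i in 1:20) {
    u <- runif(3, 0, 2)
    H <- extracellular_H(u[1], u[2], u[3], env, hb)
    rates <- hrbc_exchange_rates(u[1], u[2], u[3], hb)
    manual <- sum(rates$rate^2 / unclass(env)[rates$species])
    expect_equal(H, manual, tolerance = 1e-12)
    env2 <- rbc_environment(GLC = 2 * 5e-3, LAC = 2e-3, K = 8e-3,
                            Na = 0.28, CO2 = 2.4e-3)
    expect_equal(extracellular_H(u[1], u[2], u[3], env2, hb), H / 2,
                 tolerance = 1e-12)
  }
  expect_equal(extracellular_H(0, 0, 0, env, hb), 0)
})

test_that("closed-form optimum equals 1-D numeric minimization to 1e-8", {
  set.seed(17)
  for (i in 1:100) {
    env <- rbc_environment(GLC = runif(1, 1e-3, 1e-2),
                           LAC = runif(1, 2e-4, 5e-3),
                           K = runif(1, 1e-3, 1e-2),
                           Na = runif(1, 0.05, 0.3),
                           CO2 = runif(1, 2e-4, 5e-2))
    u1 <- runif(1, 0.5, 2); u2 <- runif(1, 0, 1)
    opt <- optimal_g6pdh(u1, u2, env)
    oracle <- numeric_g6pdh_oracle(u1, u2, env, hb)
    expect_lt(abs(opt$u_g6pdh_opt - oracle) / max(1, abs(oracle)), 1e-8)
  }
})

test_that("a and b depend only on concentration ratios", {
  env <- rbc_environment()
  o1 <- optimal_g6pdh(1, 0.5, env)
  env2 <- rbc_environment(GLC = 3 * 5e-3, LAC = 3e-3, K = 1.2e-2,
                          Na = 0.42, CO2 = 3.6e-3)
  o2 <- optimal_g6pdh(1, 0.5, env2)
  expect_equal(o1$a, o2$a, tolerance = 1e-12)
  expect_equal(o1$b, o2$b, tolerance = 1e-12)
})

test_that("CO2-dominant environments route essentially all glucose through the PPP", {
  env_hi <- rbc_environment(CO2 = 50)   # CO2 overwhelming the other species
  opt <- optimal_g6pdh(1, 0, env_hi)
  expect_gt(opt$a, 5.9)                 # approaches the carbon-stoichiometric 6
  f <- ppp_fraction(opt$u_g6pdh_opt, 1)
  expect_gt(as.numeric(f), 0.98)
})

test_that("the PPP fraction is the carbon-rescaled G6PDH flux", {
  expect_equal(as.numeric(ppp_fraction(0, 1)), 0)
  expect_equal(as.numeric(ppp_fraction(6, 1)), 1)
  expect_equal(as.numeric(ppp_fraction(3, 1)), 0.5)
  expect_equal(as.numeric(ppp_fraction(c(1, 2), 1)),
               2 * as.numeric(ppp_fraction(c(0.5, 1), 1)))
  expect_true(attr(ppp_fraction(7, 1), "clipped"))
  expect_false(attr(ppp_fraction(3, 1), "clipped"))
  expect_error(ppp_fraction(1, 0), "positive")
})

test_that("fraction bounds bracket the admissible regime and match a 2-D grid", {
  env <- rbc_environment()
  bounds <- ppp_fraction_bounds(env, hb)
  expect_lt(bounds$F_min, bounds$F_max)
  expect_gte(bounds$F_min, 0)
  expect_lte(bounds$F_max, 1)
  # any interior shunt flux gives a fraction inside the bounds
  for (u2 in seq(0.1, 0.9, by = 0.2) * bounds$u_dpgm_max) {
    f <- as.numeric(ppp_fraction(optimal_g6pdh(1, u2, env)$u_g6pdh_opt, 1))
    expect_gte(f, bounds$F_min - 1e-9)
    expect_lte(f, bounds$F_max + 1e-9)
  }
  # 2-D grid oracle at 1e-3 resolution on the shunt axis
  u2_grid <- seq(0, bounds$u_dpgm_max, by = 1e-3)
  f_grid <- vapply(u2_grid, function(u2) {
    as.numeric(ppp_fraction(optimal_g6pdh(1, u2, env)$u_g6pdh_opt, 1))
  }, numeric(1))
  expect_equal(min(f_grid), bounds$F_min, tolerance = 1e-3)
  expect_equal(max(f_grid), bounds$F_max, tolerance = 1e-3)
})

test_that("the optimal fraction grows with ambient CO2", {
  f_at <- function(co2) {
    env <- rbc_environment(CO2 = co2)
    as.numeric(ppp_fraction(optimal_g6pdh(1, 0, env)$u_g6pdh_opt, 1))
  }
  fs <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1, 1), f_at, numeric(1))
  expect_true(all(diff(fs) >= 0))
})

test_that("the maximal CO2-to-glucose export ratio is the carbon stoichiometry", {
  expect_equal(hrbc_max_co2_ratio(hb), 6, tolerance = 1e-9)
})
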