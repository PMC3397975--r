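#' Specification of a random reaction-network ensemble
#'
#' The ensemble of artificial reactors in which the ergodicity-breaking
#' transition is studied: stoichiometric coefficients are i.i.d.
#' \eqn{\xi^\mu_i = \pm 1} with probability `p/2` each (0 with probability
#' `1 - p`); every species is independently a boundary species with probability
#' `q` and then receives intake `u = b0`; reference concentrations and flux
#' bounds are 1 (dimensionless mode). The control parameter is the ratio
#' `n = N/M` of reactions to species.
#'
#' @param M Number of species.
#' @param n Default ratio N/M (N is rounded to the nearest integer).
#' @param p Probability that a stoichiometric entry is non-zero, in (0, 1].
#' @param q Probability that a species exchanges with the exterior, in [0, 1].
#' @param b0 Intake magnitude assigned to boundary species. Its value only
#'   rescales H in the unbalanced phase; it does not move the transition point.
#' @param reps Realizations per phase point.
#' @param steps,eta Simulation length and learning rate used per realization.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(M = 50, n = 1, p = 0.25, q = 0.5, b0 = 1,
                          reps = 20, steps = 2e4, eta = 1) {
  stopifnot(M >= 1, p > 0, p <= 1, q >= 0, q <= 1, reps >= 1, steps >= 2,
            eta > 0)
  structure(list(M = M, n = n, p = p, q = q, b0 = b0, reps = reps,
                 steps = steps, eta = eta),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> M = %d, p = %g, q = %g, b0 = %g, reps = %d, T = %g\n",
              x$M, x$p, x$q, x$b0, x$reps, x$steps))
  invisible(x)
}

#' Sample one random reaction network from an ensemble
#'
#' Reactions drawn with an all-zero coefficient vector are resampled.
#'
#' @param spec An `ensemble_spec`.
#' @param seed Optional RNG seed.
#' @param n Ratio N/M (defaults to `spec$n`).
#' @return A `reaction_network` with `cbar = 1` and `qmax = 1` throughout.
#' @export
sample_random_network <- function(spec, seed = NULL, n = spec$n) {
  if (!is.null(seed)) set.seed(seed)
  M <- spec$M
  N <- max(1L, as.integer(round(n * M)))
  X <- matrix(sample(c(-1, 0, 1), M * N, replace = TRUE,
                     prob = c(spec$p / 2, 1 - spec$p, spec$p / 2)), M, N)
  for (j in seq_len(N)) {
    while (all(X[, j] == 0)) {
      X[, j] <- sample(c(-1, 0, 1), M, replace = TRUE,
                       prob = c(spec$p / 2, 1 - spec$p, spec$p / 2))
    }
  }
  boundary <- runif(M) < spec$q
  sp_id <- sprintf("S%d", seq_len(M))
  rx_id <- sprintf("R%d", seq_len(N))
  stoich <- lapply(seq_len(N), function(j) {
    nz <- which(X[, j] != 0)
    setNames(X[nz, j], sp_id[nz])
  })
  reaction_network(
    species = tibble(id = sp_id, cbar = 1,
                     u = ifelse(boundary, spec$b0, 0), is_boundary = boundary),
    reactions = tibble(id = rx_id, stoich = stoich, qmax = 1),
    validate = FALSE)
}

#' Ensemble averages at one point of the phase diagram
#'
#' Runs `spec$reps` independent realizations at ratio `n`: each samples a
#' network, simulates the stochastic dynamics, estimates fluxes, classifies
#' reactions, and records the per-species variational function
#' `H(nu_hat) / M` together with the frozen fraction `phi`. The unbiased
#' initial condition starts all accumulators at 0 (no prior directionality);
#' the biased one starts them at +5 (essentially saturated forward), probing
#' ergodicity: in the balanced phase the two initial conditions reach steady
#' states with different order parameters.
#'
#' @param spec An `ensemble_spec`.
#' @param n Ratio N/M.
#' @param init `"unbiased"` (y0 = 0) or `"biased"` (y0 = +5).
#' @param seed Master seed for the point; realization seeds are derived from it.
#' @param eps_slope Classification threshold (see [classify_reactions()]).
#' @return A one-row tibble of class `phase_point` with columns `n`, `init`,
#'   `H_mean`, `H_se`, `phi`, `phi_se`, `nbid` (= n (1 - phi)), `nbid_se` and
#'   `reps`; per-realization values are attached as attribute `"realizations"`.
#' @export
run_phase_point <- function(spec, n = spec$n, init = c("unbiased", "biased"),
                            seed = NULL, eps_slope = 1e-2) {
  init <- match.arg(init)
  y0 <- if (init == "biased") 5 else 0
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(2147483646L, 2L * spec$reps)
  H <- phi_r <- numeric(spec$reps)
  for (r in seq_len(spec$reps)) {
    net <- sample_random_network(spec, seed = rep_seeds[2L * r - 1L], n = n)
    traj <- simulate_dynamics(net, steps = spec$steps, eta = spec$eta, y0 = y0,
                              seed = rep_seeds[2L * r], warn_clip = FALSE)
    nu <- estimate_fluxes(traj, net)
    H[r] <- hamiltonian(net, nu) / spec$M
    phi_r[r] <- phi(classify_reactions(traj, eps_slope = eps_slope))
  }
  se <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
  out <- tibble(n = n, init = init,
                H_mean = mean(H), H_se = se(H),
                phi = mean(phi_r), phi_se = se(phi_r),
                nbid = n * (1 - mean(phi_r)), nbid_se = n * se(phi_r),
                reps = spec$reps)
  class(out) <- c("phase_point", class(out))
  attr(out, "realizations") <- tibble(rep = seq_len(spec$reps), H = H, phi = phi_r)
  out
}

#' Sweep the phase diagram over a grid of ratios n = N/M
#'
#' Produces both the unbiased and the biased curves. The same realization seeds
#' are used for both initial conditions at each grid point, so the comparison
#' is over paired network samples.
#'
#' @param spec An `ensemble_spec`.
#' @param n_grid Sorted grid of ratios (at least 3 points).
#' @param seed Master seed.
#' @param init Which initial conditions to run (default both).
#' @param verbose Print progress lines.
#' @return A tibble of class `phase_sweep`, one row per (n, init), with the
#'   columns of [run_phase_point()]. Per-realization detail is attached as
#'   attribute `"realizations"`.
#' @export
phase_sweep <- function(spec, n_grid, seed = NULL,
                        init = c("unbiased", "biased"), verbose = FALSE) {
  stopifnot(length(n_grid) >= 3L, !is.unsorted(n_grid))
  init <- match.arg(init, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  point_seeds <- sample.int(2147483646L, length(n_grid))
  rows <- list(); detail <- list()
  for (i in seq_along(n_grid)) {
    for (ic in init) {
      pt <- run_phase_point(spec, n = n_grid[i], init = ic,
                            seed = point_seeds[i])
      det <- attr(pt, "realizations")
      det$n <- n_grid[i]; det$init <- ic
      rows[[length(rows) + 1L]] <- pt
      detail[[length(detail) + 1L]] <- det
      if (verbose)
        message(sprintf("n = %.3f %-9s H = %.4g phi = %.3f",
                        n_grid[i], ic, pt$H_mean, pt$phi))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phase_sweep", class(out))
  attr(out, "realizations") <- dplyr::bind_rows(detail)
  attr(out, "spec") <- spec
  out
}

#' Locate the ergodicity-breaking transition from a phase sweep
#'
#' Two estimators of the critical ratio: the first grid crossing where the
#' ensemble-averaged `H` falls below `eps_H` (linear interpolation), and the
#' crossing of the relative number of bidirectional reactions
#' `nbid = n (1 - phi)` through 1. In the theory the two coincide: balance
#' becomes achievable exactly when the bidirectional reactions outnumber the
#' species.
#'
#' @param points A `phase_sweep` (or compatible tibble); if both initial
#'   conditions are present, `init` selects which curve is used.
#' @param eps_H Threshold below which `H` is considered zero (default 1e-2).
#' @param init Curve to use (default `"unbiased"`).
#' @return Tibble with columns `method` (`"H"` or `"nbid"`), `n_c`,
#'   `half_width` (grid-resolution error bar) and `status` (`"ok"` or
#'   `"not bracketed"`).
#' @export
estimate_critical_point <- function(points, eps_H = 1e-2, init = "unbiased") {
  pts <- as_tibble(points)
  if ("init" %in% names(pts)) pts <- pts[pts$init == init, ]
  pts <- pts[order(pts$n), ]
  if (nrow(pts) < 3L) abort("need at least 3 phase points")
  slack <- 2 * pmax(pts$nbid_se, 0, na.rm = TRUE) + 1e-9
  if (any(diff(pts$nbid) < -(slack[-1] + slack[-nrow(pts)])))
    abort("nbid must be non-decreasing in n (is the grid sorted and converged?)")

  interp_cross <- function(xv, yv, level, decreasing) {
    # first index where the curve reaches `level` in the stated direction
    # (non-strict, so a curve that touches the level exactly still counts)
    below <- if (decreasing) yv <= level else yv >= level
    k <- which(below)[1]
    if (is.na(k) || k == 1L)
      return(c(NA_real_, NA_real_))
    x0 <- xv[k - 1]; x1 <- xv[k]; y0 <- yv[k - 1]; y1 <- yv[k]
    xc <- if (y1 == y0) (x0 + x1) / 2 else x0 + (level - y0) * (x1 - x0) / (y1 - y0)
    c(xc, (x1 - x0) / 2)
  }
  h_cross <- interp_cross(pts$n, pts$H_mean, eps_H, decreasing = TRUE)
  b_cross <- interp_cross(pts$n, pts$nbid, 1, decreasing = FALSE)
  tibble(method = c("H", "nbid"),
         n_c = c(h_cross[1], b_cross[1]),
         half_width = c(h_cross[2], b_cross[2]),
         status = ifelse(is.na(c(h_cross[1], b_cross[1])),
                         "not bracketed", "ok"))
}
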