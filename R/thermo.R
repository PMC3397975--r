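#' Thermodynamic state of a reactor
#'
#' Bundles the quantities needed to attach physical thermodynamics to a
#' network: standard Gibbs energy changes per reaction, the concentrations at
#' which reactions operate, a reference concentration, the gas constant and
#' the temperature. Defaults are physiological (310 K) with `R` in J/mol/K;
#' set `R = 1, T_abs = 1` for dimensionless work.
#'
#' @param dG0 Standard Gibbs energy change per reaction (scalar recycled).
#' @param conc Operating concentrations per species; when `NULL` the network's
#'   reference concentrations `cbar` are used at evaluation time.
#' @param c0 Reference concentration (default 1).
#' @param R Gas constant (default 8.314 J/mol/K).
#' @param T_abs Absolute temperature (default 310 K).
#' @return An object of class `thermo_state`.
#' @export
thermo_state <- function(dG0 = 0, conc = NULL, c0 = 1, R = 8.314,
                         T_abs = 310) {
  stopifnot(c0 > 0, R > 0, T_abs > 0)
  if (!is.null(conc) && any(conc <= 0)) abort("concentrations must be positive")
  structure(list(dG0 = dG0, conc = conc, c0 = c0, R = R, T_abs = T_abs),
            class = "thermo_state")
}

ts_conc <- function(net, ts) {
  conc <- ts$conc %||% net$species$cbar
  if (length(conc) == 1L) conc <- rep(conc, nrow(net$species))
  if (any(conc <= 0)) abort("concentrations must be positive")
  conc
}

#' Gibbs energy change per reaction
#'
#' \deqn{\Delta G_i = \Delta G^0_i + R T \sum_\mu \xi^\mu_i \ln(c_\mu / c_0),}
#' the distance of each reaction from detailed balance at the given
#' concentrations: zero at equilibrium, negative when the forward direction is
#' thermodynamically favoured.
#'
#' @param net A `reaction_network`.
#' @param ts A `thermo_state`.
#' @return Tibble with columns `reaction`, `delta_G`.
#' @export
gibbs_energy <- function(net, ts = thermo_state()) {
  conc <- ts_conc(net, ts)
  S <- stoich_matrix(net)
  dg0 <- rep(ts$dG0, length.out = ncol(S))
  dG <- dg0 + ts$R * ts$T_abs * unname(drop(crossprod(S, log(conc / ts$c0))))
  tibble(reaction = net$reactions$id, delta_G = dG)
}

#' Forward-to-reverse flux ratio from Gibbs energies
#'
#' Detailed balance for the microscopic transitions implies
#' \eqn{\nu^+/\nu^- = e^{-\Delta G/(R T)}}: unity at equilibrium, large when
#' the forward direction is strongly favoured.
#'
#' @param dG Numeric Gibbs energies, or a tibble with a `delta_G` column (as
#'   returned by [gibbs_energy()] or [deltaG_from_y()]).
#' @param ts A `thermo_state`.
#' @return Tibble with columns `delta_G`, `ratio` (plus `reaction` if present
#'   in the input).
#' @export
flux_ratio <- function(dG, ts = thermo_state()) {
  if (is.data.frame(dG)) {
    out <- as_tibble(dG)
    out$ratio <- exp(-out$delta_G / (ts$R * ts$T_abs))
    return(out)
  }
  tibble(delta_G = as.numeric(dG),
         ratio = exp(-as.numeric(dG) / (ts$R * ts$T_abs)))
}

#' Entropy production per volume
#'
#' The reaction contribution to the entropy production,
#' \eqn{\sigma = -\frac{1}{T}\sum_i \nu_i \Delta G_i}. It is non-negative
#' whenever every flux runs against its Gibbs energy gradient (every term
#' \eqn{-\nu_i \Delta G_i \ge 0}), i.e. for thermodynamically feasible states.
#'
#' @param net A `reaction_network`.
#' @param nu Flux vector (numeric or tibble with `flux` column).
#' @param dG Gibbs energies (numeric or tibble with `delta_G`); computed from
#'   `ts` when `NULL`.
#' @param ts A `thermo_state`.
#' @return Scalar entropy production.
#' @export
entropy_production <- function(net, nu, dG = NULL, ts = thermo_state()) {
  nu <- as_flux_vector(nu, net)
  if (is.null(dG)) dG <- gibbs_energy(net, ts)
  if (is.data.frame(dG)) dG <- dG$delta_G
  -sum(nu * dG) / ts$T_abs
}

#' Check the entropy-production decay relation
#'
#' In a steady state with flux vector \eqn{\nu} and imbalance residuals
#' \eqn{r_\mu}, concentrations drift as \eqn{\dot c_\mu = r_\mu} and the full
#' entropy production (reaction terms plus the boundary-exchange
#' chemical-potential terms) decays at a rate proportional to H:
#' \eqn{d\sigma/dt = -\kappa H / T} with \eqn{\kappa = R\,T} for the entropy
#' production as implemented here (so \eqn{d\sigma/dt = -R\,H} exactly at the
#' reference concentrations). Balanced states (H = 0) have constant entropy
#' production; unbalanced ones dissipate at a rate that decreases as slowly as
#' the constraints allow. This function estimates \eqn{d\sigma/dt} by finite
#' differences along the concentration bookkeeping and reports it next to the
#' prediction, as an empirical consistency ratio.
#'
#' @param traj A `trajectory_record` (its post-burn-in fluxes are used), or a
#'   flux vector.
#' @param net The `reaction_network`.
#' @param ts A `thermo_state` (standard potentials are taken as zero).
#' @param kappa Proportionality constant in `-kappa * H / T_abs`; default
#'   `ts$R * ts$T_abs`, the self-consistent value.
#' @param window_frac Fractional concentration change over the probe window
#'   (default 0.01, keeping the linearization accurate).
#' @param n_points Checkpoints of the finite-difference window (>= 10).
#' @return Tibble with columns `dsigma_dt`, `reference` (`-kappa H / T_abs`),
#'   `ratio`, `H`.
#' @export
entropy_decay_check <- function(traj, net, ts = thermo_state(),
                                kappa = ts$R * ts$T_abs,
                                window_frac = 0.01, n_points = 11) {
  if (n_points < 10) abort("need at least 10 checkpoints in the window")
  nu <- if (inherits(traj, "trajectory_record")) {
    estimate_fluxes(traj, net)$flux
  } else {
    as_flux_vector(traj, net)
  }
  S <- stoich_matrix(net)
  cbar <- net$species$cbar
  r <- drop(S %*% nu) + net$species$u
  H <- sum(r^2 / cbar)
  if (max(abs(r)) == 0) {
    return(tibble(dsigma_dt = 0, reference = 0, ratio = NA_real_, H = H))
  }
  t_max <- window_frac * min(cbar / pmax(abs(r), 1e-300))
  tgrid <- seq(0, t_max, length.out = n_points)
  sigma <- vapply(tgrid, function(t) {
    conc <- cbar + r * t
    mu <- ts$R * ts$T_abs * log(conc / ts$c0)   # ideal chemical potentials
    -sum(r * mu) / ts$T_abs                     # reaction + exchange terms
  }, numeric(1))
  dsdt <- (sigma[2] - sigma[1]) / (tgrid[2] - tgrid[1])
  ref <- -kappa * H / ts$T_abs
  tibble(dsigma_dt = dsdt, reference = ref, ratio = dsdt / ref, H = H)
}

#' Free energy of a flux perturbation around equilibrium
#'
#' Forcing a small flux \eqn{\delta\nu_i} through each reaction of an
#' equilibrated closed system for a time \eqn{\tau} displaces concentrations by
#' \eqn{\delta c_\mu = \tau \sum_i \xi^\mu_i \delta\nu_i}; for an ideal dilute
#' system the Gibbs free energy per volume of the perturbed state exceeds the
#' equilibrium value by
#' \deqn{\Delta G = \frac{R T \tau^2}{2} \sum_\mu
#'       \frac{(\sum_i \xi^\mu_i \delta\nu_i)^2}{c_\mu}
#'       = \frac{R T \tau^2}{2} H_0(\delta\nu) \ge 0,}
#' with \eqn{H_0} the variational function of the closed system — the second
#' law in quadratic form.
#'
#' @param net A `reaction_network` (its `u` is ignored: the unperturbed state
#'   is equilibrium).
#' @param delta_nu Perturbing flux vector.
#' @param tau Duration of the perturbation (> 0).
#' @param ts A `thermo_state`.
#' @return Scalar free-energy excess (>= 0).
#' @export
perturbation_free_energy <- function(net, delta_nu, tau, ts = thermo_state()) {
  stopifnot(tau > 0)
  delta_nu <- as_flux_vector(delta_nu, net)
  conc <- ts_conc(net, ts)
  S <- stoich_matrix(net)
  dr <- drop(S %*% delta_nu)
  (ts$R * ts$T_abs * tau^2 / 2) * sum(dr^2 / conc)
}
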