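#' Simulate the stochastic resource-allocation dynamics
#'
#' Runs the discrete-time dynamics in which each reaction carries an
#' accumulator \eqn{y_i} (a running score of how favourable the forward
#' direction has been): at every step each reaction samples a microscopic
#' direction \eqn{m_i \in \{-1,+1\}} with
#' \deqn{P(m_i = +1) = \frac{1 + \tanh y_i}{2},}
#' so the log-probability ratio of forward to reverse is \eqn{2 y_i}
#' (proportional to the substrate-to-product concentration ratio, i.e. to the
#' negative Gibbs energy of the reaction), and then all accumulators move
#' against the gradient of `H`:
#' \deqn{y_i \leftarrow y_i - \eta\, \rho \big(\textstyle\sum_j J_{ij} m_j + h_i\big),}
#' with learning rate `eta` and coupling rescale factor `rescale`
#' (\eqn{\rho}, default `1/M`, which keeps the drift well behaved when the
#' network is large). Time-averaged sampled directions estimate the reaction
#' fluxes; reactions whose accumulator stays bounded remain bidirectional,
#' those whose accumulator drifts linearly freeze into one direction.
#'
#' The mean-field variant (`stochastic = FALSE`) replaces the sampled
#' directions by their conditional expectation \eqn{\tanh y} and is
#' deterministic; it serves as an oracle for the stochastic dynamics.
#'
#' @param net A `reaction_network`.
#' @param steps Number of update steps T.
#' @param eta Learning rate (drift step size), positive.
#' @param y0 Initial accumulators (scalar recycled, or length-N vector;
#'   default 0, the unbiased "equilibrium" start).
#' @param seed RNG seed for reproducibility (optional).
#' @param burnin Steps discarded before flux averaging (default `floor(steps/2)`).
#' @param rescale Coupling rescale factor (default `1/M`).
#' @param stochastic Sample directions (default) or use the mean-field drift.
#' @param n_checkpoints Number of geometrically spaced checkpoints at which the
#'   accumulators and running flux averages are recorded (default 256; the
#'   steps `floor(steps/2)` and `steps` are always included).
#' @param couplings Optional precomputed `coupling_system` (without rescale).
#' @param clip Accumulators are clipped to `[-clip, clip]` (default 500; tanh
#'   saturates to machine precision far earlier, so this only guards overflow).
#' @param warn_clip Warn when clipping occurs (default `TRUE`; ensemble runs
#'   silence it, since frozen reactions routinely drive their accumulator to
#'   the rail).
#' @return An object of class `trajectory_record`: checkpointed accumulators
#'   `y` and running direction averages `m_mean` (N x checkpoints matrices),
#'   `H_series` (H of the running flux average at each checkpoint),
#'   `checkpoint_steps`, `y_final`, the post-burn-in direction sum used for
#'   flux estimation, and the run parameters.
#' @seealso [estimate_fluxes()], [classify_reactions()], [deltaG_from_y()]
#' @export
simulate_dynamics <- function(net, steps = 2e4, eta = 1, y0 = 0, seed = NULL,
                              burnin = NULL, rescale = NULL, stochastic = TRUE,
                              n_checkpoints = 256, couplings = NULL, clip = 500,
                              warn_clip = TRUE) {
  stopifnot(steps >= 1, eta > 0)
  N <- nrow(net$reactions)
  M <- nrow(net$species)
  if (is.null(burnin)) burnin <- floor(steps / 2)
  if (burnin >= steps) abort("burnin must be smaller than steps")
  if (is.null(rescale)) rescale <- 1 / M
  if (length(y0) == 1L) y0 <- rep(y0, N)
  stopifnot(length(y0) == N)
  cs <- couplings %||% build_couplings(net)

  ck <- checkpoint_schedule(steps, n_checkpoints)
  if (!is.null(seed)) set.seed(seed)
  out <- .sim_core(cs$J, cs$h, y0, as.integer(steps), as.integer(burnin),
                   eta, rescale, as.integer(ck), stochastic, clip)
  if (out$clipped > 0 && warn_clip)
    warn(sprintf("%d accumulator updates hit the clipping bound |y| = %g",
                 out$clipped, clip))

  # running flux average at each checkpoint and the H it attains
  nu_ck <- out$m_mean / (net$volume * net$dt)
  r_ck <- (cs$S %*% nu_ck) + cs$u
  H_series <- colSums(r_ck^2 / cs$cbar)

  structure(
    list(y = out$y, m_mean = out$m_mean, H_series = H_series,
         checkpoint_steps = ck, y_final = drop(out$y_final),
         msum_post = drop(out$msum_post),
         steps = steps, burnin = burnin, eta = eta, rescale = rescale,
         stochastic = stochastic, seed = seed, clipped = out$clipped,
         clip = clip,
         reaction_id = net$reactions$id, M = M,
         volume = net$volume, dt = net$dt),
    class = "trajectory_record")
}

# Geometric checkpoint schedule covering both the transient and the asymptotic
# linear-growth regime; always contains floor(steps/2) and steps, which the
# classifier needs.
checkpoint_schedule <- function(steps, n_checkpoints) {
  ck <- unique(round(exp(seq(0, log(steps), length.out = n_checkpoints))))
  sort(unique(c(ck, max(1, floor(steps / 2)), steps)))
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record> N = %d reactions, %d steps (%d burn-in), %s\n",
              length(x$y_final), x$steps, x$burnin,
              if (x$stochastic) "stochastic" else "mean-field"))
  cat(sprintf("  eta = %g, rescale = %g, final H on running flux = %g\n",
              x$eta, x$rescale, tail(x$H_series, 1)))
  invisible(x)
}

#' Time-averaged flux estimates from a trajectory
#'
#' The flux of a reaction is the average net number of microscopic transitions
#' per time per volume: the post-burn-in mean of the sampled directions divided
#' by `volume * dt`.
#'
#' @param traj A `trajectory_record`.
#' @param net The network it was simulated from.
#' @return Tibble with columns `reaction` and `flux`.
#' @export
estimate_fluxes <- function(traj, net) {
  n_eff <- traj$steps - traj$burnin
  if (n_eff <= 0) abort("burnin >= steps: no samples to average")
  tibble(reaction = traj$reaction_id,
         flux = traj$msum_post / n_eff / (net$volume * net$dt))
}

#' Classify reactions as bidirectional or frozen
#'
#' A reaction whose accumulator drifts linearly in time has frozen into
#' unidirectional operation (its reverse microscopic transitions have
#' disappeared); one whose accumulator stays bounded remains bidirectional,
#' with its flux pinned by the zero-gradient condition. The drift estimate is
#' the accumulator change over the second half of the run, expressed in
#' rescaled units (divided by `eta * rescale`), i.e. the average gradient
#' magnitude experienced over that window.
#'
#' @param traj A `trajectory_record` with at least 4 checkpoints.
#' @param eps_slope Threshold on the absolute rescaled slope above which a
#'   reaction is called unidirectional (default 1e-2).
#' @return An object of class `reaction_classification`: a tibble with columns
#'   `reaction`, `slope`, `label` (one of `bidirectional`,
#'   `unidirectional_forward`, `unidirectional_reverse`), with the frozen
#'   fraction `phi` as an attribute (see [phi()]).
#' @export
classify_reactions <- function(traj, eps_slope = 1e-2) {
  if (length(traj$checkpoint_steps) < 4L)
    abort("classification needs at least 4 checkpoints")
  t_half <- max(1, floor(traj$steps / 2))
  i_half <- match(t_half, traj$checkpoint_steps)
  i_end <- match(traj$steps, traj$checkpoint_steps)
  window <- (traj$checkpoint_steps[i_end] - traj$checkpoint_steps[i_half])
  slope <- (traj$y[, i_end] - traj$y[, i_half]) /
    (window * traj$eta * traj$rescale)
  # accumulators sitting on the clipping rail had a linear drift that the
  # windowed slope can no longer see: they are frozen by construction
  railed <- abs(traj$y_final) >= 0.995 * (traj$clip %||% Inf)
  label <- dplyr::case_when(
    railed & traj$y_final > 0 ~ "unidirectional_forward",
    railed ~ "unidirectional_reverse",
    abs(slope) <= eps_slope ~ "bidirectional",
    slope > 0 ~ "unidirectional_forward",
    TRUE ~ "unidirectional_reverse")
  out <- tibble(reaction = traj$reaction_id, slope = slope, label = label)
  class(out) <- c("reaction_classification", class(out))
  attr(out, "phi") <- mean(label != "bidirectional")
  attr(out, "eps_slope") <- eps_slope
  out
}

#' Fraction of unidirectional (frozen) reactions
#'
#' @param classification A `reaction_classification`.
#' @return Scalar in `[0, 1]`.
#' @export
phi <- function(classification) {
  attr(classification, "phi")
}

#' Gibbs energy estimates from accumulators
#'
#' In a steady state the forward/reverse transition probability ratio of
#' reaction i is \eqn{e^{2 y_i}}, and detailed balance relates that ratio to
#' the Gibbs energy change, \eqn{\nu^+/\nu^- = e^{-\Delta G/(R T)}}. The final
#' accumulators therefore estimate \eqn{\Delta G_i = -2 R T\, y_i}.
#'
#' @param traj A `trajectory_record`.
#' @param R Gas constant (default 8.314 J/mol/K; use 1 in dimensionless mode).
#' @param T_abs Absolute temperature (default 310 K).
#' @return Tibble with columns `reaction`, `y`, `delta_G`.
#' @export
deltaG_from_y <- function(traj, R = 8.314, T_abs = 310) {
  tibble(reaction = traj$reaction_id, y = traj$y_final,
         delta_G = -2 * R * T_abs * traj$y_final)
}
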