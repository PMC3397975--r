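#' Linear-stability spectrum of the bidirectional sector
#'
#' In a steady state, small perturbations of the accumulators of reactions that
#' remain bidirectional relax according to the restricted coupling matrix
#' \deqn{K_{ij} = \frac{1}{M} \sum_\mu \xi^\mu_i \xi^\mu_j / \bar c_\mu,
#'       \quad i, j \in \mathrm{bidirectional},}
#' times a positive diagonal factor from the derivative of tanh (which cannot
#' change eigenvalue signs and is therefore not included in the verdict). `K`
#' is a Gram matrix: its eigenvalues are non-negative, and for random
#' stoichiometries with i.i.d. entries of variance \eqn{\sigma^2} its smallest
#' eigenvalue converges (as \eqn{M \to \infty} at fixed aspect ratio
#' \eqn{r = N_{bid}/M}) to the Marchenko-Pastur edge
#' \eqn{\lambda_{min} \to \sigma^2 (1 - \sqrt r)^2}. Stability (and hence
#' ergodicity) requires \eqn{r < 1}; at \eqn{r = 1} the edge touches zero and
#' the dynamics becomes marginal.
#'
#' @param net A `reaction_network`.
#' @param classification A `reaction_classification` from [classify_reactions()],
#'   or a logical/character vector marking bidirectional reactions.
#' @param sigma2 Entry variance of the stoichiometric coefficients; estimated
#'   from the network (`mean(S^2)`) when `NULL`. For the standard `+/-1` with
#'   density `p` ensemble this equals `p`.
#' @return An object of class `spectrum_report`: `r`, `lambda_min`,
#'   `lambda_edge`, `sigma2`, `stable`, the full spectrum `values`, and
#'   `n_bidirectional`. When no reaction is bidirectional, `r = 0` and
#'   `lambda_min` is `NA` with `defined = FALSE`.
#' @export
bidirectional_spectrum <- function(net, classification, sigma2 = NULL) {
  if (inherits(classification, "reaction_classification") ||
      is.data.frame(classification)) {
    keep <- classification$label == "bidirectional"
  } else if (is.character(classification)) {
    keep <- classification == "bidirectional"
  } else {
    keep <- as.logical(classification)
  }
  S <- stoich_matrix(net)
  M <- nrow(S)
  if (is.null(sigma2)) sigma2 <- mean(S^2)
  n_bid <- sum(keep)
  r <- n_bid / M
  lambda_edge <- sigma2 * max(0, 1 - sqrt(r))^2
  if (n_bid == 0L) {
    return(structure(list(r = 0, lambda_min = NA_real_, lambda_edge = sigma2,
                          sigma2 = sigma2, stable = NA, values = numeric(0),
                          n_bidirectional = 0L, M = M, defined = FALSE),
                     class = "spectrum_report"))
  }
  Sb <- S[, keep, drop = FALSE]
  K <- crossprod(Sb, Sb / net$species$cbar) / M
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  structure(list(r = r, lambda_min = lam_min, lambda_edge = lambda_edge,
                 sigma2 = sigma2, stable = lam_min > 1e-10, values = ev,
                 n_bidirectional = n_bid, M = M, defined = TRUE),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<spectrum_report> r = %.4g (N_bid = %d, M = %d)\n",
              x$r, x$n_bidirectional, x$M))
  cat(sprintf("  lambda_min = %s, MP edge = %.4g (sigma2 = %.4g), stable = %s\n",
              if (x$defined) format(x$lambda_min, digits = 6) else "undefined",
              x$lambda_edge, x$sigma2, x$stable))
  invisible(x)
}

#' Stability verdict from a spectrum report
#'
#' `ergodic_stable` when the bidirectional sector is smaller than the species
#' set (`r < 1`) with a strictly positive smallest eigenvalue; `marginal` when
#' `r` is within `grid_tol` of 1 (or the spectrum touches zero); `unstable`
#' when `r > 1`, where the balanced solution set is under-constrained and the
#' reached steady state depends on the initial conditions.
#'
#' @param report A `spectrum_report`.
#' @param grid_tol Width of the marginal band around r = 1 (default 0.05).
#' @param eig_tol Absolute eigenvalue tolerance (default 1e-10).
#' @return One of `"ergodic_stable"`, `"marginal"`, `"unstable"`.
#' @export
stability_verdict <- function(report, grid_tol = 0.05, eig_tol = 1e-10) {
  r <- report$r
  if (abs(r - 1) < grid_tol) return("marginal")
  if (r > 1) return("unstable")
  lam <- report$lambda_min
  if (report$defined && !is.na(lam) && lam <= eig_tol) return("marginal")
  "ergodic_stable"
}
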