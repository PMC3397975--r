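# broom-style accessors for the package's result objects.

#' Tidy a trajectory record
#'
#' One row per (checkpoint, reaction): accumulator `y` and running direction
#' average `m_mean`.
#'
#' @param x A `trajectory_record`.
#' @param ... Unused.
#' @return A long tibble with columns `step`, `reaction`, `y`, `m_mean`.
#' @export
tidy.trajectory_record <- function(x, ...) {
  K <- length(x$checkpoint_steps)
  tibble(step = rep(x$checkpoint_steps, each = length(x$reaction_id)),
         reaction = rep(x$reaction_id, times = K),
         y = as.vector(x$y),
         m_mean = as.vector(x$m_mean))
}

#' @rdname tidy.trajectory_record
#' @export
glance.trajectory_record <- function(x, ...) {
  tibble(steps = x$steps, burnin = x$burnin, eta = x$eta,
         rescale = x$rescale, stochastic = x$stochastic,
         H_final = unname(tail(x$H_series, 1)), clipped = x$clipped)
}

#' Tidy a minimization result
#'
#' @param x A `minimization_result`.
#' @param ... Unused.
#' @return Tibble with columns `reaction`, `flux`, `at_bound`.
#' @export
tidy.minimization_result <- function(x, ...) {
  tibble(reaction = names(x$nu), flux = unname(x$nu),
         at_bound = names(x$nu) %in% x$active_set)
}

#' @rdname tidy.minimization_result
#' @export
glance.minimization_result <- function(x, ...) {
  tibble(H_min = x$H_min, kkt_residual = x$kkt_residual,
         n_active = length(x$active_set), iterations = x$iterations,
         converged = x$converged,
         norm = x$norm %||% sqrt(sum(x$nu^2)))
}

#' Tidy a feasibility certificate
#'
#' Returns the certificate as a long tibble: the species potentials when
#' feasible, the cycle flux components when not.
#'
#' @param x A `feasibility_certificate`.
#' @param ... Unused.
#' @return Tibble with columns `kind`, `id`, `value`.
#' @export
tidy.feasibility_certificate <- function(x, ...) {
  if (x$feasible) {
    tibble(kind = "potential", id = names(x$potentials),
           value = unname(x$potentials))
  } else {
    tibble(kind = "cycle", id = names(x$cycle), value = unname(x$cycle))
  }
}

#' @rdname tidy.feasibility_certificate
#' @export
glance.feasibility_certificate <- function(x, ...) {
  tibble(feasible = x$feasible, trivial = isTRUE(x$trivial),
         distance = x$distance, n_active = length(x$active))
}

#' Tidy a spectrum report
#'
#' @param x A `spectrum_report`.
#' @param ... Unused.
#' @return Tibble of eigenvalues with their index.
#' @export
tidy.spectrum_report <- function(x, ...) {
  tibble(index = seq_along(x$values), eigenvalue = x$values)
}

#' @rdname tidy.spectrum_report
#' @export
glance.spectrum_report <- function(x, ...) {
  tibble(r = x$r, lambda_min = x$lambda_min, lambda_edge = x$lambda_edge,
         sigma2 = x$sigma2, stable = x$stable,
         n_bidirectional = x$n_bidirectional, M = x$M)
}

#' Tidy a solution space
#'
#' @param x A `solution_space`.
#' @param ... Unused.
#' @return Tibble with the particular solution and one column per basis vector.
#' @export
tidy.solution_space <- function(x, ...) {
  if (!x$balanced) return(tibble(reaction = character(0), flux = numeric(0)))
  out <- tibble(reaction = names(x$particular), flux = unname(x$particular))
  if (x$dimension > 0) {
    B <- x$basis
    colnames(B) <- sprintf("basis_%d", seq_len(ncol(B)))
    out <- dplyr::bind_cols(out, as_tibble(B))
  }
  out
}

#' @rdname tidy.solution_space
#' @export
glance.solution_space <- function(x, ...) {
  tibble(balanced = x$balanced, dimension = x$dimension, rank = x$rank,
         H_min = x$H_min)
}
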