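# The red-blood-cell case study: a reduced erythrocyte network (glycolysis +
# pentose phosphate pathway + Rapoport-Leubering shunt + two ionic pumps)
# whose steady-state flux space is exactly three-dimensional, analyzed through
# the variational function of the extracellular medium.

#' Load the packaged reduced red-blood-cell network
#'
#' The reduced human erythrocyte model: 30 metabolites and 23 reactions (21
#' enzymatic steps plus the Na/K-ATPase and NADPHase pumps). Glycolysis ends in
#' lactate export coupled to K/Na exchange through the ATPase; the pentose
#' phosphate pathway releases CO2 and regenerates NADPH consumed by the
#' NADPHase; the Rapoport-Leubering shunt bypasses the phosphoglycerate kinase
#' step. The five boundary species are extracellular glucose, lactate, K, Na
#' and CO2. Concentrations are textbook physiological values (the fixture is a
#' reconstruction of the standard reduced model).
#'
#' @return A validated `reaction_network` with 30 species and 23 reactions.
#' @export
load_hrbc_network <- function() {
  sf <- system.file("extdata", "hrbc_species.tsv", package = "fluxness",
                    mustWork = TRUE)
  rf <- system.file("extdata", "hrbc_reactions.tsv", package = "fluxness",
                    mustWork = TRUE)
  net <- read_network(sf, rf)
  if (nrow(net$species) != 30L || nrow(net$reactions) != 23L ||
      !setequal(net$species$id[net$species$is_boundary],
                c("GLC", "LAC", "K", "Na", "CO2")))
    abort("hRBC fixture integrity check failed", class = "fluxness_fixture_error")
  net
}

#' Free-flux basis of the red-cell model
#'
#' Imposing exact mass balance on all 25 intracellular metabolites leaves a
#' three-dimensional space of steady-state flux vectors: only three of the 23
#' reactions are linearly independent. The free coordinates are chosen as the
#' glucose uptake (hexokinase flux, `u_glc`), the Rapoport-Leubering shunt flux
#' (`u_dpgm`) and the pentose-phosphate commitment flux (`u_g6pdh`). The
#' returned basis matrix `B` (23 x 3) maps these to the full flux vector; its
#' rows for HK, DPGM and G6PDH form the identity.
#'
#' @param net The hRBC network (loaded if missing).
#' @return An object of class `hrbc_basis`: `B`, the internal stoichiometric
#'   matrix rank, and the reaction/species bookkeeping.
#' @export
hrbc_free_flux_basis <- function(net = load_hrbc_network()) {
  S <- stoich_matrix(net)
  internal <- !net$species$is_boundary
  nb <- null_basis(S[internal, , drop = FALSE])
  if (nb$dimension != 3L)
    abort(sprintf("hRBC fixture error: steady-state flux space has dimension %d, expected 3",
                  nb$dimension), class = "fluxness_fixture_error")
  key <- c("HK", "DPGM", "G6PDH")
  idx <- match(key, net$reactions$id)
  Tm <- nb$basis[idx, , drop = FALSE]
  if (abs(det(Tm)) < 1e-12)
    abort("hRBC fixture error: HK/DPGM/G6PDH do not span the free-flux space",
          class = "fluxness_fixture_error")
  B <- nb$basis %*% solve(Tm)
  dimnames(B) <- list(net$reactions$id, c("u_glc", "u_dpgm", "u_g6pdh"))
  structure(list(B = B, rank = nb$rank, reaction_id = net$reactions$id,
                 boundary_S = S[!internal, , drop = FALSE]),
            class = "hrbc_basis")
}

#' Full red-cell flux vector from the three free fluxes
#'
#' @param u_glc Glucose uptake (> 0 for physiological operation).
#' @param u_dpgm Rapoport-Leubering shunt flux.
#' @param u_g6pdh Pentose-phosphate (G6PDH) flux.
#' @param basis An `hrbc_basis` (computed if missing).
#' @return Tibble with columns `reaction`, `flux`; intracellular mass balance
#'   holds identically for any input.
#' @export
hrbc_fluxes <- function(u_glc, u_dpgm, u_g6pdh,
                        basis = hrbc_free_flux_basis()) {
  nu <- drop(basis$B %*% c(u_glc, u_dpgm, u_g6pdh))
  tibble(reaction = basis$reaction_id, flux = nu)
}

#' Extracellular concentration rates of the red-cell model
#'
#' Rates of change of the five extracellular species (GLC, LAC, K, Na, CO2)
#' induced by the operation of one cell: `rate_s = sum_i xi^s_i nu_i`.
#' Glucose is consumed (`rate = -u_glc`), lactate and CO2 are exported, the
#' pump depletes extracellular K and enriches Na. Carbon is conserved:
#' `6 * (GLC consumption) = 3 * (LAC rate) + (CO2 rate)` for every input.
#'
#' @inheritParams hrbc_fluxes
#' @return Tibble with columns `species`, `rate`.
#' @export
hrbc_exchange_rates <- function(u_glc, u_dpgm, u_g6pdh,
                                basis = hrbc_free_flux_basis()) {
  nu <- drop(basis$B %*% c(u_glc, u_dpgm, u_g6pdh))
  rates <- unname(drop(basis$boundary_S %*% nu))
  tibble(species = rownames(basis$boundary_S), rate = rates)
}

#' Extracellular environment of the red-cell model
#'
#' Typical blood concentrations are the defaults: glucose 5 mM, lactate 1 mM,
#' K 4 mM, Na 140 mM, CO2 1.2 mM.
#'
#' @param GLC,LAC,K,Na,CO2 Extracellular concentrations, mol/L, positive.
#' @return Named numeric vector of class `rbc_environment`.
#' @export
rbc_environment <- function(GLC = 5e-3, LAC = 1e-3, K = 4e-3, Na = 0.140,
                            CO2 = 1.2e-3) {
  x <- c(GLC = GLC, LAC = LAC, K = K, Na = Na, CO2 = CO2)
  if (any(!is.finite(x)) || any(x <= 0))
    abort("all five extracellular concentrations must be positive")
  structure(x, class = "rbc_environment")
}

#' Variational function of the extracellular medium
#'
#' The concentration-weighted squared perturbation that one operating cell
#' imposes on its surroundings:
#' \eqn{H_{ext} = \sum_s \dot x_s^2 / x_s} over the five extracellular
#' species. It is quadratic in the three free fluxes; the physiological
#' operating point minimizes it at fixed glucose uptake and shunt flux.
#'
#' @inheritParams hrbc_fluxes
#' @param env An `rbc_environment`.
#' @return Scalar `H_ext >= 0`.
#' @export
extracellular_H <- function(u_glc, u_dpgm, u_g6pdh, env = rbc_environment(),
                            basis = hrbc_free_flux_basis()) {
  rates <- hrbc_exchange_rates(u_glc, u_dpgm, u_g6pdh, basis)
  x <- unclass(env)[rates$species]
  sum(rates$rate^2 / x)
}

#' Optimal pentose-phosphate flux at fixed uptake and shunt flux
#'
#' Minimizing the extracellular variational function over `u_g6pdh` at fixed
#' (`u_glc`, `u_dpgm`) has the closed form
#' \deqn{u^*_{g6pdh} = a\,u_{glc} + b\,u_{dpgm},}
#' with, writing \eqn{W = 4/x_K + 9/x_{Na}} for the pump weight and
#' \eqn{D = 1/(9 x_{LAC}) + 1/x_{CO_2} + W/9},
#' \deqn{a = \frac{2/(3 x_{LAC}) + 2W/3}{D}, \qquad b = -\frac{W/3}{D}.}
#' Both are invariant under a common rescaling of the five concentrations.
#' When CO2 dominates (\eqn{x_{CO_2} \to \infty}), \eqn{a \to 6}: the pentose
#' phosphate pathway consumes essentially all of the glucose, the factor 6
#' reflecting the carbon stoichiometry of glucose and CO2.
#'
#' @param u_glc Glucose uptake (> 0).
#' @param u_dpgm Shunt flux.
#' @param env An `rbc_environment`.
#' @return One-row tibble with columns `u_g6pdh_opt`, `a`, `b`.
#' @export
optimal_g6pdh <- function(u_glc, u_dpgm = 0, env = rbc_environment()) {
  stopifnot(u_glc > 0)
  x <- unclass(env)
  W <- 4 / x[["K"]] + 9 / x[["Na"]]
  D <- 1 / (9 * x[["LAC"]]) + 1 / x[["CO2"]] + W / 9
  if (!is.finite(D) || D <= 0)
    abort("degenerate quadratic coefficient in the g6pdh optimum")
  a <- (2 / (3 * x[["LAC"]]) + 2 * W / 3) / D
  b <- -(W / 3) / D
  tibble(u_g6pdh_opt = a * u_glc + b * u_dpgm, a = a, b = b)
}

#' Fraction of glucose consumed through the pentose phosphate pathway
#'
#' \eqn{F = u_{g6pdh} / (6\,u_{glc})}: the G6PDH flux rescaled by its
#' carbon-stoichiometric maximum (all six glucose carbons released as CO2).
#' Values outside `[0, 1]` are reported via the `"clipped"` attribute.
#'
#' @param u_g6pdh Pentose-phosphate flux (vectorized).
#' @param u_glc Glucose uptake (> 0).
#' @return Numeric vector of fractions, attribute `"clipped"` marking entries
#'   outside `[0, 1]`.
#' @export
ppp_fraction <- function(u_g6pdh, u_glc) {
  if (any(u_glc <= 0)) abort("u_glc must be positive")
  f <- u_g6pdh / (6 * u_glc)
  structure(f, clipped = f < 0 | f > 1)
}

#' Range of the pentose-phosphate fraction over the admissible regime
#'
#' With the G6PDH flux at its optimum throughout, the shunt flux `u_dpgm` is
#' swept from 0 to its stoichiometric maximum — the largest value keeping the
#' physically one-way steps running forward (see `hrbc_forward_only()`;
#' near-equilibrium interconversions carry no prior direction and legitimately
#' reverse when the pentose phosphate pathway recycles fructose-6-phosphate).
#' Since the optimum decreases with the shunt flux (`b < 0`), the maximal
#' fraction is attained at `u_dpgm = 0` and the minimal one at the shunt
#' maximum.
#'
#' @param env An `rbc_environment`.
#' @param basis An `hrbc_basis` (computed if missing).
#' @param u_glc Glucose uptake normalizer (default 1; F is scale-invariant).
#' @return One-row tibble with `F_min`, `F_max`, `u_dpgm_max`, `a`, `b`.
#' @export
ppp_fraction_bounds <- function(env = rbc_environment(),
                                basis = hrbc_free_flux_basis(), u_glc = 1) {
  opt <- optimal_g6pdh(u_glc, 0, env)
  a <- opt$a; b <- opt$b
  # nu(u_dpgm) = c0 + c1 * u_dpgm with the optimal u_g6pdh substituted
  c0 <- drop(basis$B %*% c(u_glc, 0, a * u_glc))
  c1 <- drop(basis$B %*% c(0, 1, b))
  keep <- basis$reaction_id %in% hrbc_forward_only()
  dec <- keep & (c1 < -1e-12)
  u2_max <- if (any(dec)) min(-c0[dec] / c1[dec]) else Inf
  if (!is.finite(u2_max) || u2_max < 0)
    abort("admissible shunt range is empty or unbounded; check the environment")
  F_max <- as.numeric(ppp_fraction(a * u_glc, u_glc))
  F_min <- as.numeric(ppp_fraction(a * u_glc + b * u2_max, u_glc))
  tibble(F_min = F_min, F_max = F_max, u_dpgm_max = u2_max, a = a, b = b)
}

#' Physically one-way reactions of the red-cell model
#'
#' No prior reversibility assumption is placed on the near-equilibrium
#' interconversions (isomerases, aldolase, transketolase/transaldolase,
#' kinase-coupled steps); the admissible operating regime only requires
#' forward operation of the committed steps: glucose uptake (HK), the two
#' branch entries (DPGM + its phosphatase, the oxidative PPP G6PDH/PGLASE/
#' GO6PDH), lactate export (LDH) and the two pumps.
#'
#' @return Character vector of reaction ids.
#' @export
hrbc_forward_only <- function() {
  c("HK", "DPGM", "DPGASE", "G6PDH", "PGLASE", "GO6PDH", "LDH",
    "ATPASE", "NADPHASE")
}

#' Maximal CO2-export-to-glucose-uptake ratio
#'
#' Maximizes the extracellular CO2 rate per unit glucose uptake over the
#' admissible operating polygon (one-way steps forward, see
#' [hrbc_forward_only()]), by exact enumeration of the polygon vertices. For
#' the packaged network the maximum is 6 — all six glucose carbons released as
#' CO2, with lactate export driven to zero — the carbon stoichiometry of
#' glucose.
#'
#' @param basis An `hrbc_basis` (computed if missing).
#' @param big Bounding box for the vertex enumeration (default 100).
#' @return Scalar maximal ratio.
#' @export
hrbc_max_co2_ratio <- function(basis = hrbc_free_flux_basis(), big = 100) {
  # flux_j(u2, u6) = a0 + a1 u2 + a2 u6 at u_glc = 1; constraints flux_j >= 0
  a0 <- basis$B[, "u_glc"]
  a1 <- basis$B[, "u_dpgm"]
  a2 <- basis$B[, "u_g6pdh"]
  keep <- basis$reaction_id %in% hrbc_forward_only()
  cons <- cbind(a0, a1, a2)[keep, , drop = FALSE]
  cons <- rbind(cons,
                c(0, 1, 0), c(0, 0, 1),              # u2 >= 0, u6 >= 0
                c(big, -1, 0), c(big, 0, -1))        # bounding box
  co2 <- basis$boundary_S["CO2", ]
  obj <- c(sum(co2 * a0), sum(co2 * a1), sum(co2 * a2))
  best <- -Inf
  nc <- nrow(cons)
  for (i in seq_len(nc - 1L)) {
    for (j in seq(i + 1L, nc)) {
      Aij <- rbind(cons[i, 2:3], cons[j, 2:3])
      if (abs(det(Aij)) < 1e-12) next
      v <- solve(Aij, -c(cons[i, 1], cons[j, 1]))
      if (all(cons[, 1] + cons[, 2:3] %*% v >= -1e-8)) {
        val <- obj[1] + sum(obj[2:3] * v)
        if (val > best) best <- val
      }
    }
  }
  best
}
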