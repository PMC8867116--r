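# Quantities derived from the fitted rate constants: equilibrium
# occupancies, reverse transfer rates, van't Hoff thermodynamics, and the
# mismatch-fate analysis that converts the excision/extension competition
# into a net fidelity contribution.

R_GAS <- 8.314  # J / (mol K)

#' Equilibrium pol-site occupancy from the transfer equilibrium constant
#'
#' With `K3 = [ED_x]/[ED_p]`, the fraction of enzyme-bound DNA residing at
#' the polymerase site is `1/(1+K3)`.
#'
#' @param K3 Transfer equilibrium constant (> 0).
#' @return Percentage in (0, 100).
#' @export
pol_site_occupancy <- function(K3) {
  stopifnot(is.numeric(K3), all(K3 > 0))
  100 / (1 + K3)
}

#' Reverse (exo-to-pol) transfer rate from k3 and K3
#'
#' @param k3 Forward pol-to-exo transfer rate, s^-1.
#' @param K3 Transfer equilibrium constant (> 0).
#' @return `k3 / K3`, s^-1.
#' @export
reverse_transfer_rate <- function(k3, K3) {
  stopifnot(is.numeric(k3), is.numeric(K3), all(K3 > 0))
  k3 / K3
}

#' Fold change between two equilibrium constants
#'
#' @param K_a,K_b Equilibrium constants (`K_b > 0`).
#' @return `K_a / K_b`.
#' @export
fold_change <- function(K_a, K_b) {
  stopifnot(is.numeric(K_a), is.numeric(K_b), all(K_b > 0))
  K_a / K_b
}

#' Two-temperature van't Hoff analysis of an equilibrium constant
#'
#' Standard free energy at the higher temperature,
#' `dG = -R T ln K`, and enthalpy from the two-point van't Hoff relation,
#' `dH = R ln(K_high/K_low) / (1/T_low - 1/T_high)`.  The forward
#' direction of the equilibrium fixes all signs.
#'
#' @param K_low,K_high Equilibrium constants at the two temperatures (> 0).
#' @param T_low,T_high Absolute temperatures in K (distinct).
#' @return A `thermo_result`: list with `delta_G_kJ` (at `T_high`),
#'   `delta_H_kJ`, `delta_S_J` (per K, from dG = dH - T dS), the inputs.
#' @export
vant_hoff <- function(K_low, T_low, K_high, T_high) {
  stopifnot(K_low > 0, K_high > 0, T_low > 0, T_high > 0, T_low != T_high)
  dG <- -R_GAS * T_high * log(K_high) / 1000
  dH <- R_GAS * log(K_high / K_low) / (1 / T_low - 1 / T_high) / 1000
  dS <- (dH - dG) * 1000 / T_high
  structure(list(delta_G_kJ = dG, delta_H_kJ = dH, delta_S_J = dS,
                 K_values = c(K_low, K_high),
                 temperatures_K = c(T_low, T_high)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("dG = %.3g kJ/mol at %.2f K; dH = %.3g kJ/mol; dS = %.3g J/mol/K\n",
              x$delta_G_kJ, x$temperatures_K[2], x$delta_H_kJ, x$delta_S_J))
  invisible(x)
}

#' Celsius to Kelvin for the standard experimental temperatures
#' @param celsius Temperature in degrees C.
#' @return Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

# Absorbing probabilities of a purely unimolecular scheme by linear
# algebra on the embedded jump chain: for transient states with generator
# Q partitioned as (T | R), B = (-Q_TT)^-1 Q_TR gives the probability of
# ending in each absorbing state from each transient start.
jump_chain_absorption <- function(scheme) {
  mats <- scheme_matrices(scheme)
  if (any(mats$r2 >= 0))
    stop("jump-chain route requires a unimolecular scheme")
  n <- length(scheme$species)
  Q <- matrix(0, n, n, dimnames = list(scheme$species, scheme$species))
  for (j in seq_along(mats$k)) {
    r <- scheme$reactions[[j]]
    from <- r$reactants
    for (p in r$products) Q[from, p] <- Q[from, p] + r$rate_constant
    Q[from, from] <- Q[from, from] - r$rate_constant
  }
  absorbing <- rowSums(abs(Q)) == 0
  if (!any(absorbing)) stop("scheme has no absorbing state")
  trans <- !absorbing
  B <- solve(-Q[trans, trans, drop = FALSE], Q[trans, absorbing, drop = FALSE])
  start <- scheme$init[trans] / sum(scheme$init)
  drop(start %*% B)
}

#' Fate of a mismatched primer: excision versus stable burial
#'
#' Computes the absorbing probabilities of the composite fate scheme (see
#' [build_fate_scheme()]) by two independent routes -- stiff ODE
#' integration to absorption and branch-probability algebra on the
#' embedded jump chain -- and requires them to agree within `tol`
#' (absolute, on the probability scale).
#'
#' @param scheme A fate `kinetic_scheme` from [build_fate_scheme()].
#' @param tol Cross-route agreement tolerance.
#' @return A `fate_report`: percentages `fraction_excised` (excised while
#'   terminal), `fraction_extended_once` (extended once, then excised),
#'   `fraction_buried`, plus `contribution_factor` and the per-route
#'   values.
#' @export
mismatch_fate <- function(scheme, tol = 1e-4) {
  prod_sp <- names(scheme$roles)[scheme$roles == "absorbing-product"]
  if (length(prod_sp) < 2) stop("fate scheme needs its absorbing states")
  # Route 1: jump chain.
  chain <- jump_chain_absorption(scheme)
  # Route 2: ODE to absorption.  The transient pool drains at the scale of
  # the slowest transfer rate; expand the horizon until < 1e-10 remains.
  total <- sum(scheme$init)
  t <- 1
  repeat {
    tr <- integrate_scheme(scheme, times = t, rtol = 1e-10, atol = 1e-16)
    y <- tr$conc[, 1]
    left <- total - sum(y[prod_sp])
    if (left < 1e-10 * total || t > 1e8) break
    t <- t * 10
  }
  ode <- y[prod_sp] / total
  chain <- chain[prod_sp]
  if (max(abs(ode - chain)) > tol)
    stop("internal consistency failure: ODE and jump-chain absorption ",
         "probabilities disagree beyond tolerance (max diff ",
         format(max(abs(ode - chain)), digits = 3), ")")
  frac <- function(v) c(excised = unname(v["excised_n0"]),
                        extended_once = unname(v["excised_n1"]),
                        buried = unname(v["buried"])) * 100
  f_ode <- frac(ode); f_chain <- frac(chain)
  is_lim <- attr(scheme, "extension_is_limit")
  report <- structure(list(
    fraction_excised = f_ode[["excised"]],
    fraction_extended_once = f_ode[["extended_once"]],
    fraction_buried = f_ode[["buried"]],
    routes = list(ode = f_ode, jump_chain = f_chain),
    buried_is_upper_limit = isTRUE(any(is_lim))),
    class = "fate_report")
  report$contribution_factor <- contribution_factor(report)
  report
}

#' @export
print.fate_report <- function(x, ...) {
  cat(sprintf("Mismatch fate: %.4g%% excised, %.4g%% extended once then excised,\n",
              x$fraction_excised, x$fraction_extended_once))
  cat(sprintf("  %.3g%% buried%s; proofreading contribution %s%.3g-fold\n",
              x$fraction_buried,
              if (x$buried_is_upper_limit) " (upper limit)" else "",
              if (x$buried_is_upper_limit) ">= " else "",
              x$contribution_factor))
  invisible(x)
}

#' Net fidelity contribution factor from a fate report
#'
#' The fold reduction in stably incorporated errors attributable to
#' proofreading: the reciprocal of the buried fraction,
#' `100 / fraction_buried(%)`.  When the extension inputs were upper
#' limits the factor is a lower bound (reported with attribute
#' `bound = ">="`).
#'
#' @param report A `fate_report`.
#' @return Fold factor (>= 1), possibly with a `bound` attribute.
#' @export
contribution_factor <- function(report) {
  fb <- report$fraction_buried
  if (fb <= 0)
    return(structure(Inf, bound = ">=",
                     note = "no burial observed; factor unbounded"))
  out <- 100 / fb
  if (isTRUE(report$buried_is_upper_limit)) attr(out, "bound") <- ">="
  out
}
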