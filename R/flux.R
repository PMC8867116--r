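# Integrated flux partitioning between competing branches of a kinetic
# network.  One-way flux of a reaction is the time integral of its forward
# mass-action rate; net flux subtracts the paired reverse reaction.  Both
# are accumulated inside the stiff integrator alongside the species so no
# post-hoc quadrature is involved.

# Time at which a scheme's reaction is essentially complete: the remaining
# reactive DNA (free + complexed, excluding material parked in dead-end
# states with no outflow) has decayed to (1 - frac) of its reachable
# extent.  Implemented as integration on an expanding horizon.
reaction_complete_time <- function(scheme, frac = 0.99, tmax = 1e6) {
  pools <- species_pools(scheme)
  prod <- scheme$roles == "absorbing-product"
  t <- 1
  total <- sum(scheme$init * pools$dna)
  end_prod <- NA_real_
  # First find the plateau of product formation, then the time to reach
  # frac of it.
  repeat {
    tr <- integrate_scheme(scheme, times = c(t / 2, t))
    p2 <- sum(tr$conc[prod, 2])
    p1 <- sum(tr$conc[prod, 1])
    if ((p2 - p1) < 1e-6 * max(total, 1e-12) || t >= tmax) {
      end_prod <- p2
      break
    }
    t <- t * 4
  }
  if (end_prod <= 0) return(t)
  target <- frac * end_prod
  lo <- 0; hi <- t
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    pm <- sum(integrate_scheme(scheme, times = mid)$conc[prod, 1])
    if (pm < target) lo <- mid else hi <- mid
  }
  hi
}

resolve_horizon <- function(scheme, horizon) {
  if (identical(horizon, "reaction-complete"))
    reaction_complete_time(scheme) else {
      stopifnot(is.numeric(horizon), horizon > 0)
      horizon
    }
}

find_edge <- function(scheme, from, to) {
  hits <- Filter(function(r) identical(r$reactants, from) ||
                   (length(r$reactants) == 2 && from %in% r$reactants &&
                      to %in% r$products) ,
                 scheme$reactions)
  hits <- Filter(function(r) to %in% r$products, hits)
  if (!length(hits))
    stop("no reaction from '", from, "' to '", to, "' in scheme")
  hits[[1]]
}

#' Time-integrated flux through one edge of the network
#'
#' @param scheme A `kinetic_scheme`.
#' @param from,to Species names identifying the reaction (the reaction
#'   consuming `from` and producing `to`).
#' @param mode `"one-way"` integrates the forward rate only; `"net"`
#'   subtracts the reverse reaction (to -> from) when one exists.
#' @param horizon Seconds, or `"reaction-complete"` (time to 99% of the
#'   reachable product endpoint).
#' @param protocol Optional protocol passed to [integrate_scheme()].
#' @return Integrated flux in uM.
#' @export
integrated_flux <- function(scheme, from, to, mode = c("one-way", "net"),
                            horizon = "reaction-complete", protocol = NULL) {
  mode <- match.arg(mode)
  fwd <- find_edge(scheme, from, to)
  labels <- fwd$label
  rev_lab <- NULL
  if (mode == "net") {
    rev <- tryCatch(find_edge(scheme, to, from), error = function(e) NULL)
    if (!is.null(rev)) rev_lab <- rev$label
  }
  h <- resolve_horizon(scheme, horizon)
  if (is.null(protocol)) protocol <- default_protocol(scheme)
  tr <- integrate_scheme(scheme, times = h, protocol = protocol,
                         track_flux = c(labels, rev_lab))
  f <- tr$flux[labels, 1]
  if (!is.null(rev_lab)) f <- f - tr$flux[rev_lab, 1]
  unname(f)
}

new_flux_partition <- function(from, a, b, pa, mode, horizon) {
  structure(list(from_state = from, branch_a = a, branch_b = b,
                 percent_a = pa, percent_b = 100 - pa,
                 mode = mode, horizon = horizon),
            class = "flux_partition")
}

#' @export
print.flux_partition <- function(x, ...) {
  cat(sprintf("Flux partition from %s: %.4g%% -> %s, %.4g%% -> %s (%s)\n",
              x$from_state, x$percent_a, x$branch_a, x$percent_b, x$branch_b,
              x$mode))
  if (!is.null(attr(x, "notice"))) cat("note:", attr(x, "notice"), "\n")
  invisible(x)
}

#' Partitioning of DNA binding between the exo and pol sites
#'
#' Percentage of DNA binding events that go directly to the exonuclease
#' site: `100 * D::ED_x / (D::ED_x + D::ED_p)` with one-way integrated
#' fluxes.
#'
#' @param scheme A proofreading `kinetic_scheme` (must contain both
#'   binding branches).
#' @param mode,horizon See [integrated_flux()].
#' @return A `flux_partition` (branch a = direct exo-site binding).
#' @export
binding_partition <- function(scheme, mode = "one-way",
                              horizon = "reaction-complete") {
  h <- resolve_horizon(scheme, horizon)
  fx <- integrated_flux(scheme, "D", "ED_x", mode = mode, horizon = h)
  fp <- integrated_flux(scheme, "D", "ED_p", mode = mode, horizon = h)
  if (fx + fp <= 0) stop("undefined partition: zero total binding flux")
  new_flux_partition("D", "ED_x", "ED_p", 100 * fx / (fx + fp), mode, h)
}

#' Partitioning of the pol-site complex between transfer and inhibition
#'
#' Percentage of ED_p outflow reaching the exo site versus the inhibited
#' state: `100 * ED_p::ED_x / (ED_p::ED_x + ED_p::ED_I)`.  When the
#' inhibited-state branch is absent the partition is reported as 100% to
#' ED_x with a notice attribute.
#'
#' @inheritParams binding_partition
#' @return A `flux_partition` (branch a = transfer to ED_x).
#' @export
edp_partition <- function(scheme, mode = "one-way",
                          horizon = "reaction-complete") {
  if (!"ED_I" %in% scheme$species) {
    out <- new_flux_partition("ED_p", "ED_x", "ED_I", 100, mode, horizon)
    attr(out, "notice") <- "inhibited-state branch absent; all outflow to ED_x"
    return(out)
  }
  h <- resolve_horizon(scheme, horizon)
  fx <- integrated_flux(scheme, "ED_p", "ED_x", mode = mode, horizon = h)
  fi <- integrated_flux(scheme, "ED_p", "ED_I", mode = mode, horizon = h)
  if (fx + fi <= 0) stop("undefined partition: zero total ED_p outflow")
  new_flux_partition("ED_p", "ED_x", "ED_I", 100 * fx / (fx + fi), mode, h)
}

#' Serialize a flux partition (JSON, with mode/horizon provenance)
#'
#' @param x A `flux_partition`.
#' @param path Optional output path.
#' @return JSON string.
#' @export
flux_to_json <- function(x, path = NULL) {
  obj <- unclass(x)
  obj$notice <- attr(x, "notice")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (!is.null(path)) writeLines(js, path)
  js
}
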