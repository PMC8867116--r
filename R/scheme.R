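#' @useDynLib exokin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames rexp
#' @importFrom utils packageVersion read.delim write.table
NULL

SPECIES_ROLES <- c("free-DNA", "free-enzyme", "complex", "absorbing-product")

#' Declare a chemical species
#'
#' @param name Short unique label, e.g. `"ED_p"`.
#' @param role One of `"free-DNA"`, `"free-enzyme"`, `"complex"`,
#'   `"absorbing-product"`.  The role determines which conservation pools
#'   (DNA, enzyme) the species belongs to and how observables are assembled.
#' @return A `kin_species` object.
#' @export
kin_species <- function(name, role) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, SPECIES_ROLES)
  structure(list(name = name, role = role), class = "kin_species")
}

#' Declare an elementary mass-action reaction
#'
#' A reversible step is represented as two `kin_reaction` records.
#'
#' @param reactants Character vector of 1 or 2 species names.
#' @param products Character vector of 1 or 2 species names.
#' @param rate_constant Non-negative rate constant; s^-1 for unimolecular
#'   steps, uM^-1 s^-1 for bimolecular steps.
#' @param label Symbol name of the rate constant (e.g. `"k3"`).
#' @return A `kin_reaction` object.  The unit tag is derived from the
#'   reactant count and stored for validation.
#' @export
kin_reaction <- function(reactants, products, rate_constant, label) {
  stopifnot(is.character(reactants), length(reactants) %in% 1:2,
            is.character(products), length(products) %in% 1:2,
            is.numeric(rate_constant), length(rate_constant) == 1L,
            is.character(label), length(label) == 1L)
  if (!is.finite(rate_constant) || rate_constant < 0)
    stop("rate constant for '", label, "' must be finite and >= 0")
  structure(list(reactants = reactants, products = products,
                 rate_constant = as.numeric(rate_constant), label = label,
                 unit = if (length(reactants) == 2L) "uM^-1 s^-1" else "s^-1"),
            class = "kin_reaction")
}

#' Assemble a kinetic scheme
#'
#' @param species List of [kin_species()] objects; names must be unique.
#' @param reactions List of [kin_reaction()] objects referencing declared
#'   species only.
#' @param initial_conditions Named numeric vector, uM.  Species omitted
#'   start at 0.
#' @param preequilibrate Optional character vector of reaction labels to
#'   disable during a pre-equilibration phase run before t = 0 (used by the
#'   extension protocol where nucleotide is added after binding
#'   equilibration).  `NULL` means no pre-equilibration.
#' @return A `kinetic_scheme` object.
#' @export
kinetic_scheme <- function(species, reactions, initial_conditions,
                           preequilibrate = NULL) {
  nm <- vapply(species, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("species names must be unique")
  roles <- vapply(species, function(s) s$role, "")
  for (r in reactions) {
    bad <- setdiff(c(r$reactants, r$products), nm)
    if (length(bad))
      stop("reaction '", r$label, "' references undeclared species: ",
           paste(bad, collapse = ", "))
  }
  ic <- setNames(numeric(length(nm)), nm)
  if (length(initial_conditions)) {
    stopifnot(!is.null(names(initial_conditions)))
    bad <- setdiff(names(initial_conditions), nm)
    if (length(bad)) stop("initial condition for unknown species: ",
                          paste(bad, collapse = ", "))
    if (any(initial_conditions < 0)) stop("initial concentrations must be >= 0")
    ic[names(initial_conditions)] <- initial_conditions
  }
  sch <- structure(list(species = nm, roles = setNames(roles, nm),
                        reactions = reactions, init = ic,
                        preequilibrate = preequilibrate),
                   class = "kinetic_scheme")
  audit_stoichiometry(sch)
  sch
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  for (r in x$reactions)
    cat(sprintf("  %-6s %s -> %s  (%g %s)\n", r$label,
                paste(r$reactants, collapse = " + "),
                paste(r$products, collapse = " + "),
                r$rate_constant, r$unit))
  invisible(x)
}

# Species-level pool membership used by the conservation audit and by
# observables: every DNA-containing species counts once toward the DNA
# pool, complexes also count toward the enzyme pool.
species_pools <- function(scheme) {
  dna <- scheme$roles %in% c("free-DNA", "complex", "absorbing-product")
  enz <- scheme$roles %in% c("free-enzyme", "complex")
  list(dna = setNames(as.numeric(dna), scheme$species),
       enzyme = setNames(as.numeric(enz), scheme$species))
}

#' Audit conservation of DNA and enzyme in every reaction
#'
#' Each elementary reaction must conserve the count of DNA-containing and
#' enzyme-containing entities.  Called automatically by [kinetic_scheme()].
#'
#' @param scheme A `kinetic_scheme`.
#' @return Invisibly `TRUE`; stops with an error on imbalance.
#' @export
audit_stoichiometry <- function(scheme) {
  pools <- species_pools(scheme)
  # The enzyme pool is audited only when free enzyme is modelled
  # explicitly; reduced schemes (extension, fate) keep the enzyme
  # implicit in every state.
  if (!any(scheme$roles == "free-enzyme")) pools$enzyme <- NULL
  for (r in scheme$reactions) {
    for (p in names(pools)) {
      d <- sum(pools[[p]][r$products]) - sum(pools[[p]][r$reactants])
      if (abs(d) > 0)
        stop("reaction '", r$label, "' does not conserve the ", p, " pool")
    }
  }
  invisible(TRUE)
}

# Numeric form used by the integrator: stoichiometry matrix, reactant index
# vectors (0-based, -1 = absent), rate vector.
scheme_matrices <- function(scheme) {
  n <- length(scheme$species)
  m <- length(scheme$reactions)
  S <- matrix(0, n, m, dimnames = list(scheme$species, NULL))
  r1 <- integer(m); r2 <- integer(m); k <- numeric(m)
  for (j in seq_len(m)) {
    r <- scheme$reactions[[j]]
    for (s in r$reactants) S[s, j] <- S[s, j] - 1
    for (s in r$products) S[s, j] <- S[s, j] + 1
    idx <- match(r$reactants, scheme$species) - 1L
    r1[j] <- idx[1]
    r2[j] <- if (length(idx) == 2L) idx[2] else -1L
    k[j] <- r$rate_constant
  }
  list(S = S, r1 = r1, r2 = r2, k = k,
       labels = vapply(scheme$reactions, function(r) r$label, ""))
}

#' Parameter set for the pol/exo partitioning (proofreading) scheme
#'
#' The named rate constants of the branched excision mechanism.  DNA binds
#' either at the polymerase site (`k1`) or directly at the exonuclease site
#' (`k2`); bound DNA transfers intramolecularly between the two sites
#' (`k3`, with equilibrium constant `K3 = [ED_x]/[ED_p]`, so the reverse
#' rate is always derived as `k3/K3`); DNA at the exo site is hydrolysed at
#' `k_exo`; an off-pathway inhibited complex `ED_I` (present when `k4`
#' and `k_minus4` are supplied) accounts for incomplete reaction endpoints.
#'
#' @param k2 Direct exo-site binding, uM^-1 s^-1.
#' @param k3 pol-to-exo transfer, s^-1.
#' @param K3 Transfer equilibrium constant (unitless, > 0 when `k3 > 0`).
#' @param k4,k_minus4 ED_p <-> ED_I interconversion, s^-1, or `NULL` when
#'   the inhibited-state branch is absent from the model ("-" table cells).
#' @param k1 pol-site binding, uM^-1 s^-1 (locked at 300 by convention).
#' @param k_minus1,k_minus2 Dissociation rates, s^-1 (locked at 0.2).
#' @param k_exo Exo-site hydrolysis, s^-1 (locked at 1000).
#' @return A `proofreading_params` object.
#' @export
proofreading_params <- function(k2, k3, K3, k4 = NULL, k_minus4 = NULL,
                                k1 = 300, k_minus1 = 0.2, k_minus2 = 0.2,
                                k_exo = 1000) {
  ed_i <- !is.null(k4)
  if (ed_i && is.null(k_minus4)) k_minus4 <- 0
  if (!ed_i && !is.null(k_minus4))
    stop("k_minus4 given without k4; supply both or neither")
  if (k3 > 0 && (is.null(K3) || is.na(K3) || K3 <= 0))
    stop("K3 must be > 0 when k3 > 0")
  vals <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
            k3 = k3, K3 = K3, k_exo = k_exo)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("invalid rate constants")
  structure(list(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
                 k3 = k3, K3 = K3, k_exo = k_exo,
                 k4 = if (ed_i) k4, k_minus4 = if (ed_i) k_minus4,
                 ed_i_present = ed_i),
            class = "proofreading_params")
}

#' Parameter set for the two-step mismatch extension scheme
#'
#' An initial collision complex `ED` isomerises (`k1_prime`/`k_minus1_prime`)
#' into the pol-site complex `ED_p` primed for polymerization, which extends
#' the primer at the observed rate `k_pol` (at the experiment's dNTP
#' concentration).  The fraction primed for polymerization is
#' `k1_prime / (k1_prime + k_minus1_prime)`.
#'
#' @param k1_prime,k_minus1_prime Isomerisation rates, s^-1.
#' @param k_pol Observed extension rate, s^-1.
#' @param dntp_conc Annotation only: dNTP concentration, uM.
#' @return An `extension_params` object.
#' @export
extension_params <- function(k1_prime, k_minus1_prime, k_pol,
                             dntp_conc = 500) {
  vals <- c(k1_prime, k_minus1_prime, k_pol)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("invalid rate constants")
  fp <- if (k1_prime + k_minus1_prime > 0)
    k1_prime / (k1_prime + k_minus1_prime) else NA_real_
  structure(list(k1_prime = k1_prime, k_minus1_prime = k_minus1_prime,
                 k_pol = k_pol, dntp_conc = dntp_conc, fraction_primed = fp),
            class = "extension_params")
}

#' Steady-state extension kinetics of a (buried-)mismatch substrate
#'
#' Exactly one of `{kcat, Km}` or `kcat_over_Km_limit` must be given: the
#' former for a measured Michaelis-Menten extension, the latter for an
#' upper bound inferred from the absence of detectable product.
#'
#' @param kcat Turnover, s^-1.
#' @param Km Michaelis constant, uM.
#' @param kcat_over_Km_limit Upper bound on kcat/Km, M^-1 s^-1.
#' @return A `mismatch_extension_kinetics` object.
#' @export
mismatch_extension_kinetics <- function(kcat = NULL, Km = NULL,
                                        kcat_over_Km_limit = NULL) {
  measured <- !is.null(kcat)
  if (measured && is.null(Km)) stop("Km required with kcat")
  if (measured == !is.null(kcat_over_Km_limit))
    stop("give exactly one of {kcat & Km} or kcat_over_Km_limit")
  structure(list(kcat = kcat, Km = Km,
                 kcat_over_Km_limit = kcat_over_Km_limit,
                 is_limit = !measured),
            class = "mismatch_extension_kinetics")
}

#' First-order extension rate implied by extension kinetics at a given
#' dNTP concentration
#'
#' Measured kinetics give `kcat * [dNTP] / (Km + [dNTP])`; a kcat/Km upper
#' limit gives `limit * [dNTP]` (the low-substrate regime the bound was
#' derived in).
#'
#' @param ext A [mismatch_extension_kinetics()] object.
#' @param dntp_conc_uM dNTP concentration in uM, or `"saturating"` to use
#'   `kcat` directly (only valid for measured kinetics).
#' @return Rate in s^-1, with attribute `is_limit`.
#' @export
extension_rate <- function(ext, dntp_conc_uM) {
  stopifnot(inherits(ext, "mismatch_extension_kinetics"))
  if (identical(dntp_conc_uM, "saturating")) {
    if (ext$is_limit)
      stop("saturating rate undefined for a kcat/Km limit; give a concentration")
    r <- ext$kcat
  } else {
    stopifnot(is.numeric(dntp_conc_uM), dntp_conc_uM >= 0)
    r <- if (ext$is_limit) {
      ext$kcat_over_Km_limit * dntp_conc_uM * 1e-6  # M^-1 s^-1 * M
    } else {
      ext$kcat * dntp_conc_uM / (ext$Km + dntp_conc_uM)
    }
  }
  if (!is.finite(r)) stop("extension rate not resolvable")
  structure(r, is_limit = ext$is_limit)
}

#' Build the branched pol/exo partitioning scheme
#'
#' Species: free enzyme `E`, free DNA `D`, pol-site complex `ED_p`,
#' exo-site complex `ED_x`, optional inhibited complex `ED_I`, and the
#' hydrolysed product `P` (the reaction starts on mixing, so all material
#' starts free).  Hydrolysis is a single exit step `ED_x -> E + P` at
#' `k_exo`; the processive excision ladder is not tracked because the
#' observable is loss of the intact starting primer.
#'
#' @param params A [proofreading_params()] object.
#' @param conc_E,conc_D Enzyme and DNA mixing concentrations, uM (> 0).
#' @return A `kinetic_scheme`.
#' @export
build_proofreading_scheme <- function(params, conc_E, conc_D) {
  stopifnot(inherits(params, "proofreading_params"))
  if (!is.numeric(conc_E) || !is.numeric(conc_D) || conc_E <= 0 || conc_D <= 0)
    stop("concentrations must be > 0")
  p <- params
  k_minus3 <- if (p$k3 > 0) p$k3 / p$K3 else 0
  species <- list(
    kin_species("E", "free-enzyme"),
    kin_species("D", "free-DNA"),
    kin_species("ED_p", "complex"),
    kin_species("ED_x", "complex"),
    kin_species("P", "absorbing-product"))
  reactions <- list(
    kin_reaction(c("E", "D"), "ED_p", p$k1, "k1"),
    kin_reaction("ED_p", c("E", "D"), p$k_minus1, "k-1"),
    kin_reaction(c("E", "D"), "ED_x", p$k2, "k2"),
    kin_reaction("ED_x", c("E", "D"), p$k_minus2, "k-2"),
    kin_reaction("ED_p", "ED_x", p$k3, "k3"),
    kin_reaction("ED_x", "ED_p", k_minus3, "k-3"),
    kin_reaction("ED_x", c("E", "P"), p$k_exo, "k_exo"))
  if (p$ed_i_present) {
    species <- append(species, list(kin_species("ED_I", "complex")), after = 4L)
    reactions <- c(reactions, list(
      kin_reaction("ED_p", "ED_I", p$k4, "k4"),
      kin_reaction("ED_I", "ED_p", p$k_minus4, "k-4")))
  }
  kinetic_scheme(species, reactions,
                 c(E = conc_E, D = conc_D))
}

#' Build the two-step mismatch extension scheme
#'
#' Species: collision complex `ED`, primed pol-site complex `ED_p`, and the
#' extended product `P_ext`.  The scheme is flagged for pre-equilibration:
#' the engine equilibrates `ED <-> ED_p` with `k_pol` disabled (the
#' preincubation before nucleotide addition) and then enables extension at
#' t = 0.
#'
#' @param params An [extension_params()] object.
#' @param conc_E Enzyme concentration, uM (annotation; enzyme is in excess
#'   and all DNA is bound in the collision complex at the start).
#' @param conc_D DNA concentration, uM (> 0).
#' @return A `kinetic_scheme`.
#' @export
build_extension_scheme <- function(params, conc_E = 0.2, conc_D = 0.075) {
  stopifnot(inherits(params, "extension_params"))
  if (conc_D <= 0) stop("concentrations must be > 0")
  p <- params
  species <- list(
    kin_species("ED", "complex"),
    kin_species("ED_p", "complex"),
    kin_species("P_ext", "absorbing-product"))
  reactions <- list(
    kin_reaction("ED", "ED_p", p$k1_prime, "k1'"),
    kin_reaction("ED_p", "ED", p$k_minus1_prime, "k-1'"),
    kin_reaction("ED_p", "P_ext", p$k_pol, "k_pol"))
  # Degenerate case (no isomerisation step modelled): all DNA starts in
  # the primed complex, otherwise in the collision complex.
  init <- if (p$k1_prime == 0 && p$k_minus1_prime == 0)
    c(ED_p = conc_D) else c(ED = conc_D)
  kinetic_scheme(species, reactions, init, preequilibrate = "k_pol")
}

#' Build the composite mismatch-fate scheme
#'
#' Chains the excision-vs-extension competition for a terminal mismatch
#' (n-0) and the once-extended (n-1 buried) mismatch.  Each stage contains
#' the pol-site complex and exo-site complex with that substrate's transfer
#' kinetics; the exo-site complex exits irreversibly to `excised` at
#' `k_exo`, while the pol-site complex extends at the first-order rate
#' implied by that stage's extension kinetics.  Extension of the n-1 stage
#' reaches the absorbing state `buried`.  Binding/dissociation and the
#' inhibited state are omitted: on the fate timescale dissociated DNA
#' rebinds and `ED_I` drains back to `ED_p`, so neither changes the
#' absorbing probabilities.
#'
#' @param excision_n0,excision_n1 [proofreading_params()] for the terminal
#'   and n-1 buried mismatch.
#' @param ext_n0,ext_n1 [mismatch_extension_kinetics()] for the two stages.
#' @param dntp_n0,dntp_n1 dNTP assumption per stage: a concentration in uM
#'   or `"saturating"`.  Defaults: saturating for the measured terminal
#'   step, 1000 uM (the experimental ceiling) for the limit-only n-1 step.
#' @return A `kinetic_scheme` with absorbing species `excised_n0`,
#'   `excised_n1` and `buried`; all material starts in `EDp_n0`.
#' @export
build_fate_scheme <- function(excision_n0, excision_n1, ext_n0, ext_n1,
                              dntp_n0 = "saturating", dntp_n1 = 1000) {
  stopifnot(inherits(excision_n0, "proofreading_params"),
            inherits(excision_n1, "proofreading_params"))
  r_ext0 <- extension_rate(ext_n0, dntp_n0)
  r_ext1 <- extension_rate(ext_n1, dntp_n1)
  stage <- function(p, tag) {
    km3 <- if (p$k3 > 0) p$k3 / p$K3 else 0
    list(
      species = list(kin_species(paste0("EDp_", tag), "complex"),
                     kin_species(paste0("EDx_", tag), "complex")),
      reactions = list(
        kin_reaction(paste0("EDp_", tag), paste0("EDx_", tag), p$k3,
                     paste0("k3_", tag)),
        kin_reaction(paste0("EDx_", tag), paste0("EDp_", tag), km3,
                     paste0("k-3_", tag)),
        kin_reaction(paste0("EDx_", tag), paste0("excised_", tag), p$k_exo,
                     paste0("k_exo_", tag))))
  }
  s0 <- stage(excision_n0, "n0")
  s1 <- stage(excision_n1, "n1")
  species <- c(s0$species, s1$species,
               list(kin_species("excised_n0", "absorbing-product"),
                    kin_species("excised_n1", "absorbing-product"),
                    kin_species("buried", "absorbing-product")))
  reactions <- c(s0$reactions, s1$reactions, list(
    kin_reaction("EDp_n0", "EDp_n1", as.numeric(r_ext0), "k_ext_n0"),
    kin_reaction("EDp_n1", "buried", as.numeric(r_ext1), "k_ext_n1")))
  sch <- kinetic_scheme(species, reactions, c(EDp_n0 = 1))
  attr(sch, "extension_is_limit") <-
    c(n0 = isTRUE(attr(r_ext0, "is_limit")), n1 = isTRUE(attr(r_ext1, "is_limit")))
  sch
}

#' Serialize a kinetic scheme to JSON
#'
#' Lossless round trip with [scheme_from_json()].
#'
#' @param scheme A `kinetic_scheme`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  obj <- list(
    species = lapply(seq_along(scheme$species), function(i)
      list(name = scheme$species[i], role = unname(scheme$roles[i]))),
    reactions = lapply(scheme$reactions, function(r)
      list(label = r$label, reactants = as.list(r$reactants),
           products = as.list(r$products), rate_constant = r$rate_constant)),
    initial_conditions = as.list(scheme$init),
    preequilibrate = as.list(scheme$preequilibrate))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a kinetic scheme from JSON
#'
#' @param x JSON string or path to a JSON file written by [scheme_to_json()].
#' @return A `kinetic_scheme`.
#' @export
scheme_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  species <- lapply(obj$species, function(s) kin_species(s$name, s$role))
  reactions <- lapply(obj$reactions, function(r)
    kin_reaction(unlist(r$reactants), unlist(r$products),
                 r$rate_constant, r$label))
  ic <- unlist(obj$initial_conditions)
  pre <- if (length(obj$preequilibrate)) unlist(obj$preequilibrate) else NULL
  kinetic_scheme(species, reactions, ic, preequilibrate = pre)
}
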