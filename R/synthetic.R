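# Synthetic quench-flow data generator.  Noiseless means come straight
# from the deterministic engine; measurement noise is Gaussian with a
# proportional component plus a small floor (quadrature-combined),
# truncated at zero, which is the simplest model consistent with
# quench-flow/capillary-electrophoresis quantification.

#' Measurement noise model
#'
#' @param proportional_sd SD as a fraction of the mean (default 0.05).
#' @param floor_sd Additive SD floor in uM (default 0.002).
#' @return A `noise_model` object.
#' @export
noise_model <- function(proportional_sd = 0.05, floor_sd = 0.002) {
  stopifnot(proportional_sd >= 0, floor_sd >= 0)
  structure(list(proportional_sd = proportional_sd, floor_sd = floor_sd),
            class = "noise_model")
}

apply_noise <- function(mu, noise) {
  sd <- sqrt((noise$proportional_sd * mu)^2 + noise$floor_sd^2)
  pmax(mu + rnorm(length(mu), 0, sd), 0)
}

#' Declare a synthetic experiment design
#'
#' @param table,row Fixture reference (see [fixtures()]).
#' @param conc_E,conc_D Enzyme and DNA concentrations, uM.  Defaults
#'   follow the experimental conditions: excision 1 uM enzyme with 0.25 uM
#'   DNA at 20 C (0.2 uM at 4 C), extension 0.2 uM enzyme with 0.075 uM
#'   DNA.
#' @param temperature_C Temperature label.
#' @param times Sampling grid, s (default [default_time_grid()]).
#' @param replicates Number of replicate time courses.
#' @param noise A [noise_model()]; `noise_model(0, 0)` for noiseless data.
#' @param seed Integer seed; the same design and seed give an identical
#'   dataset.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(table, row, conc_E = NULL, conc_D = NULL,
                              temperature_C = NULL, times = NULL,
                              replicates = 1L, noise = noise_model(),
                              seed = 1L) {
  kind <- if (table == "extension") "extension" else "excision"
  if (is.null(temperature_C))
    temperature_C <- if (table == "excision_4C") 4 else 20
  if (is.null(conc_E)) conc_E <- if (kind == "excision") 1 else 0.2
  if (is.null(conc_D))
    conc_D <- if (kind == "extension") 0.075
              else if (temperature_C == 4) 0.2 else 0.25
  if (is.null(times)) times <- default_time_grid(kind)
  structure(list(table = table, row = row, kind = kind,
                 conc_E = conc_E, conc_D = conc_D,
                 temperature_C = temperature_C, times = times,
                 replicates = as.integer(replicates), noise = noise,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

generate_common <- function(design, scheme, observable) {
  tr <- integrate_scheme(scheme, times = design$times)
  mean_tc <- observe(tr, observable,
                     substrate_id = paste0(design$table, ":", design$row),
                     temperature = design$temperature_C)
  set.seed(design$seed)
  out <- lapply(seq_len(design$replicates), function(rep) {
    tc <- mean_tc
    tc$replicate <- rep
    if (design$noise$proportional_sd > 0 || design$noise$floor_sd > 0)
      tc$concentration_uM <- apply_noise(mean_tc$concentration_uM,
                                         design$noise)
    attr(tc, "conc_E") <- design$conc_E
    attr(tc, "conc_D") <- design$conc_D
    tc
  })
  attr(out, "mean") <- mean_tc
  attr(out, "design") <- design
  out
}

#' Generate synthetic single-turnover excision time courses
#'
#' Remaining-starting-primer decays for the branched pol/exo scheme built
#' from the referenced fixture.  With zero noise the replicates equal the
#' engine output exactly.
#'
#' @param design An [experiment_design()] referencing an excision fixture.
#' @return List of `time_course` replicates (each carrying `conc_E` and
#'   `conc_D` attributes); the noiseless mean is in attribute `"mean"`.
#' @export
generate_excision <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$kind != "excision") stop("design does not reference an excision fixture")
  p <- fixture(design$table, design$row)
  sch <- build_proofreading_scheme(p, conc_E = design$conc_E,
                                   conc_D = design$conc_D)
  generate_common(design, sch, "remaining-starting-primer")
}

#' Generate synthetic mismatch extension time courses
#'
#' Extended-product formation for the two-step extension scheme, with the
#' pre-equilibration phase (nucleotide withheld) run before t = 0.
#' Product appears biphasically when the fraction primed is below 1.
#'
#' @param design An [experiment_design()] referencing an extension fixture.
#' @return As [generate_excision()].
#' @export
generate_extension <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$kind != "extension") stop("design does not reference an extension fixture")
  p <- fixture(design$table, design$row)
  sch <- build_extension_scheme(p, conc_E = design$conc_E,
                                conc_D = design$conc_D)
  generate_common(design, sch, "extended-product")
}
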