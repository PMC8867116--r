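#' Experimental protocol for a simulation
#'
#' A protocol is an ordered list of phases.  At most one phase may have
#' `duration = "equilibrium"` and it must precede the timed phase; it
#' emulates a preincubation that is run to steady state (e.g. letting DNA
#' equilibrate between active sites before nucleotide addition).  Each
#' phase can disable reactions by label and inject species at its start.
#'
#' @param phases List of [protocol_phase()] objects.
#' @return A `kin_protocol` object.
#' @export
kin_protocol <- function(phases) {
  eq <- vapply(phases, function(p) identical(p$duration, "equilibrium"), TRUE)
  if (sum(eq) > 1L) stop("at most one equilibrium phase is allowed")
  if (any(eq) && !eq[1L]) stop("the equilibrium phase must come first")
  structure(list(phases = phases), class = "kin_protocol")
}

#' @rdname kin_protocol
#' @param duration Phase length in seconds, or `"equilibrium"` to integrate
#'   until all net rates fall below the steady-state tolerance.
#' @param disable Character vector of reaction labels switched off during
#'   this phase.
#' @param inject Named numeric vector of concentrations (uM) added to the
#'   state at the start of the phase.
#' @export
protocol_phase <- function(duration, disable = character(), inject = NULL) {
  if (!identical(duration, "equilibrium"))
    stopifnot(is.numeric(duration), duration > 0)
  structure(list(duration = duration, disable = disable, inject = inject),
            class = "protocol_phase")
}

#' Default protocol implied by a scheme
#'
#' Schemes flagged with a `preequilibrate` reaction set get an equilibrium
#' phase with those reactions disabled, followed by the timed phase;
#' otherwise a single timed phase (mixing starts the reaction at t = 0).
#'
#' @param scheme A `kinetic_scheme`.
#' @return A `kin_protocol`.
#' @export
default_protocol <- function(scheme) {
  if (!is.null(scheme$preequilibrate)) {
    kin_protocol(list(protocol_phase("equilibrium",
                                     disable = scheme$preequilibrate),
                      protocol_phase(Inf)))
  } else {
    kin_protocol(list(protocol_phase(Inf)))
  }
}

#' Integrate a kinetic scheme
#'
#' Mass-action ODE integration with a stiff L-stable Rosenbrock method and
#' analytic Jacobian.  An equilibrium phase, if present, is integrated
#' until `max |dc/dt| < ss_ftol` before the timed phase starts at t = 0.
#' Optionally accumulates one-way reaction fluxes (time integrals of
#' forward rates) for named reactions.
#'
#' @param scheme A `kinetic_scheme`.
#' @param times Strictly increasing output times in seconds (>= 0).
#' @param protocol A `kin_protocol`; default [default_protocol()].
#' @param track_flux Character vector of reaction labels whose integrated
#'   one-way flux (uM) should be accumulated during the timed phase.
#' @param rtol,atol Integration tolerances (relative; absolute in uM).
#' @param ss_ftol Steady-state tolerance for equilibrium phases, uM/s.
#' @return A `kin_trajectory`: list with `times`, `conc` (species x time
#'   matrix, uM), `flux` (tracked flux x time matrix or NULL), `scheme`.
#' @export
integrate_scheme <- function(scheme, times, protocol = default_protocol(scheme),
                             track_flux = NULL,
                             rtol = 1e-8, atol = 1e-12, ss_ftol = 1e-8) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(protocol, "kin_protocol"))
  if (length(times) < 1L || any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and >= 0")
  mats <- scheme_matrices(scheme)
  y <- scheme$init
  n <- length(y)

  phases <- protocol$phases
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    if (!is.null(ph$inject)) {
      bad <- setdiff(names(ph$inject), scheme$species)
      if (length(bad)) stop("inject references unknown species: ",
                            paste(bad, collapse = ", "))
      y[names(ph$inject)] <- y[names(ph$inject)] + ph$inject
    }
    k <- mats$k
    if (length(ph$disable)) {
      bad <- setdiff(ph$disable, mats$labels)
      if (length(bad)) stop("disable references unknown reactions: ",
                            paste(bad, collapse = ", "))
      k[mats$labels %in% ph$disable] <- 0
    }
    if (identical(ph$duration, "equilibrium")) {
      res <- tryCatch(
        .ma_equilibrate_cpp(mats$S, mats$r1, mats$r2, k, y,
                            ss_ftol, 1e7, rtol, atol),
        error = function(e) stop("equilibration failed in phase ", i, ": ",
                                 conditionMessage(e)))
      if (!isTRUE(attr(res, "converged")))
        stop("equilibrium phase did not reach steady state (phase ", i, ")")
      y <- setNames(as.numeric(res), scheme$species)
    } else {
      # final (timed) phase: integrate over the requested grid
      track <- NULL
      Sx <- mats$S
      if (!is.null(track_flux)) {
        idx <- match(track_flux, mats$labels)
        if (anyNA(idx)) stop("track_flux references unknown reactions: ",
                             paste(track_flux[is.na(idx)], collapse = ", "))
        add <- matrix(0, length(idx), ncol(Sx))
        for (t in seq_along(idx)) add[t, idx[t]] <- 1
        Sx <- rbind(Sx, add)
        y <- c(y, setNames(numeric(length(idx)), paste0("flux:", track_flux)))
      }
      t_out <- times
      need0 <- t_out[1] > 0
      if (need0) t_out <- c(0, t_out)
      out <- tryCatch(
        .ma_integrate_cpp(Sx, mats$r1, mats$r2, k, as.numeric(y), t_out,
                          rtol, atol),
        error = function(e) stop("integration failed in phase ", i, ": ",
                                 conditionMessage(e)))
      rownames(out) <- names(y)
      if (need0) out <- out[, -1, drop = FALSE]
      conc <- out[seq_len(n), , drop = FALSE]
      flux <- if (!is.null(track_flux)) {
        fl <- out[-seq_len(n), , drop = FALSE]
        rownames(fl) <- track_flux
        fl
      }
      return(structure(list(times = times, conc = conc, flux = flux,
                            scheme = scheme),
                       class = "kin_trajectory"))
    }
  }
  stop("protocol has no timed phase")
}

#' Map a simulated trajectory to an experimental observable
#'
#' `"remaining-starting-primer"` sums all species still carrying the intact
#' primer (free DNA plus every enzyme-DNA complex); `"extended-product"`
#' (alias `"product"`) sums the absorbing product species.
#'
#' @param traj A `kin_trajectory` from [integrate_scheme()].
#' @param observable Observable name.
#' @param substrate_id,temperature,replicate Annotation fields for the
#'   resulting record.
#' @param clip Clip round-off negatives to 0 in the reported values
#'   (never inside the integrator state).
#' @return A `time_course` data.frame with columns `substrate_id`,
#'   `temperature_C`, `replicate`, `time_s`, `observable`,
#'   `concentration_uM`.
#' @export
observe <- function(traj, observable = c("remaining-starting-primer",
                                         "extended-product", "product"),
                    substrate_id = "substrate", temperature = NA,
                    replicate = 1L, clip = TRUE) {
  stopifnot(inherits(traj, "kin_trajectory"))
  observable <- match.arg(observable)
  roles <- traj$scheme$roles
  sel <- switch(observable,
    "remaining-starting-primer" = names(roles)[roles %in% c("free-DNA", "complex")],
    names(roles)[roles == "absorbing-product"])
  if (!length(sel)) stop("observable '", observable,
                         "' undefined for this scheme")
  v <- colSums(traj$conc[sel, , drop = FALSE])
  if (clip) v <- pmax(v, 0)
  time_course(substrate_id = substrate_id, temperature_C = temperature,
              replicate = replicate, time_s = traj$times,
              observable = if (observable == "product") "extended-product"
                           else observable,
              concentration_uM = v)
}

#' Construct a time-course record
#'
#' The standard container for observed or simulated concentration-vs-time
#' data: one row per sampled time.
#'
#' @param substrate_id,temperature_C,replicate,time_s,observable,concentration_uM
#'   Column values (recycled to a common length).
#' @return A data.frame of class `time_course`.
#' @export
time_course <- function(substrate_id, temperature_C, replicate, time_s,
                        observable, concentration_uM) {
  if (is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  if (any(concentration_uM < -1e-9)) stop("concentrations must be >= 0")
  if (length(time_s) == 0L)
    return(structure(data.frame(substrate_id = character(),
                                temperature_C = numeric(),
                                replicate = integer(), time_s = numeric(),
                                observable = character(),
                                concentration_uM = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("time_course", "data.frame")))
  structure(data.frame(substrate_id = substrate_id,
                       temperature_C = temperature_C,
                       replicate = as.integer(replicate),
                       time_s = time_s, observable = observable,
                       concentration_uM = concentration_uM,
                       stringsAsFactors = FALSE),
            class = c("time_course", "data.frame"))
}

#' Read / write time courses as delimited text
#'
#' Tab-separated with a header; lines starting with `#` carry provenance
#' metadata and are ignored on read.
#'
#' @param x A `time_course` (or plain data.frame with its columns).
#' @param path File path.
#' @param meta Optional named character vector written as `# key: value`.
#' @return `write_time_course` returns `path` invisibly;
#'   `read_time_course` returns a `time_course`.
#' @export
write_time_course <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_course
#' @export
read_time_course <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("substrate_id", "temperature_C", "replicate", "time_s",
            "observable", "concentration_uM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  class(df) <- c("time_course", "data.frame")
  df
}

#' Default log-spaced output grids mirroring quench-flow sampling
#'
#' @param kind `"excision"` (1 ms to 10 s) or `"extension"` (1 ms to 180 s).
#' @param n Number of points.
#' @return Numeric vector of times in seconds.
#' @export
default_time_grid <- function(kind = c("excision", "extension"), n = NULL) {
  kind <- match.arg(kind)
  if (kind == "excision") {
    if (is.null(n)) n <- 20L
    10^seq(log10(1e-3), log10(10), length.out = n)
  } else {
    if (is.null(n)) n <- 25L
    10^seq(log10(1e-3), log10(180), length.out = n)
  }
}

#' Stochastic simulation oracle (Gillespie SSA)
#'
#' Exact stochastic simulation of a scheme at molecule scale, used to
#' validate the deterministic integrator.  Concentrations are converted to
#' molecule counts with `scale = n_molecules / total initial DNA`, run
#' `n_runs` times, and the mean count trajectory is converted back to uM.
#'
#' @param scheme A `kinetic_scheme`.
#' @param times Output times (s).
#' @param n_molecules DNA molecules per run.
#' @param n_runs Number of runs averaged.
#' @param seed Integer seed (fully reproducible).
#' @param protocol Optional protocol; only equilibrium-free single-phase
#'   protocols are supported (the deterministic engine handles the rest).
#' @return List: `times`, `mean` (species x time, uM), `se` (Monte-Carlo
#'   standard error of the mean, uM).
#' @export
gillespie_oracle <- function(scheme, times, n_molecules = 200, n_runs = 100,
                             seed = 1, protocol = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (n_molecules * n_runs > 5e6) stop("stochastic oracle resource guard")
  mats <- scheme_matrices(scheme)
  pools <- species_pools(scheme)
  dna0 <- sum(scheme$init * pools$dna)
  if (dna0 <= 0) stop("scheme has no DNA to scale by")
  scale <- n_molecules / dna0
  n0 <- round(scheme$init * scale)
  n <- length(n0); m <- length(mats$k)
  bimol <- mats$r2 >= 0
  set.seed(seed)
  acc <- matrix(0, n, length(times))
  acc2 <- matrix(0, n, length(times))
  for (run in seq_len(n_runs)) {
    y <- n0
    t <- 0
    snap <- matrix(NA_real_, n, length(times))
    it <- 1L
    repeat {
      a <- mats$k
      for (j in seq_len(m)) {
        if (mats$r1[j] >= 0) a[j] <- a[j] * y[mats$r1[j] + 1L]
        if (bimol[j]) a[j] <- a[j] * y[mats$r2[j] + 1L] / scale
      }
      a0 <- sum(a)
      t_next <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
      while (it <= length(times) && times[it] < t_next) {
        snap[, it] <- y
        it <- it + 1L
      }
      if (it > length(times)) break
      t <- t_next
      j <- sample.int(m, 1L, prob = a)
      y <- y + mats$S[, j]
    }
    acc <- acc + snap
    acc2 <- acc2 + snap^2
  }
  mean_counts <- acc / n_runs
  var_counts <- pmax(acc2 / n_runs - mean_counts^2, 0)
  se_counts <- sqrt(var_counts / n_runs)
  rownames(mean_counts) <- rownames(se_counts) <- scheme$species
  list(times = times, mean = mean_counts / scale, se = se_counts / scale)
}
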