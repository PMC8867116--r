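# Global fitting of mechanism parameters to time-course data by
# simulation.  Parameters are optimised on a log10 scale (all rate and
# equilibrium constants are positive), with uniform weighting in
# concentration units, seeded multi-start to guard against local minima in
# the biphasic landscape, and standard errors from the curvature
# (Gauss-Newton J'J) at the optimum.  Ill-conditioned directions are
# reported as not-determined rather than given fabricated errors.

#' Declare a fit specification
#'
#' @param datasets List of `time_course` data.frames (the observations).
#' @param simulate_fn `function(params, dataset)` returning predicted
#'   concentrations at `dataset$time_s` for the named parameter vector
#'   `params` (locked and floated values combined).
#' @param params Named numeric vector of initial values for all
#'   parameters.
#' @param locked Character vector of parameter names held fixed.
#' @param lower,upper Named bounds for floated parameters (defaults:
#'   `value/1e3` and `value*1e3`, floored at 1e-6).  Every floated
#'   parameter must be bounded below by a positive value (log-scale).
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(datasets, simulate_fn, params, locked = character(),
                     lower = NULL, upper = NULL) {
  stopifnot(length(datasets) >= 1, is.function(simulate_fn),
            is.numeric(params), !is.null(names(params)))
  floated <- setdiff(names(params), locked)
  if (!length(floated)) stop("floated parameter set is empty")
  lo <- pmax(params[floated] / 1e3, 1e-6)
  hi <- pmax(params[floated] * 1e3, 1e-3)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo <= 0)) stop("floated parameters must have positive lower bounds")
  structure(list(datasets = datasets, simulate_fn = simulate_fn,
                 params = params, locked = locked, floated = floated,
                 lower = lo, upper = hi),
            class = "fit_spec")
}

fit_residuals <- function(spec, params) {
  unlist(lapply(spec$datasets, function(d) {
    pred <- spec$simulate_fn(params, d)
    d$concentration_uM - pred
  }), use.names = FALSE)
}

fit_objective <- function(spec, params) {
  r <- try(fit_residuals(spec, params), silent = TRUE)
  if (inherits(r, "try-error") || any(!is.finite(r))) return(1e12)
  sum(r^2)
}

# Box-constrained Levenberg-Marquardt on log10-parameters with a
# forward-difference residual Jacobian.  Damped Gauss-Newton is the right
# local method for least squares by simulation: it needs only p+1
# integrations per iteration and handles the ill-conditioned (banana)
# valleys of biphasic kinetics via the damping term.
lm_minimize <- function(res_fn, lp, lo, hi, max_iter = 60,
                        step = 1e-6, rtol_obj = 1e-12) {
  clip <- function(x) pmin(pmax(x, lo), hi)
  lp <- clip(lp)
  r <- res_fn(lp)
  if (is.null(r)) return(NULL)
  rss <- sum(r^2)
  lambda <- 1e-3
  p <- length(lp)
  for (iter in seq_len(max_iter)) {
    J <- matrix(0, length(r), p)
    for (j in seq_len(p)) {
      lpj <- lp; lpj[j] <- lpj[j] + step
      rj <- res_fn(lpj)
      if (is.null(rj))
        return(list(par = lp, value = rss, iterations = iter,
                    converged = FALSE))
      J[, j] <- (rj - r) / step
    }
    g <- drop(crossprod(J, r))
    A <- crossprod(J)
    dA <- diag(A)
    dA[dA <= 0] <- max(dA, 1e-12)
    improved <- FALSE
    for (tries in 1:25) {
      M <- A + lambda * diag(dA, p)
      delta <- tryCatch(-solve(M, g), error = function(e) NULL)
      if (!is.null(delta)) {
        lp_new <- clip(lp + delta)
        r_new <- res_fn(lp_new)
        if (!is.null(r_new) && sum(r_new^2) < rss) {
          gain <- rss - sum(r_new^2)
          lp <- lp_new; r <- r_new; rss <- sum(r_new^2)
          lambda <- max(lambda / 5, 1e-12)
          improved <- TRUE
          if (gain < rtol_obj * (rss + 1e-300) && lambda <= 1e-10)
            return(list(par = lp, value = rss, iterations = iter,
                        converged = TRUE))
          break
        }
      }
      lambda <- lambda * 5
      if (lambda > 1e10) break
    }
    if (!improved)
      return(list(par = lp, value = rss, iterations = iter,
                  converged = TRUE))
  }
  list(par = lp, value = rss, iterations = max_iter, converged = FALSE)
}

#' Fit mechanism parameters to time-course data by simulation
#'
#' Least squares with seeded multi-start local optimisation (damped
#' Gauss-Newton / Levenberg-Marquardt on log10-parameters).  Locked
#' parameters are returned bit-identical to their input values.
#'
#' @param spec A [fit_spec()].
#' @param seed Integer seed for the multi-start draws.
#' @param n_starts Number of starts: the first from `spec$params`, the
#'   rest log-uniform within bounds.
#' @return A `fit_result`: `estimates` (full named vector), `se` (floated
#'   parameters; NA where not determined), `rss`, `converged`,
#'   `condition_number`, `not_determined` (names of ill-constrained
#'   parameters), `at_bound` (names of parameters pinned at a box bound,
#'   i.e. limit-only estimates), `fitted` (list of predicted curves per
#'   dataset), `n_obs`, `spec`.
#' @export
kin_fit <- function(spec, seed = 1, n_starts = 8) {
  stopifnot(inherits(spec, "fit_spec"))
  set.seed(seed)
  fl <- spec$floated
  llo <- log10(spec$lower[fl]); lhi <- log10(spec$upper[fl])
  starts <- list(log10(pmin(pmax(spec$params[fl], spec$lower[fl]),
                            spec$upper[fl])))
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- llo + runif(length(fl)) * (lhi - llo)

  make_params <- function(lp) {
    p <- spec$params
    p[fl] <- 10^lp
    p
  }
  res_fn <- function(lp) {
    r <- try(fit_residuals(spec, make_params(lp)), silent = TRUE)
    if (inherits(r, "try-error") || any(!is.finite(r))) NULL else r
  }

  best <- NULL
  for (s in starts) {
    o <- lm_minimize(res_fn, s, llo, lhi)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    return(structure(list(estimates = spec$params, se = NULL, rss = NA,
                          converged = FALSE,
                          diagnostics = "all optimizer starts failed",
                          spec = spec),
                     class = "fit_result"))

  est <- make_params(best$par)
  at_bound <- fl[best$par <= llo + 1e-9 | best$par >= lhi - 1e-9]
  # bit-identical locked values
  est[spec$locked] <- spec$params[spec$locked]
  resid <- fit_residuals(spec, est)
  rss <- sum(resid^2)
  n_obs <- length(resid)

  # Curvature-based standard errors: numerical Jacobian of residuals with
  # respect to the floated parameters (linear scale, central differences).
  J <- matrix(NA_real_, n_obs, length(fl))
  for (j in seq_along(fl)) {
    h <- max(est[fl[j]] * 1e-5, 1e-10)
    pp <- est; pp[fl[j]] <- est[fl[j]] + h
    pm <- est; pm[fl[j]] <- max(est[fl[j]] - h, 0)
    J[, j] <- (fit_residuals(spec, pm) - fit_residuals(spec, pp)) /
      (pp[fl[j]] - pm[fl[j]])
  }
  sv <- svd(J)
  cond <- if (min(sv$d) > 0) max(sv$d) / min(sv$d) else Inf
  dof <- max(n_obs - length(fl), 1)
  s2 <- rss / dof
  nd <- character()
  se <- rep(NA_real_, length(fl)); names(se) <- fl
  if (is.finite(cond) && cond <= 1e8) {
    cov <- chol2inv(chol(crossprod(J)))
    se[] <- sqrt(pmax(diag(cov), 0) * s2)
  } else {
    # identify the parameters dominating near-null directions; report the
    # others' errors from the pseudo-inverse restricted to the
    # well-conditioned subspace
    small <- sv$d < max(sv$d) / 1e8
    flat <- rowSums(abs(sv$v[, small, drop = FALSE]) > 0.1) > 0
    nd <- fl[flat]
    dplus <- ifelse(small, 0, 1 / sv$d^2)
    cov <- sv$v %*% (dplus * t(sv$v))
    se[] <- sqrt(pmax(diag(cov), 0) * s2)
    se[nd] <- NA_real_
  }

  # Convergence: accept either the optimizer's own flag or a vanishing
  # gradient (L-BFGS-B reports abnormal line searches at RSS ~ 0).
  grad <- -2 * drop(crossprod(J, resid))
  grad_ok <- max(abs(grad)) < 1e-6 * (1 + rss)
  fitted <- lapply(spec$datasets, function(d) {
    d$concentration_uM <- spec$simulate_fn(est, d)
    d
  })
  structure(list(estimates = est, se = se, rss = rss,
                 converged = isTRUE(best$converged) || grad_ok,
                 condition_number = cond, not_determined = nd,
                 at_bound = at_bound,
                 fitted = fitted, n_obs = n_obs, seed = seed,
                 spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Global fit:", if (isTRUE(x$converged)) "converged" else "NOT converged",
      sprintf("(RSS = %.4g over %d points)\n", x$rss, x$n_obs))
  fl <- setdiff(names(x$estimates), x$spec$locked)
  for (p in fl)
    cat(sprintf("  %-10s %.4g %s\n", p, x$estimates[[p]],
                if (p %in% x$not_determined) "(ND)"
                else if (!is.null(x$se) && is.finite(x$se[[p]]))
                  sprintf("+/- %.3g", x$se[[p]]) else ""))
  if (length(x$spec$locked))
    cat("  locked:", paste(x$spec$locked, collapse = ", "), "\n")
  if (length(x$not_determined))
    cat("  ill-conditioned directions involve:",
        paste(x$not_determined, collapse = ", "), "\n")
  if (length(x$at_bound))
    cat("  at bound (limit-only):", paste(x$at_bound, collapse = ", "), "\n")
  invisible(x)
}

# Simulation function shared by the excision fits: build the branched
# pol/exo scheme from a named parameter vector and return the
# remaining-primer observable at the dataset's times.
simulate_excision <- function(params, dataset, rtol = 1e-8) {
  p <- as.list(params)
  ed_i <- all(c("k4", "k_minus4") %in% names(params))
  pp <- proofreading_params(k2 = p$k2, k3 = p$k3, K3 = p$K3,
                            k4 = if (ed_i) p$k4,
                            k_minus4 = if (ed_i) p$k_minus4,
                            k1 = p$k1, k_minus1 = p$k_minus1,
                            k_minus2 = p$k_minus2, k_exo = p$k_exo)
  sch <- build_proofreading_scheme(pp, conc_E = attr(dataset, "conc_E"),
                                   conc_D = attr(dataset, "conc_D"))
  tr <- integrate_scheme(sch, times = dataset$time_s, rtol = rtol,
                         atol = rtol * 1e-4)
  obs <- observe(tr, "remaining-starting-primer")
  obs$concentration_uM
}

#' Fit the branched excision mechanism to remaining-primer time courses
#'
#' Applies the standard locking convention (k1 = 300 uM^-1 s^-1,
#' k-1 = k-2 = 0.2 s^-1, k_exo = 1000 s^-1 locked; k2, k3, K3 and, when
#' present, k4/k-4 floated).
#'
#' @param datasets List of `time_course` data.frames; each must carry
#'   attributes `conc_E` and `conc_D` (uM) -- see
#'   [generate_excision()] output.
#' @param init A [proofreading_params()] giving starting values (and
#'   whether the inhibited-state branch is modelled).
#' @param seed,n_starts Passed to [kin_fit()].
#' @param float Optional character vector overriding the floated set.
#' @param rtol Integration tolerance used inside the objective; loosen to
#'   1e-7 for noisy-data fits where speed matters (model error then ~1e-6
#'   of the signal, far below measurement noise).
#' @return A `fit_result`.
#' @export
fit_excision <- function(datasets, init, seed = 1, n_starts = 8,
                         float = NULL, rtol = 1e-8) {
  stopifnot(inherits(init, "proofreading_params"))
  params <- c(k1 = init$k1, k_minus1 = init$k_minus1, k2 = init$k2,
              k_minus2 = init$k_minus2, k3 = init$k3, K3 = init$K3,
              k_exo = init$k_exo)
  if (init$ed_i_present)
    params <- c(params, k4 = init$k4, k_minus4 = init$k_minus4)
  default_float <- intersect(c("k2", "k3", "K3", "k4", "k_minus4"),
                             names(params))
  if (is.null(float)) float <- default_float
  locked <- setdiff(names(params), float)
  spec <- fit_spec(datasets,
                   function(p, d) simulate_excision(p, d, rtol = rtol),
                   params, locked = locked)
  kin_fit(spec, seed = seed, n_starts = n_starts)
}

simulate_extension <- function(params, dataset, rtol = 1e-8) {
  p <- as.list(params)
  ep <- extension_params(k1_prime = p$k1_prime,
                         k_minus1_prime = p$k_minus1_prime, k_pol = p$k_pol)
  sch <- build_extension_scheme(ep, conc_D = attr(dataset, "conc_D"))
  tr <- integrate_scheme(sch, times = dataset$time_s, rtol = rtol,
                         atol = rtol * 1e-4)
  obs <- observe(tr, "extended-product")
  obs$concentration_uM
}

#' Fit the two-step extension mechanism to product time courses
#'
#' Floats `{k1', k-1', k_pol}` by default; `lock_k_pol` holds k_pol at its
#' initial value (the convention for fast substrates where only the
#' primed fraction is constrained).
#'
#' @param datasets List of `time_course` data.frames with a `conc_D`
#'   attribute (uM).
#' @param init An [extension_params()] with starting values.
#' @param lock_k_pol Lock k_pol at `init$k_pol`.
#' @param seed,n_starts Passed to [kin_fit()].
#' @param rtol Integration tolerance inside the objective.
#' @return A `fit_result`.
#' @export
fit_extension <- function(datasets, init, lock_k_pol = FALSE, seed = 1,
                          n_starts = 8, rtol = 1e-8) {
  stopifnot(inherits(init, "extension_params"))
  params <- c(k1_prime = init$k1_prime,
              k_minus1_prime = init$k_minus1_prime, k_pol = init$k_pol)
  locked <- if (lock_k_pol) "k_pol" else character()
  spec <- fit_spec(datasets,
                   function(p, d) simulate_extension(p, d, rtol = rtol),
                   params, locked = locked)
  kin_fit(spec, seed = seed, n_starts = n_starts)
}

#' Upper limit on kcat/Km from the absence of detectable product
#'
#' If no product above the detection fraction `f` accumulates in time `t`
#' at nucleotide concentration `[dNTP]` (well below Km, so extension is
#' first order with rate `(kcat/Km)[dNTP]`), then
#' `kcat/Km < -ln(1 - f) / ([dNTP] t)`.
#'
#' @param observed_max_fraction Detection threshold as a fraction of total
#'   substrate, in (0, 1).  Default 0.018.
#' @param duration Observation time, s.
#' @param dntp_conc Nucleotide concentration, M.
#' @return Upper bound on kcat/Km in M^-1 s^-1.
#' @export
upper_limit_kcat_km <- function(observed_max_fraction = 0.018, duration,
                                dntp_conc) {
  f <- observed_max_fraction
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("detection fraction must be in (0, 1)")
  stopifnot(duration > 0, dntp_conc > 0)
  -log(1 - f) / (dntp_conc * duration)
}

#' Serialize a fit result as structured text (JSON)
#'
#' @param x A `fit_result`.
#' @param path Optional output path.
#' @return JSON string.
#' @export
fit_to_json <- function(x, path = NULL) {
  obj <- list(estimates = as.list(x$estimates),
              se = as.list(x$se), rss = x$rss, converged = x$converged,
              condition_number = x$condition_number,
              not_determined = x$not_determined,
              locked = x$spec$locked, n_obs = x$n_obs, seed = x$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
  if (!is.null(path)) writeLines(js, path)
  js
}
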