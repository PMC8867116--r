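# Command-line workbench: reproducible runs driven by JSON configuration
# files.  Numeric results go to files; log lines go to standard error.
# Exit codes: 0 success, 2 usage/configuration error, 3 numerical failure.

cli_log <- function(...) message("[exokin] ", ...)

usage_error <- function(msg) stop(structure(
  class = c("exokin_usage_error", "error", "condition"),
  list(message = msg, call = NULL)))

read_config <- function(path) {
  if (is.null(path) || !file.exists(path))
    usage_error(paste0("config file not found: ", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

need_fields <- function(cfg, fields, where = "config") {
  miss <- setdiff(fields, names(cfg))
  if (length(miss))
    usage_error(paste0("missing ", where, " field(s): ",
                       paste(miss, collapse = ", ")))
}

provenance <- function(cfg) {
  list(config = cfg,
       package = "exokin",
       version = as.character(utils::packageVersion("exokin")))
}

write_report <- function(obj, cfg, path) {
  obj$provenance <- provenance(cfg)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"),
             path)
  cli_log("wrote ", path)
}

cfg_design <- function(cfg) {
  need_fields(cfg, c("table", "row"))
  noise <- if (!is.null(cfg$noise))
    noise_model(cfg$noise$proportional_sd %||% 0.05,
                cfg$noise$floor_sd %||% 0.002)
  else noise_model()
  experiment_design(cfg$table, cfg$row,
                    conc_E = cfg$conc_E, conc_D = cfg$conc_D,
                    times = cfg$times,
                    replicates = cfg$replicates %||% 1L,
                    noise = noise, seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cmd_simulate <- function(cfg, out_dir) {
  design <- cfg_design(cfg)
  design$noise <- noise_model(0, 0)
  gen <- if (design$kind == "extension") generate_extension(design)
         else generate_excision(design)
  tc <- attr(gen, "mean")
  path <- file.path(out_dir, sprintf("simulate_%s_%s.tsv", cfg$table, cfg$row))
  write_time_course(tc, path, meta = c(
    config = jsonlite::toJSON(cfg, auto_unbox = TRUE),
    package = paste0("exokin ", utils::packageVersion("exokin"))))
  cli_log("wrote ", path)
  0L
}

cmd_generate <- function(cfg, out_dir) {
  design <- cfg_design(cfg)
  gen <- if (design$kind == "extension") generate_extension(design)
         else generate_excision(design)
  tc <- do.call(rbind, gen)
  path <- file.path(out_dir, sprintf("generate_%s_%s.tsv", cfg$table, cfg$row))
  write_time_course(tc, path, meta = c(
    config = jsonlite::toJSON(cfg, auto_unbox = TRUE),
    package = paste0("exokin ", utils::packageVersion("exokin"))))
  cli_log("wrote ", path)
  0L
}

cmd_fit <- function(cfg, out_dir) {
  need_fields(cfg, c("kind", "data", "table", "row"))
  datasets <- lapply(cfg$data, function(p) {
    if (!file.exists(p)) usage_error(paste0("data file not found: ", p))
    tc <- read_time_course(p)
    if (!nrow(tc)) usage_error(paste0("empty dataset: ", p))
    attr(tc, "conc_E") <- cfg$conc_E %||% 1
    attr(tc, "conc_D") <- cfg$conc_D %||% 0.25
    tc
  })
  init <- fixture(cfg$table, cfg$row)
  fit <- if (cfg$kind == "extension") {
    datasets <- lapply(datasets, function(d) {
      attr(d, "conc_D") <- cfg$conc_D %||% 0.075
      d
    })
    fit_extension(datasets, init, lock_k_pol = isTRUE(cfg$lock_k_pol),
                  seed = cfg$seed %||% 1L, n_starts = cfg$n_starts %||% 8L)
  } else {
    fit_excision(datasets, init, seed = cfg$seed %||% 1L,
                 n_starts = cfg$n_starts %||% 8L)
  }
  if (!isTRUE(fit$converged)) cli_log("warning: fit did not converge")
  path <- file.path(out_dir, "fit.json")
  obj <- jsonlite::fromJSON(fit_to_json(fit), simplifyVector = TRUE)
  write_report(list(fit = obj), cfg, path)
  for (i in seq_along(fit$fitted))
    write_time_course(fit$fitted[[i]],
                      file.path(out_dir, sprintf("fitted_%d.tsv", i)))
  0L
}

cmd_flux <- function(cfg, out_dir) {
  need_fields(cfg, c("table", "row"))
  p <- fixture(cfg$table, cfg$row)
  sch <- build_proofreading_scheme(p, conc_E = cfg$conc_E %||% 1,
                                   conc_D = cfg$conc_D %||% 0.25)
  mode <- cfg$mode %||% "one-way"
  horizon <- cfg$horizon %||% "reaction-complete"
  bp <- binding_partition(sch, mode = mode, horizon = horizon)
  ep <- edp_partition(sch, mode = mode, horizon = horizon)
  write_report(list(binding = unclass(bp),
                    edp = c(unclass(ep), notice = attr(ep, "notice"))),
               cfg, file.path(out_dir, "flux.json"))
  0L
}

build_fate_from_config <- function(cfg) {
  n0 <- cfg$n0 %||% list(table = "excision_buried", row = "n-0")
  n1 <- cfg$n1 %||% list(table = "excision_buried", row = "n-1")
  ext0 <- mismatch_extension_kinetics(kcat = TERMINAL_MISMATCH_EXTENSION$kcat,
                                      Km = TERMINAL_MISMATCH_EXTENSION$Km)
  ext1 <- mismatch_extension_kinetics(
    kcat_over_Km_limit = BURIED_MISMATCH_EXTENSION_LIMIT)
  build_fate_scheme(fixture(n0$table, n0$row), fixture(n1$table, n1$row),
                    ext0, ext1,
                    dntp_n0 = cfg$dntp_n0 %||% "saturating",
                    dntp_n1 = cfg$dntp_n1 %||% 1000)
}

cmd_fate <- function(cfg, out_dir) {
  sch <- build_fate_from_config(cfg)
  rep <- mismatch_fate(sch)
  write_report(list(fraction_excised = rep$fraction_excised,
                    fraction_extended_once = rep$fraction_extended_once,
                    fraction_buried = rep$fraction_buried,
                    buried_is_upper_limit = rep$buried_is_upper_limit,
                    contribution_factor = as.numeric(rep$contribution_factor),
                    contribution_is_lower_bound =
                      identical(attr(rep$contribution_factor, "bound"), ">="),
                    contribution_at_least_1e4 =
                      as.numeric(rep$contribution_factor) >= 1e4,
                    routes = rep$routes),
               cfg, file.path(out_dir, "fate.json"))
  0L
}

cmd_thermo <- function(cfg, out_dir) {
  need_fields(cfg, c("K_low", "T_low_C", "K_high", "T_high_C"))
  th <- vant_hoff(cfg$K_low, celsius_to_kelvin(cfg$T_low_C),
                  cfg$K_high, celsius_to_kelvin(cfg$T_high_C))
  write_report(unclass(th), cfg, file.path(out_dir, "thermo.json"))
  0L
}

cmd_report <- function(cfg, out_dir) {
  # Combined derived-quantity report with input provenance per constant.
  low <- fixture("excision_4C", "1"); high <- fixture("excision_20C", "1")
  none <- fixture("excision_20C", "0"); four <- fixture("excision_20C", "4")
  th <- vant_hoff(low$K3, celsius_to_kelvin(4), high$K3, celsius_to_kelvin(20))
  sch <- build_fate_from_config(cfg)
  fate <- mismatch_fate(sch)
  write_report(list(
    thermo = c(unclass(th),
               inputs = list(list(K_low = "excision_4C row 1",
                                  K_high = "excision_20C row 1"))),
    reverse_transfer_s1 = list(`20C` = reverse_transfer_rate(high$k3, high$K3),
                               `4C` = reverse_transfer_rate(low$k3, low$K3)),
    pol_site_occupancy_pct = list(`20C` = pol_site_occupancy(high$K3),
                                  `4C` = pol_site_occupancy(low$K3)),
    K3_fold_increase_one_mismatch = fold_change(high$K3, none$K3),
    K3_fold_increase_four_mismatches = fold_change(four$K3, none$K3),
    fate = list(fraction_excised = fate$fraction_excised,
                fraction_buried = fate$fraction_buried,
                contribution_factor = as.numeric(fate$contribution_factor),
                contribution_at_least_1e4 =
                  as.numeric(fate$contribution_factor) >= 1e4)),
    cfg, file.path(out_dir, "report.json"))
  0L
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `generate`, `fit`, `flux`, `fate`, `thermo`,
#' `report`.  Each takes `--config <file.json>` and `--out <dir>`
#' (`thermo`, `fate` and `report` accept an empty config `{}` for the
#' bundled defaults).  See the package vignette for config fields.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Integer exit status (0 success, 2 usage error, 3 numerical
#'   failure); the installed script passes it to `quit()`.
#' @export
exokin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (!length(args)) usage_error(
      "usage: exokin <simulate|generate|fit|flux|fate|thermo|report> --config <json> [--out <dir>]")
    cmd <- args[[1]]
    rest <- args[-1]
    opt <- list(config = NULL, out = ".")
    i <- 1L
    while (i <= length(rest)) {
      a <- rest[[i]]
      if (a == "--config") { opt$config <- rest[[i + 1L]]; i <- i + 2L }
      else if (a == "--out") { opt$out <- rest[[i + 1L]]; i <- i + 2L }
      else usage_error(paste0("unknown argument: ", a))
    }
    if (!dir.exists(opt$out)) dir.create(opt$out, recursive = TRUE)
    cfg <- if (cmd %in% c("thermo", "fate", "report") && is.null(opt$config))
      list() else read_config(opt$config)
    fn <- switch(cmd,
                 simulate = cmd_simulate, generate = cmd_generate,
                 fit = cmd_fit, flux = cmd_flux, fate = cmd_fate,
                 thermo = cmd_thermo, report = cmd_report,
                 usage_error(paste0("unknown command: ", cmd)))
    fn(cfg, opt$out)
  }
  tryCatch(run(),
           exokin_usage_error = function(e) {
             message("usage error: ", conditionMessage(e)); 2L
           },
           error = function(e) {
             message("error: ", conditionMessage(e)); 3L
           })
}
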