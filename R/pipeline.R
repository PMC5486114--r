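## Pipeline configuration. JSON only: the run config and CORCEMA
## conditions use the same key names as the R constructors.

CONFIG_KEYS <- list(
  top = c("mode", "seed", "conditions", "simulate", "input", "output_dir",
          "estimator_options"),
  conditions = c("p0_uM", "l0_uM", "l0_mM", "kd_uM", "kon_per_M_s",
                 "temperature_K", "spectrometer_MHz"),
  simulate_std_af = c("af0_max", "ic50_mM", "ladder_mM", "b", "sigma"),
  simulate_t1sel = c("ic50_uM", "t1b_plus_tau", "ladder_uM", "sigma",
                     "mode", "t1_free"),
  estimator_options = c("subtract_free", "weighted"))

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0)
    stopf("config: unknown key(s) in %s: %s", where,
          paste(extra, collapse = ", "))
}

#' Validate a pipeline run configuration
#'
#' Rejects unknown keys at every level and checks the mode-specific
#' requirements before any computation runs.
#'
#' @param cfg configuration list (see [run_pipeline]).
#' @return the validated config, invisibly.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stopf("config must be a list / JSON object")
  check_keys(cfg, CONFIG_KEYS$top, "top level")
  if (is.null(cfg$mode) || !cfg$mode %in% c("std-af", "t1sel"))
    stopf("config: mode must be 'std-af' or 't1sel'")
  if (!is.null(cfg$conditions))
    check_keys(cfg$conditions, CONFIG_KEYS$conditions, "conditions")
  if (is.null(cfg$simulate) && is.null(cfg$input))
    stopf("config: give either a simulate block or an input path")
  if (!is.null(cfg$simulate)) {
    allowed <- if (cfg$mode == "std-af") CONFIG_KEYS$simulate_std_af else
      CONFIG_KEYS$simulate_t1sel
    check_keys(cfg$simulate, allowed, "simulate")
  }
  if (!is.null(cfg$estimator_options))
    check_keys(cfg$estimator_options, CONFIG_KEYS$estimator_options,
               "estimator_options")
  invisible(cfg)
}

cfg_default <- function(x, default) if (is.null(x)) default else x

#' Run an IC50 workflow end to end
#'
#' Executes one of the two estimator workflows -- `"std-af"`
#' (amplification-factor build-up slopes, Langmuir isotherm) or `"t1sel"`
#' (inversion-recovery fits, x-intercept of the `[P]0 T1obs` line) -- on
#' either simulated inputs (a `simulate` block) or files (`input`), and
#' returns a machine-readable report. The same config and seed always give
#' an identical report.
#'
#' @param config a configuration list or path to a JSON file with keys:
#'   `mode` ("std-af" | "t1sel"); `seed` (integer); `conditions`
#'   (`p0_uM`, `l0_mM`/`l0_uM`, `spectrometer_MHz`, ...); one of
#'   `simulate` (generator parameters; see [gen_af_buildup_series] /
#'   [gen_t1_titration]) or `input` (CSV path in the [read_peak_table] /
#'   [read_ir_table] dialect); optional `output_dir` and
#'   `estimator_options`.
#' @return report list with `mode`, `seed`, `ic50`, `ic50_units`, `se`,
#'   `n_points`, `stages` (per-stage parameter log). Written to
#'   `output_dir/report.json` when an output directory is configured.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config))
    jsonlite::read_json(config, simplifyVector = TRUE) else config
  validate_config(cfg)
  seed <- as.integer(cfg_default(cfg$seed, 1L))
  p0 <- cfg_default(cfg$conditions$p0_uM,
                    if (cfg$mode == "std-af") 19 else 20)
  stages <- list()
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed (input: %s): %s", name,
            cfg_default(cfg$input, "simulated"), conditionMessage(e)))
  }
  if (cfg$mode == "std-af") {
    curves <- stage_wrap("load", {
      if (!is.null(cfg$simulate)) {
        sim <- cfg$simulate
        gen_af_buildup_series(
          af0_max = sim$af0_max, ic50_mM = sim$ic50_mM,
          ladder_mM = cfg_default(sim$ladder_mM, sim$ic50_mM * 2^(-2:2)),
          protein_conc_uM = p0, b = cfg_default(sim$b, 1),
          sigma = cfg_default(sim$sigma, 0), seed = seed)
      } else read_peak_table(cfg$input)
    })
    stages$load <- list(n_curves = length(curves), p0_uM = p0)
    res <- stage_wrap("std-af-fit", std_af_ic50(curves, p0_uM = p0))
    stages$fit <- list(af0 = unname(res$af0),
                       ladder_mM = res$titration$ligand_concs)
    ic50 <- res$fit$ic50
    se <- unname(res$fit$parameter_uncertainties["ic50"])
    units <- "mM"; n <- length(res$af0)
  } else {
    traces <- stage_wrap("load", {
      if (!is.null(cfg$simulate)) {
        sim <- cfg$simulate
        gen_t1_titration(
          ic50_uM = sim$ic50_uM,
          t1b_plus_tau = cfg_default(sim$t1b_plus_tau, 0.1),
          ladder_uM = cfg_default(sim$ladder_uM, c(80, 160, 320, 480, 640)),
          protein_conc_uM = p0, mode = cfg_default(sim$mode, "linear"),
          t1_free = cfg_default(sim$t1_free, 3),
          sigma = cfg_default(sim$sigma, 0), seed = seed,
          output = "traces")
      } else read_ir_table(cfg$input)
    })
    stages$load <- list(n_traces = length(traces), p0_uM = p0)
    opt <- cfg_default(cfg$estimator_options, list())
    res <- stage_wrap("t1-fit", t1_ic50(
      traces, subtract_free = isTRUE(opt$subtract_free)))
    stages$fit <- list(t1_obs_s = res$t1_obs,
                       ladder_uM = res$titration$ligand_concs,
                       slope = res$slope, intercept = res$intercept)
    ic50 <- res$ic50; se <- res$se; units <- "uM"
    n <- length(res$t1_obs)
  }
  report <- list(mode = cfg$mode, seed = seed, ic50 = ic50,
                 ic50_units = units, se = se, n_points = n,
                 stages = stages)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Validate a pipeline report against the packaged schema
#'
#' Checks required fields and primitive types against the JSON schema
#' shipped in `inst/schema/report-schema.json` (a minimal in-house check;
#' no external JSON-schema engine is required).
#'
#' @param report a report list or path to a report JSON file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  schema <- jsonlite::read_json(
    system.file("schema", "report-schema.json", package = "stdnmr"),
    simplifyVector = TRUE)
  for (f in schema$required)
    if (is.null(report[[f]])) stopf("report: missing required field '%s'", f)
  for (f in names(schema$properties)) {
    if (is.null(report[[f]])) next
    want <- schema$properties[[f]]$type
    ok <- switch(want,
                 number = is.numeric(report[[f]]),
                 integer = is.numeric(report[[f]]) &&
                   report[[f]] == round(report[[f]]),
                 string = is.character(report[[f]]),
                 object = is.list(report[[f]]),
                 TRUE)
    if (!ok) stopf("report: field '%s' must be a %s", f, want)
  }
  if (!report$ic50_units %in% c("mM", "uM"))
    stopf("report: ic50_units must be 'mM' or 'uM'")
  invisible(TRUE)
}
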