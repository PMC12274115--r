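run_config_keys <- c("seed", "output_dir", "panel_path", "schema", "scheme",
                     "model", "attribution", "forecast", "triangulation",
                     "generator", "log_level")

#' Build / validate a pipeline run configuration
#'
#' A single configuration drives every stage; unknown keys are
#' rejected, and parse -> render -> parse is the identity.
#'
#' @param x a named list, or the path of a YAML file.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_config(paste0("no such config file: ", x))
    x <- yaml::read_yaml(x)
  }
  unknown <- setdiff(names(x), run_config_keys)
  if (length(unknown)) {
    stop_config(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    seed = as.integer(x$seed %||% 1L),
    output_dir = x$output_dir %||% "aidmort_out",
    panel_path = x$panel_path %||% NULL,
    schema = x$schema %||% NULL,
    scheme = x$scheme %||% "estimate",
    model = utils::modifyList(
      list(outcome = "all_age", exposure = "categorical",
           time_controls = "shocks", family = "poisson", weights = "none",
           fit_years = c(2001L, 2021L)),
      x$model %||% list()),
    attribution = utils::modifyList(
      list(n_draws = 100000L, mode = "full"), x$attribution %||% list()),
    forecast = utils::modifyList(
      list(horizon = c(2024L, 2030L), n_sims = 1000L,
           report_years = c(2025L, 2030L)), x$forecast %||% list()),
    triangulation = utils::modifyList(
      list(pre = 2001L, post = 2021L, caliper = 0.2,
           control_outcome = "injuries"), x$triangulation %||% list()),
    generator = x$generator %||% list(),
    log_level = x$log_level %||% "info")
  if (cfg$attribution$n_draws < 1L) stop_config("attribution n_draws must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Render a run configuration as YAML
#' @param cfg a [run_config()].
#' @param path optional file to write.
#' @export
render_config <- function(cfg, path = NULL) {
  txt <- yaml::as.yaml(unclass(cfg))
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

stage_seed <- function(cfg, stage) {
  offs <- c(simulate = 11L, fit = 23L, attribute = 37L, forecast = 53L,
            triangulate = 71L)
  (cfg$seed * 1000L + offs[[stage]]) %% .Machine$integer.max
}

write_manifest <- function(cfg, stage, files, extra = list()) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(list(stage = stage, config_hash = rlang::hash(unclass(cfg)),
                     seed = stage_seed(cfg, stage),
                     package_version = as.character(utils::packageVersion("aidmort")),
                     files = files), extra)
  path <- file.path(cfg$output_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipeline_scheme <- function(cfg, panel) {
  if (identical(cfg$scheme, "estimate")) quartile_thresholds(panel)
  else exposure_scheme(unlist(cfg$scheme))
}

pipeline_panel <- function(cfg) {
  if (is.null(cfg$panel_path)) {
    stop_config("config has no panel_path; run the simulate stage first")
  }
  schema <- do.call(panel_schema, cfg$schema %||%
                      list(outcomes = names(default_outcome_defs()),
                           covariates = names(default_covariate_defs())))
  load_panel(cfg$panel_path, schema)
}

fit_window <- function(cfg, panel) {
  fy <- cfg$model$fit_years
  subset_panel(panel, panel$year >= fy[1] & panel$year <= fy[2])
}

pipeline_spec <- function(cfg, scheme) {
  model_spec(outcome = cfg$model$outcome, scheme = scheme,
             exposure = cfg$model$exposure,
             time_controls = cfg$model$time_controls,
             family = cfg$model$family, weights = cfg$model$weights)
}

#' Run one pipeline stage from a configuration
#'
#' Stages: `simulate` (synthetic panel + ground-truth sidecar), `fit`
#' (rate-ratio table), `attribute` (deaths averted), `forecast`
#' (scenario excess-deaths table), `triangulate` (matched DiD +
#' negative control). Every stage writes delimited outputs plus a JSON
#' manifest (config hash, stage seed, package version) into
#' `cfg$output_dir`.
#'
#' @param cfg a [run_config()].
#' @param stage stage name.
#' @export
run_stage <- function(cfg, stage = c("simulate", "fit", "attribute",
                                     "forecast", "triangulate")) {
  stage <- match.arg(stage)
  switch(stage,
         simulate = stage_simulate(cfg),
         fit = stage_fit(cfg),
         attribute = stage_attribute(cfg),
         forecast = stage_forecast(cfg),
         triangulate = stage_triangulate(cfg))
}

stage_simulate <- function(cfg) {
  gen_args <- cfg$generator
  gen_args$seed <- gen_args$seed %||% stage_seed(cfg, "simulate")
  gcfg <- do.call(generator_config, gen_args)
  sim <- generate_panel(gcfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  panel_path <- file.path(cfg$output_dir, "panel.csv")
  write_panel(sim$panel, panel_path)
  truth_path <- file.path(cfg$output_dir, "truth.json")
  jsonlite::write_json(list(rr = sim$truth$rr,
                            funding_law = sim$truth$funding_law,
                            ref_median = as.list(sim$truth$ref_median)),
                       truth_path, auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "simulate", c(panel_path, truth_path))
  invisible(list(panel_path = panel_path, truth_path = truth_path,
                 panel = sim$panel, truth = sim$truth))
}

stage_fit <- function(cfg) {
  panel <- pipeline_panel(cfg)
  scheme <- pipeline_scheme(cfg, panel)
  fit <- fit_fe_poisson(fit_window(cfg, panel), pipeline_spec(cfg, scheme))
  tab <- rr_table(fit, terms = "all")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(cfg$output_dir, paste0("rr_", cfg$model$outcome, ".csv"))
  utils::write.csv(tab, tab_path, row.names = FALSE)
  txt_path <- file.path(cfg$output_dir, paste0("rr_", cfg$model$outcome, ".txt"))
  writeLines(format_rr_table(fit), txt_path)
  meta_path <- file.path(cfg$output_dir, "fit_metadata.json")
  jsonlite::write_json(list(cuts = as.list(scheme$cuts),
                            percentile_definition = scheme$percentile_definition,
                            medians = as.list(fit$medians),
                            n_obs = fit$n_obs, n_countries = fit$n_countries,
                            dropped = fit$dropped),
                       meta_path, auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "fit", c(tab_path, txt_path, meta_path))
  invisible(list(fit = fit, scheme = scheme, table = tab))
}

stage_attribute <- function(cfg) {
  fitres <- stage_fit(cfg)
  res <- deaths_averted_mc(fitres$fit, n_draws = cfg$attribution$n_draws,
                           seed = stage_seed(cfg, "attribute"),
                           mode = cfg$attribution$mode)
  out <- tibble::tibble(outcome = cfg$model$outcome,
                        observed = res$observed,
                        counterfactual = res$counterfactual,
                        averted = res$averted, ci_low = res$ci_low,
                        ci_high = res$ci_high,
                        pct_averted = percent_averted(res))
  path <- file.path(cfg$output_dir, paste0("averted_", cfg$model$outcome, ".csv"))
  utils::write.csv(out, path, row.names = FALSE)
  write_manifest(cfg, "attribute", path,
                 extra = list(n_draws = res$n_draws, mode = res$mode))
  invisible(list(result = res, table = out))
}

stage_forecast <- function(cfg) {
  panel <- pipeline_panel(cfg)
  scheme <- pipeline_scheme(cfg, panel)
  fit <- fit_fe_poisson(fit_window(cfg, panel), pipeline_spec(cfg, scheme))
  horizon <- seq(cfg$forecast$horizon[1], cfg$forecast$horizon[2])
  cohort <- build_cohort(panel, horizon = horizon)
  scen <- if (!is.null(cfg$forecast$scenarios)) {
    lapply(names(cfg$forecast$scenarios), function(nm) {
      scenario_spec(nm, cfg$forecast$scenarios[[nm]])
    })
  } else {
    list(scenario_bau(horizon), scenario_defunding(horizon))
  }
  res <- run_forecast(fit, cohort, scen, scheme = scheme,
                      n_sims = cfg$forecast$n_sims,
                      seed = stage_seed(cfg, "forecast"))
  ry <- seq(cfg$forecast$report_years[1], cfg$forecast$report_years[2])
  ex <- excess_summary(res, years = intersect(ry, res$years))
  mrr <- mortality_rate_ratio(res)
  ex_path <- file.path(cfg$output_dir, paste0("excess_", cfg$model$outcome, ".csv"))
  utils::write.csv(ex, ex_path, row.names = FALSE)
  mrr_path <- file.path(cfg$output_dir, paste0("mrr_", cfg$model$outcome, ".csv"))
  utils::write.csv(mrr, mrr_path, row.names = FALSE)
  write_manifest(cfg, "forecast", c(ex_path, mrr_path),
                 extra = list(n_sims = res$n_sims))
  invisible(list(result = res, excess = ex, mrr = mrr, cohort = cohort))
}

stage_triangulate <- function(cfg) {
  panel <- pipeline_panel(cfg)
  scheme <- pipeline_scheme(cfg, panel)
  spec <- pipeline_spec(cfg, scheme)
  trt <- assign_coverage_treatment(fit_window(cfg, panel), scheme)
  base <- panel[panel$year == cfg$triangulation$pre, ]
  base <- base[match(trt$country_id, base$country_id), ]
  covs <- panel_covariates(panel)
  pm <- propensity_model(base, trt$treated, covs)
  ms <- ps_match(pm$scores, trt$treated, trt$country_id,
                 caliper = cfg$triangulation$caliper)
  did <- did_estimate(panel, ms, cfg$model$outcome,
                      pre = cfg$triangulation$pre, post = cfg$triangulation$post)
  nc <- negative_control_check(fit_window(cfg, panel), spec,
                               control_outcome = cfg$triangulation$control_outcome)
  out <- tibble::tibble(effect_log = did$effect_log, se = did$se,
                        ci_low = did$ci_low, ci_high = did$ci_high,
                        ratio = did$ratio, n_pairs = did$n_pairs,
                        negative_control_pass = nc$pass)
  path <- file.path(cfg$output_dir, "triangulation.csv")
  utils::write.csv(out, path, row.names = FALSE)
  write_manifest(cfg, "triangulate", path)
  invisible(list(did = did, matched = ms, negative_control = nc, table = out))
}
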