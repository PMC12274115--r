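#' A forecast scenario: per-year multipliers on reference funding
#'
#' Each country's per-capita funding in horizon year `t` is
#' `m_t * reference`, the reference being its last observed year.
#'
#' @param name scenario label.
#' @param multipliers named numeric vector, names = years, values >= 0.
#' @export
scenario_spec <- function(name, multipliers) {
  m <- unlist(multipliers)
  if (any(m < 0) || is.null(names(m))) {
    stop_config("multipliers must be a named (year) vector of non-negative values")
  }
  structure(list(name = name,
                 multipliers = setNames(as.numeric(m), names(m))),
            class = "scenario_spec")
}

#' Business-as-usual scenario (funding held at reference levels)
#' @param horizon projection years.
#' @export
scenario_bau <- function(horizon = 2024:2030) {
  scenario_spec("business_as_usual", setNames(rep(1, length(horizon)), horizon))
}

#' Defunding scenario: 83% cut in 2025, termination from 2026
#' @param horizon projection years.
#' @export
scenario_defunding <- function(horizon = 2024:2030) {
  m <- setNames(rep(1, length(horizon)), horizon)
  m[as.character(2025)] <- 0.17
  m[names(m) >= "2026"] <- 0
  scenario_spec("defunding", m)
}

guess_transform <- function(x) {
  x <- x[!is.na(x)]
  if (all(x > 0 & x < 1)) return("logit_unit")
  if (all(x >= 0 & x <= 100) && any(x > 1)) return("logit_pct")
  if (all(x > 0)) return("log")
  "identity"
}

#' Extrapolate a covariate series over a projection horizon
#'
#' Fits a linear trend on a transformed scale (logit for proportions,
#' log for strictly positive series, identity otherwise) over the most
#' recent `lookback` observed years and projects it, back-transforming
#' and clipping to the admissible range.
#'
#' @param values observed values.
#' @param years observed years (same length).
#' @param horizon years to project.
#' @param transform `"logit_unit"`, `"logit_pct"`, `"log"`,
#'   `"identity"`, or `"auto"` (guessed from the value range).
#' @param lookback number of most recent years used for the trend.
#' @return numeric vector over `horizon`.
#' @export
extrapolate_covariate <- function(values, years, horizon, transform = "auto",
                                  lookback = 10L) {
  ok <- !is.na(values)
  values <- values[ok]; years <- years[ok]
  if (length(values) < 3L) {
    stop_value("extrapolation needs at least 3 observed points")
  }
  if (transform == "auto") transform <- guess_transform(values)
  tr <- transform_fun(transform)
  ord <- order(years)
  years <- years[ord]; values <- values[ord]
  use <- years >= max(years) - lookback + 1L
  yv <- tr$f(values[use]); xv <- years[use]
  if (length(unique(yv)) == 1L) {
    proj <- rep(yv[1], length(horizon))
  } else {
    co <- coef(lm(yv ~ xv))
    proj <- co[1] + co[2] * horizon
  }
  out <- tr$inv(proj)
  clamp(out, tr$lo, tr$hi)
}

#' Build the synthetic projection cohort
#'
#' For each country, every covariate, denominator and the population are
#' extrapolated over the horizon ([extrapolate_covariate()]); the
#' reference per-capita funding is the last observed year's value.
#' Covariates are then dichotomized with the retrospective pooled
#' medians (frozen, not re-estimated). Horizon years already present in
#' the panel are copied as observed. Countries lacking the look-back
#' history are excluded with a logged reason.
#'
#' @param panel a (non-dichotomized) `aid_panel`.
#' @param horizon projection years.
#' @param lookback trend window in years.
#' @return a `cohort` tibble with `provenance` and `usaid_ref` columns,
#'   indicator covariates, and a `medians` attribute.
#' @export
build_cohort <- function(panel, horizon = 2024:2030, lookback = 10L) {
  if (isTRUE(attr(panel, "dichotomized"))) {
    stop_value("build_cohort needs the panel with continuous covariates")
  }
  covs <- panel_covariates(panel)
  outs <- panel_outcomes(panel)
  medians <- attr(dichotomize_covariates(panel), "medians")
  last_year <- max(panel$year)
  excluded <- character(0)
  rows <- list()
  for (cid in unique(panel$country_id)) {
    sub <- panel[panel$country_id == cid, ]
    sub <- sub[order(sub$year), ]
    if (sum(!is.na(sub$population)) < 3L) {
      excluded <- c(excluded, cid); next
    }
    future <- horizon[horizon > last_year]
    observed <- horizon[horizon <= last_year]
    rec <- NULL
    if (length(observed)) {
      ob <- sub[sub$year %in% observed,
                c("country_id", "year", "income_group", "population",
                  "live_births", "usaid_pc", covs,
                  paste0("denom_", outs)), drop = FALSE]
      ob$provenance <- "observed"
      rec <- ob
    }
    if (length(future)) {
      ext <- tryCatch({
        fu <- tibble::tibble(country_id = cid, year = as.integer(future),
                             income_group = sub$income_group[1])
        fu$population <- extrapolate_covariate(sub$population, sub$year, future,
                                               "log", lookback)
        fu$live_births <- extrapolate_covariate(sub$live_births, sub$year, future,
                                                "log", lookback)
        fu$usaid_pc <- NA_real_
        for (cv in covs) {
          fu[[cv]] <- extrapolate_covariate(sub[[cv]], sub$year, future,
                                            "auto", lookback)
        }
        for (o in outs) {
          dn <- paste0("denom_", o)
          fu[[dn]] <- extrapolate_covariate(sub[[dn]], sub$year, future,
                                            "log", lookback)
        }
        fu$provenance <- "extrapolated"
        fu
      }, error = function(e) NULL)
      if (is.null(ext)) { excluded <- c(excluded, cid); next }
      rec <- if (is.null(rec)) ext else rbind(rec, ext[, names(rec)])
    }
    ref <- sub$usaid_pc[sub$year == last_year]
    rec$usaid_ref <- if (length(ref)) ref else NA_real_
    rows[[cid]] <- rec
  }
  if (!length(rows)) stop_value("no country has enough look-back history")
  cohort <- do.call(rbind, rows)
  for (cv in covs) cohort[[cv]] <- as.integer(cohort[[cv]] > medians[[cv]])
  structure(tibble::as_tibble(cohort),
            covariates = covs, outcomes = outs, medians = medians,
            excluded = excluded, class = c("aid_cohort", class(tibble::tibble())))
}

#' Assign scenario funding and exposure categories to a cohort
#'
#' @param cohort from [build_cohort()].
#' @param scenario a [scenario_spec()].
#' @param scheme the retrospective [exposure_scheme()] (frozen cuts).
#' @return cohort with `usaid_pc` and `exposure_category` columns.
#' @export
apply_scenario <- function(cohort, scenario, scheme = exposure_scheme()) {
  m <- scenario$multipliers[as.character(cohort$year)]
  if (anyNA(m)) {
    missing_years <- unique(cohort$year[is.na(m)])
    stop_config(paste0("scenario '", scenario$name, "' has no multiplier for year(s) ",
                       paste(missing_years, collapse = ", ")))
  }
  out <- cohort
  out$usaid_pc <- unname(m) * cohort$usaid_ref
  out$exposure_category <- categorize_exposure(out$usaid_pc, scheme)
  attr(out, "scenario") <- scenario$name
  for (a in c("covariates", "outcomes", "medians", "excluded")) {
    attr(out, a) <- attr(cohort, a)
  }
  out
}

cohort_design <- function(fit, cohort_s) {
  covs <- attr(cohort_s, "covariates")
  lev <- exposure_levels()[-1L]
  X_exp <- vapply(lev, function(l) as.numeric(cohort_s$exposure_category == l),
                  numeric(nrow(cohort_s)))
  colnames(X_exp) <- paste0("exposure_", lev)
  used <- intersect(colnames(X_exp), fit$exposure_terms)
  extra <- setdiff(colnames(X_exp)[colSums(X_exp) > 0], fit$exposure_terms)
  if (length(extra)) {
    stop_schema(paste0("cohort contains exposure bands absent from the fit: ",
                       paste(extra, collapse = ", ")))
  }
  X_time_names <- setdiff(fit$beta_terms, c(fit$exposure_terms, covs))
  X_time <- matrix(0, nrow(cohort_s), length(X_time_names),
                   dimnames = list(NULL, X_time_names))
  if (fit$spec$time_controls == "year" && length(X_time_names)) {
    # carry the last observed year's level forward
    last_col <- X_time_names[length(X_time_names)]
    X_time[, last_col] <- 1
  }
  X <- cbind(X_exp[, used, drop = FALSE],
             as.matrix(cohort_s[, covs, drop = FALSE]), X_time)
  X[, fit$beta_terms, drop = FALSE]
}

#' Run the two-stage microsimulation forecast
#'
#' Stage two of the forecaster: for each Monte-Carlo draw, a coefficient
#' vector is sampled from `MVN(beta_hat, cluster-robust vcov)` and the
#' projected deaths per country-year are computed for every scenario
#' with the *same* draw (common random numbers), so scenario contrasts
#' reflect parameter uncertainty, not independent sampling noise.
#' Country intercepts and any time-control levels from the retrospective
#' fit are carried forward unchanged.
#'
#' @param fit an `fe_fit` for the outcome being projected.
#' @param cohort from [build_cohort()].
#' @param scenarios list of [scenario_spec()]; the first is the baseline.
#' @param scheme frozen exposure scheme.
#' @param n_sims Monte-Carlo draws.
#' @param seed integer seed.
#' @param mode coefficient block to draw, as in [deaths_averted_mc()].
#' @return a `forecast_result`.
#' @export
run_forecast <- function(fit, cohort, scenarios = list(scenario_bau(),
                                                       scenario_defunding()),
                         scheme = exposure_scheme(), n_sims = 1000L, seed = 1L,
                         mode = "full") {
  if (length(scenarios) < 2L) stop_config("need at least a baseline and one scenario")
  outcome <- fit$spec$outcome
  alpha_names <- paste0("country_", unique(cohort$country_id))
  known <- alpha_names %in% names(fit$coefficients)
  if (!all(known)) {
    cohort <- cohort[cohort$country_id %in%
                       sub("^country_", "", alpha_names[known]), ]
  }
  yrs <- sort(unique(cohort$year))
  denom <- cohort[[paste0("denom_", outcome)]]
  off <- log(denom / 1000)
  alpha <- fit$coefficients[paste0("country_", cohort$country_id)]
  yf <- factor(cohort$year, levels = yrs)

  sel <- if (mode == "full") fit$beta_terms else fit$exposure_terms
  base_beta <- fit$coefficients[fit$beta_terms]

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  draws <- draw_coefficients(fit, n_sims, mode)

  scen_names <- vapply(scenarios, function(s) s$name, character(1))
  point <- matrix(0, length(yrs), length(scenarios),
                  dimnames = list(yrs, scen_names))
  sims <- array(0, dim = c(n_sims, length(yrs), length(scenarios)),
                dimnames = list(NULL, yrs, scen_names))
  for (s in seq_along(scenarios)) {
    cs <- apply_scenario(cohort, scenarios[[s]], scheme)
    X <- cohort_design(fit, cs)
    eta_fixed_full <- alpha + off + drop(X %*% base_beta)
    point[, s] <- rowsum(exp(eta_fixed_full), yf)[, 1]
    Xs <- X[, sel, drop = FALSE]
    eta_base <- eta_fixed_full - drop(Xs %*% fit$coefficients[sel])
    chunk <- 500L
    for (start in seq(1L, n_sims, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n_sims)
      Eta <- eta_base + Xs %*% t(draws[idx, , drop = FALSE])
      sims[idx, , s] <- t(rowsum(exp(Eta), yf))
    }
  }
  structure(list(outcome = outcome, years = yrs, scenarios = scen_names,
                 point = point, sims = sims,
                 denom_year = rowsum(denom, yf)[, 1],
                 n_sims = as.integer(n_sims), seed = as.integer(seed)),
            class = "forecast_result")
}

#' Annual and cumulative excess deaths with uncertainty intervals
#'
#' Excess in year `t` is projected deaths under the (second) scenario
#' minus the baseline, per draw; the cumulative row is the per-draw sum
#' of annual excess (an exact identity), summarized by percentiles.
#'
#' @param result a `forecast_result`.
#' @param years years to report (default: all projected years).
#' @param level interval level.
#' @export
excess_summary <- function(result, years = NULL, level = 0.95) {
  if (length(result$scenarios) < 2L) stop_value("need two scenarios")
  yrs <- years %||% result$years
  ysel <- match(yrs, result$years)
  if (anyNA(ysel)) stop_value("requested years not in the forecast")
  ex_point <- result$point[ysel, 2] - result$point[ysel, 1]
  ex_draws <- result$sims[, ysel, 2, drop = FALSE] -
    result$sims[, ysel, 1, drop = FALSE]
  ex_draws <- matrix(ex_draws, nrow = result$n_sims)
  a <- (1 - level) / 2
  qs <- apply(ex_draws, 2, quantile, probs = c(a, 1 - a), type = 7)
  cum_draws <- rowSums(ex_draws)
  cum_q <- quantile(cum_draws, c(a, 1 - a), type = 7)
  tibble::tibble(
    year = c(as.character(yrs), paste0(min(yrs), "-", max(yrs))),
    excess = c(unname(ex_point), sum(ex_point)),
    ui_low = c(unname(qs[1, ]), unname(cum_q[1])),
    ui_high = c(unname(qs[2, ]), unname(cum_q[2]))
  )
}

#' Per-year mortality rate ratio, scenario versus baseline
#'
#' Both scenarios share the cohort denominators, so the ratio of rates
#' equals the ratio of projected deaths.
#'
#' @param result a `forecast_result`.
#' @param level interval level.
#' @export
mortality_rate_ratio <- function(result, level = 0.95) {
  if (any(result$point[, 1] <= 0)) {
    bad <- result$years[result$point[, 1] <= 0]
    stop_value(paste0("zero baseline deaths in year(s) ",
                      paste(bad, collapse = ", "), ": ratio undefined"))
  }
  mrr_point <- result$point[, 2] / result$point[, 1]
  mrr_draws <- result$sims[, , 2] / result$sims[, , 1]
  if (is.null(dim(mrr_draws))) mrr_draws <- matrix(mrr_draws, nrow = result$n_sims)
  a <- (1 - level) / 2
  qs <- apply(mrr_draws, 2, quantile, probs = c(a, 1 - a), type = 7)
  tibble::tibble(year = result$years, mrr = unname(mrr_point),
                 ui_low = unname(qs[1, ]), ui_high = unname(qs[2, ]))
}

#' Render an excess-deaths table as "point (low-high)" strings
#' @param summaries named list of [excess_summary()] tibbles (one per
#'   outcome column).
#' @export
format_excess_table <- function(summaries) {
  fmt <- function(s) sprintf("%s (%s-%s)",
                             formatC(round(s$excess), format = "d", big.mark = " "),
                             formatC(round(s$ui_low), format = "d", big.mark = " "),
                             formatC(round(s$ui_high), format = "d", big.mark = " "))
  out <- tibble::tibble(year = summaries[[1]]$year)
  for (nm in names(summaries)) out[[nm]] <- fmt(summaries[[nm]])
  out
}
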