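#' Default outcome definitions for the synthetic generator
#'
#' Each outcome carries its denominator type, a year-2001 mean rate per
#' 1000 of that denominator, an annual secular log-rate drift, and the
#' true rate ratios for the low / intermediate / high funding bands.
#' Injury mortality is generated with all rate ratios equal to 1, so it
#' can serve as a negative-control outcome.
#' @export
default_outcome_defs <- function() {
  list(
    all_age    = list(denom = "population",  base_rate = 11.65, trend = log(0.87) / 20,
                      rr = c(low = 0.94, intermediate = 0.91, high = 0.85)),
    infant     = list(denom = "live_births", base_rate = 45.0,  trend = log(0.55) / 20,
                      rr = c(low = 0.90, intermediate = 0.84, high = 0.74)),
    preschool  = list(denom = "live_births", base_rate = 8.0,   trend = log(0.50) / 20,
                      rr = c(low = 0.79, intermediate = 0.72, high = 0.56)),
    under5     = list(denom = "live_births", base_rate = 73.71, trend = log(0.51) / 20,
                      rr = c(low = 0.86, intermediate = 0.80, high = 0.68)),
    school_age = list(denom = "population",  base_rate = 0.60,  trend = log(0.60) / 20,
                      rr = c(low = 0.91, intermediate = 0.88, high = 0.80)),
    hiv        = list(denom = "population",  base_rate = 0.90,  trend = log(0.60) / 20,
                      rr = c(low = 0.80, intermediate = 0.55, high = 0.35)),
    injuries   = list(denom = "population",  base_rate = 0.75,  trend = 0,
                      rr = c(low = 1, intermediate = 1, high = 1))
  )
}

#' Default covariate path definitions for the synthetic generator
#'
#' Start / end values are 2001 and 2021 cross-country means; `sd` is the
#' cross-country spread on the natural scale; `effect` is the log rate
#' ratio applied to the above-median indicator of the covariate.
#' @export
default_covariate_defs <- function() {
  list(
    gini                  = list(transform = "logit_unit", start = 0.55,  end = 0.58,  sd = 0.07, effect = log(1.06)),
    primary_education     = list(transform = "logit_pct",  start = 67.25, end = 75.61, sd = 20,   effect = log(0.98)),
    education_expenditure = list(transform = "logit_pct",  start = 88.65, end = 88.0,  sd = 1.5,  effect = log(0.93)),
    piped_water           = list(transform = "logit_pct",  start = 77.23, end = 90.10, sd = 15,   effect = log(0.96)),
    adequate_sanitation   = list(transform = "logit_pct",  start = 46.37, end = 77.47, sd = 22,   effect = log(0.92)),
    nurses                = list(transform = "log",        start = 0.99,  end = 1.45,  sd = 0.9,  effect = log(0.88)),
    hospital_beds         = list(transform = "log",        start = 1.70,  end = 1.58,  sd = 1.2,  effect = log(0.99)),
    health_expenditure    = list(transform = "log",        start = 4.33,  end = 5.01,  sd = 1.5,  effect = log(0.94)),
    military_expenditure  = list(transform = "log",        start = 2.24,  end = 1.89,  sd = 1.8,  effect = log(1.08))
  )
}

#' Calibrate a zero-inflated lognormal funding law to target quartiles
#'
#' Solves for the zero mass `p0` and the lognormal `meanlog` / `sdlog`
#' such that the 25th/50th/75th percentiles of the mixture equal the
#' target cut points exactly.
#'
#' @param quartiles increasing positive targets (q25, q50, q75).
#' @return list with `p0`, `meanlog`, `sdlog`.
#' @export
calibrate_funding_law <- function(quartiles = unname(default_cuts())) {
  l <- log(quartiles)
  target <- (l[3] - l[2]) / (l[2] - l[1])
  zr <- function(p0) {
    z <- qnorm((c(0.25, 0.5, 0.75) - p0) / (1 - p0))
    (z[3] - z[2]) / (z[2] - z[1]) - target
  }
  p0 <- if (abs(zr(0)) < 1e-12) 0 else uniroot(zr, c(1e-9, 0.2499), tol = 1e-12)$root
  z <- qnorm((c(0.25, 0.5, 0.75) - p0) / (1 - p0))
  sdlog <- (l[3] - l[1]) / (z[3] - z[1])
  meanlog <- l[2] - sdlog * z[2]
  list(p0 = p0, meanlog = meanlog, sdlog = sdlog)
}

#' Configuration of the synthetic panel generator
#'
#' Defaults emulate the study geometry the pipeline targets: 133
#' countries observed 2001-2023, right-skewed zero-inflated per-capita
#' funding whose low-income quartiles equal the default cut points,
#' country-level log-rate heterogeneity, secular mortality decline,
#' shock-period bumps, and log-linear band effects on each outcome.
#'
#' @param n_countries number of countries.
#' @param years inclusive year range of the panel.
#' @param income_mix proportions of low / lower-middle / upper-middle
#'   income countries.
#' @param outcomes outcome definitions, see [default_outcome_defs()].
#' @param covariates covariate definitions, see [default_covariate_defs()].
#' @param country_effect_sd sd of country log-rate intercepts.
#' @param shock_periods,shock_effect shock periods and the common
#'   log-rate bump applied in them.
#' @param funding_quartiles target low-income quartiles of usaid_pc.
#' @param funding_country_share share of log-funding variance at the
#'   country (persistent) level; the rest is AR(1) year noise.
#' @param funding_rho AR(1) coefficient of the year noise.
#' @param funding_income_scale multiplicative funding scale per income group.
#' @param funding_extra_zero additional never-funded probability per group.
#' @param funding_drift annual log drift of funding (0 = stationary).
#' @param dispersion `"poisson"` or `"nb"`; `nb_size` is the negative
#'   binomial size (smaller = more overdispersion).
#' @param confounding_strength adds `strength * standardized country
#'   funding level` to every country log-rate intercept (0 = none);
#'   used to build confounded fixtures for the triangulation tools.
#' @param seed integer RNG seed; a fixed seed gives byte-identical panels.
#' @export
generator_config <- function(n_countries = 133L,
                             years = c(2001L, 2023L),
                             income_mix = c(low = 0.20, `lower-middle` = 0.40,
                                            `upper-middle` = 0.40),
                             outcomes = default_outcome_defs(),
                             covariates = default_covariate_defs(),
                             country_effect_sd = 0.35,
                             shock_periods = default_shock_periods(),
                             shock_effect = log(1.03),
                             funding_quartiles = unname(default_cuts()),
                             funding_country_share = 0.85,
                             funding_rho = 0.6,
                             funding_income_scale = c(low = 1, `lower-middle` = 0.45,
                                                      `upper-middle` = 0.15),
                             funding_extra_zero = c(low = 0, `lower-middle` = 0.15,
                                                    `upper-middle` = 0.35),
                             funding_drift = 0,
                             dispersion = "poisson",
                             nb_size = 50,
                             confounding_strength = 0,
                             seed = 1L) {
  assert_scalar_number(n_countries, "n_countries", lo = 4)
  if (length(years) != 2L || years[2] <= years[1]) {
    stop_config("years must be an increasing (first, last) pair")
  }
  if (abs(sum(income_mix) - 1) > 1e-8 || any(income_mix < 0)) {
    stop_config("income_mix must be non-negative proportions summing to 1")
  }
  assert_scalar_number(country_effect_sd, "country_effect_sd", lo = 1e-12)
  assert_scalar_number(funding_country_share, "funding_country_share", 0, 1)
  if (!dispersion %in% c("poisson", "nb")) {
    stop_config("dispersion must be 'poisson' or 'nb'")
  }
  for (o in names(outcomes)) {
    rr <- outcomes[[o]]$rr
    if (length(rr) != 3L || any(rr <= 0)) {
      stop_config(sprintf("outcome '%s': rr must be 3 positive values", o))
    }
  }
  cfg <- list(n_countries = as.integer(n_countries), years = as.integer(years),
              income_mix = income_mix, outcomes = outcomes,
              covariates = covariates, country_effect_sd = country_effect_sd,
              shock_periods = shock_periods, shock_effect = shock_effect,
              funding_quartiles = funding_quartiles,
              funding_country_share = funding_country_share,
              funding_rho = funding_rho,
              funding_income_scale = funding_income_scale,
              funding_extra_zero = funding_extra_zero,
              funding_drift = funding_drift,
              dispersion = dispersion, nb_size = nb_size,
              confounding_strength = confounding_strength,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Render a generator configuration to YAML text
#' @param config a [generator_config()].
#' @export
render_generator_config <- function(config) {
  yaml::as.yaml(unclass(config))
}

#' Parse a generator configuration from YAML text
#' @param text YAML string produced by [render_generator_config()].
#' @export
parse_generator_config <- function(text) {
  x <- yaml::yaml.load(text)
  x$outcomes <- lapply(x$outcomes, function(o) {
    o$rr <- unlist(o$rr); o
  })
  do.call(generator_config, x)
}

#' Ground-truth rate-ratio table of a generator configuration
#'
#' @param config a [generator_config()].
#' @return tibble with columns outcome, category, rr.
#' @export
truth_table <- function(config) {
  rows <- lapply(names(config$outcomes), function(o) {
    rr <- config$outcomes[[o]]$rr
    tibble::tibble(outcome = o,
                   category = c("low", "intermediate", "high"),
                   rr = unname(rr))
  })
  do.call(rbind, rows)
}

transform_fun <- function(kind) {
  switch(kind,
         logit_unit = list(f = function(x) logit(clamp(x, 1e-4, 1 - 1e-4)),
                           inv = inv_logit, lo = 0, hi = 1),
         logit_pct = list(f = function(x) logit(clamp(x / 100, 1e-4, 1 - 1e-4)),
                          inv = function(z) 100 * inv_logit(z), lo = 0, hi = 100),
         log = list(f = function(x) log(pmax(x, 1e-8)), inv = exp, lo = 0, hi = Inf),
         identity = list(f = identity, inv = identity, lo = -Inf, hi = Inf),
         stop_config(paste0("unknown transform: ", kind)))
}

transformed_sd <- function(def) {
  tr <- transform_fun(def$transform)
  hi <- min(def$start + def$sd, if (is.finite(tr$hi)) 0.999 * tr$hi else Inf)
  lo <- max(def$start - def$sd, 0.001 * max(def$start, 1e-6))
  (tr$f(hi) - tr$f(lo)) / 2
}

ar1_path <- function(n, rho, sd_marginal) {
  if (sd_marginal <= 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd_marginal)
  innov_sd <- sd_marginal * sqrt(1 - rho^2)
  for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + rnorm(1, 0, innov_sd)
  e
}

#' Generate a synthetic country-year panel with known ground truth
#'
#' Simulates, for each country, an income group, a population path,
#' covariate paths (linear drift plus AR(1) noise on a transformed
#' scale), a persistent zero-inflated lognormal funding path, and death
#' counts drawn Poisson (or negative-binomial) around the configured
#' log-linear rate model. Returns the validated panel together with a
#' ground-truth sidecar (true rate ratios, country effects, per-record
#' expected deaths) used by the parameter-recovery and attribution
#' oracles.
#'
#' @param config a [generator_config()].
#' @return list with elements `panel` (an `aid_panel`) and `truth`.
#' @export
generate_panel <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) stop_config("invalid config")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  yrs <- seq(config$years[1], config$years[2])
  ny <- length(yrs)
  nc <- config$n_countries
  t_idx <- yrs - yrs[1]

  counts <- floor(config$income_mix * nc)
  rem <- nc - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  groups <- rep(names(config$income_mix), counts)
  country_id <- sprintf("C%03d", seq_len(nc))

  # populations: lognormal size, income-group-specific growth
  growth <- c(low = 0.020, `lower-middle` = 0.013, `upper-middle` = 0.008)
  pop0 <- rlnorm(nc, log(1e7), 1.5)
  pop <- outer(pop0, rep(1, ny)) * exp(outer(growth[groups], t_idx))

  # fertility (for live births), declining like the covariate paths
  fert_def <- list(transform = "log", start = 3.94, end = 2.87, sd = 1.2)
  fert <- matrix(0, nc, ny)
  tr <- transform_fun("log")
  f_start <- tr$f(fert_def$start); f_end <- tr$f(fert_def$end)
  f_sd <- transformed_sd(fert_def)
  for (i in seq_len(nc)) {
    b <- rnorm(1, 0, f_sd)
    drift <- f_start + (f_end - f_start) * t_idx / 20
    fert[i, ] <- tr$inv(drift + b + ar1_path(ny, 0.7, 0.15 * f_sd))
  }
  live_births <- pop * 0.0075 * fert

  # covariate paths + reference medians (mid-study mean path value)
  cov_names <- names(config$covariates)
  cov_vals <- list()
  ref_median <- setNames(numeric(length(cov_names)), cov_names)
  for (cv in cov_names) {
    def <- config$covariates[[cv]]
    tr <- transform_fun(def$transform)
    s_t <- tr$f(def$start); e_t <- tr$f(def$end)
    sd_t <- transformed_sd(def)
    m <- matrix(0, nc, ny)
    for (i in seq_len(nc)) {
      b <- rnorm(1, 0, sd_t)
      drift <- s_t + (e_t - s_t) * t_idx / 20
      m[i, ] <- tr$inv(drift + b + ar1_path(ny, 0.7, 0.15 * sd_t))
    }
    cov_vals[[cv]] <- m
    # effects act on the pooled-median indicator -- the same
    # dichotomization rule the analysis model applies
    ref_median[cv] <- median(m)
  }

  # funding: calibrated zero-inflated lognormal, persistent by country
  law <- calibrate_funding_law(config$funding_quartiles)
  sigma_c <- law$sdlog * sqrt(config$funding_country_share)
  sigma_y <- law$sdlog * sqrt(1 - config$funding_country_share)
  zero_p <- clamp(law$p0 + config$funding_extra_zero[groups], 0, 0.95)
  funded <- runif(nc) >= zero_p
  level <- law$meanlog + log(config$funding_income_scale[groups]) +
    rnorm(nc, 0, sigma_c)
  usaid_pc <- matrix(0, nc, ny)
  for (i in seq_len(nc)) {
    if (funded[i]) {
      usaid_pc[i, ] <- exp(level[i] + ar1_path(ny, config$funding_rho, sigma_y) +
                             config$funding_drift * t_idx)
    }
  }

  scheme <- exposure_scheme(config$funding_quartiles)
  cat_mat <- matrix(as.character(categorize_exposure(as.vector(usaid_pc), scheme)),
                    nc, ny)

  # country log-rate intercepts per outcome (+ optional confounding)
  out_names <- names(config$outcomes)
  conf_shift <- if (config$confounding_strength != 0) {
    lv <- ifelse(funded, level, min(level) - 1)
    config$confounding_strength * as.numeric(scale(lv))
  } else numeric(nc)
  alpha <- sapply(out_names, function(o) {
    rnorm(nc, 0, config$country_effect_sd) + conf_shift
  })

  shock_in <- rep(FALSE, ny)
  for (p in config$shock_periods) shock_in <- shock_in | (yrs %in% p)

  ii <- rep(seq_len(nc), each = ny)
  tt <- rep(seq_len(ny), times = nc)
  df <- tibble::tibble(
    country_id = country_id[ii],
    year = yrs[tt],
    income_group = groups[ii],
    population = pop[cbind(ii, tt)],
    live_births = live_births[cbind(ii, tt)],
    usaid_pc = usaid_pc[cbind(ii, tt)]
  )
  df$usaid_total <- df$usaid_pc * df$population
  for (cv in cov_names) df[[cv]] <- cov_vals[[cv]][cbind(ii, tt)]

  cov_effect <- rep(0, nrow(df))
  for (cv in cov_names) {
    cov_effect <- cov_effect +
      config$covariates[[cv]]$effect * as.numeric(df[[cv]] > ref_median[cv])
  }
  cat_vec <- cat_mat[cbind(ii, tt)]
  shock_vec <- config$shock_effect * as.numeric(shock_in[tt])

  expected <- list()
  for (o in out_names) {
    def <- config$outcomes[[o]]
    log_rr <- c(baseline = 0, log(def$rr))
    denom <- if (def$denom == "live_births") df$live_births else df$population
    log_lambda <- log(def$base_rate) + alpha[cbind(ii, match(o, out_names))] +
      def$trend * (df$year - yrs[1]) + shock_vec + cov_effect +
      log_rr[cat_vec]
    mu <- exp(log_lambda) * denom / 1000
    deaths <- if (config$dispersion == "poisson") {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = config$nb_size)
    }
    df[[paste0("deaths_", o)]] <- as.numeric(deaths)
    df[[paste0("denom_", o)]] <- denom
    df[[paste0("rate_", o)]] <- 1000 * deaths / denom
    expected[[o]] <- tibble::tibble(
      country_id = df$country_id, year = df$year, outcome = o,
      category = cat_vec, mu = mu,
      mu_null = mu / exp(log_rr[cat_vec]))
  }

  panel <- as_panel(df, outcomes = out_names, covariates = cov_names,
                    year_range = c(yrs[1], 2030L))
  truth <- list(
    rr = truth_table(config),
    country_effects = tibble::tibble(country_id = country_id,
                                     income_group = groups,
                                     funded = funded,
                                     funding_level = ifelse(funded, exp(level), 0)),
    alpha = alpha,
    ref_median = ref_median,
    expected = do.call(rbind, expected),
    funding_law = law,
    scheme = scheme,
    config = config
  )
  list(panel = panel, truth = truth)
}

#' Analytic deaths averted implied by the generator's ground truth
#'
#' Sums, over exposed records of one outcome, the expected extra deaths
#' had the true band rate ratio been 1: `sum(mu_null - mu)`.
#'
#' @param truth the truth sidecar from [generate_panel()].
#' @param outcome outcome name.
#' @param years optional year filter.
#' @export
truth_averted <- function(truth, outcome, years = NULL) {
  e <- truth$expected[truth$expected$outcome == outcome, ]
  if (!is.null(years)) e <- e[e$year %in% years, ]
  sum(e$mu_null - e$mu)
}
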