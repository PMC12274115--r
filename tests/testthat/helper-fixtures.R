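# Shared fixtures, generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# mid-sized panel with the default outcome set
small_sim <- function() {
  cached("small_sim", generate_panel(
    generator_config(n_countries = 40, years = c(2001L, 2021L), seed = 42L)))
}

# study-sized geometry, two outcomes, used by slower checks
paper_sim <- function() {
  cached("paper_sim", generate_panel(
    generator_config(n_countries = 133L, years = c(2001L, 2021L),
                     outcomes = default_outcome_defs()[c("all_age", "under5")],
                     seed = 42L)))
}

# 2 countries x 2 years; treated country's rate drops 100 -> 80 while the
# control stays at 100, treated exposed (high band) only in year 2.
# The FE-Poisson exposure coefficient has the closed form
# log((80/100) / (100/100)).
toy_2x2_panel <- function() {
  df <- tibble::tibble(
    country_id = c("A", "A", "B", "B"),
    year = c(2001L, 2002L, 2001L, 2002L),
    income_group = "low",
    population = 1e6,
    live_births = 2e4,
    usaid_total = c(0, 0, 0, 10 * 1e6),
    usaid_pc = c(0, 0, 0, 10),
    deaths_all_age = c(100, 100, 100, 80),
    denom_all_age = 1000,
    rate_all_age = 1000 * c(100, 100, 100, 80) / 1000
  )
  as_panel(df, outcomes = "all_age", covariates = character(0))
}

toy_2x2_spec <- function() {
  model_spec("all_age", time_controls = "year")
}

# brute-force percentile with linear interpolation between order statistics
interp_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
}

# minimal fe_fit carrier for rr_table arithmetic checks
fake_fit <- function(beta, se) {
  structure(list(coefficients = beta, se = se,
                 exposure_terms = names(beta), beta_terms = names(beta)),
            class = "fe_fit")
}
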