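test_that("covariate extrapolation continues transformed-linear trends exactly", {
  yrs <- 2010:2020
  expect_equal(extrapolate_covariate(rep(4.2, 11), yrs, 2021:2023),
               rep(4.2, 3))
  # exact linear history on the log scale continues the line (OLS oracle)
  vals <- exp(0.3 + 0.05 * (yrs - 2010))
  co <- coef(lm(log(vals) ~ yrs))
  expect_equal(extrapolate_covariate(vals, yrs, 2021:2025, transform = "log"),
               exp(co[1] + co[2] * 2021:2025), tolerance = 1e-10,
               ignore_attr = TRUE)
  # proportions stay inside their admissible range
  prop <- c(0.90, 0.93, 0.95, 0.965, 0.975, 0.982, 0.987, 0.991, 0.994, 0.996)
  out <- extrapolate_covariate(prop, 2012:2021, 2022:2030,
                               transform = "logit_unit")
  expect_true(all(out <= 1 & out >= 0))
  expect_error(extrapolate_covariate(c(1, 2), 2001:2002, 2003),
               class = "aidmort_value_error")
})

test_that("the projection cohort has one record per country-year with frozen medians", {
  sim <- small_sim()
  cohort <- build_cohort(sim$panel, horizon = 2024:2030)
  expect_identical(nrow(cohort), length(unique(sim$panel$country_id)) * 7L)
  expect_true(all(cohort$provenance == "extrapolated"))
  med <- attr(dichotomize_covariates(sim$panel), "medians")
  expect_equal(attr(cohort, "medians"), med)
  expect_true(all(unlist(cohort[, panel_covariates(sim$panel)]) %in% 0:1))
  # horizon years inside the observed window are copied as observed
  mixed <- build_cohort(sim$panel, horizon = 2020:2024)
  obs <- mixed[mixed$provenance == "observed" & mixed$country_id == "C001", ]
  src <- sim$panel[sim$panel$country_id == "C001" &
                     sim$panel$year %in% 2020:2021, ]
  expect_equal(obs$population, src$population)
  # denominators continue a monotone history monotonically
  one <- cohort[cohort$country_id == "C001", ]
  hist_pop <- sim$panel$population[sim$panel$country_id == "C001"]
  if (all(diff(log(hist_pop)) > 0)) {
    expect_true(all(diff(one$population) > 0))
  }
})

test_that("scenario application freezes cuts and rescales reference funding", {
  sim <- small_sim()
  cohort <- build_cohort(sim$panel, horizon = 2024:2030)
  sch <- exposure_scheme()
  bau <- apply_scenario(cohort, scenario_bau(), sch)
  ref_cat <- categorize_exposure(cohort$usaid_ref, sch)
  expect_equal(as.character(bau$exposure_category), as.character(ref_cat))
  cut <- apply_scenario(cohort, scenario_defunding(), sch)
  expect_true(all(cut$exposure_category[cut$year >= 2026] == "baseline"))
  # 83% cut applied to a high-band reference of 20.45 gives $3.48,
  # which sits below the intermediate cut of 3.97: the low band
  expect_equal(0.17 * 20.45, 3.4765)
  expect_equal(as.character(categorize_exposure(0.17 * 20.45, sch)), "low")
  bad <- scenario_spec("short", c(`2024` = 1))
  expect_error(apply_scenario(cohort, bad, sch), class = "aidmort_config_error")
})

test_that("a 3-country toy forecast matches the closed-form excess", {
  # hand-made fit: three countries, known intercepts, high-band RR 0.85
  rr_high <- 0.85
  fit <- structure(list(
    coefficients = c(country_A = log(10), country_B = log(12),
                     country_C = log(8), exposure_high = log(rr_high)),
    beta_terms = "exposure_high", exposure_terms = "exposure_high",
    vcov_cluster = matrix(0, 4, 4,
                          dimnames = list(c("country_A", "country_B", "country_C",
                                            "exposure_high"),
                                          c("country_A", "country_B", "country_C",
                                            "exposure_high"))),
    spec = model_spec("all_age"),
    se = c(exposure_high = 0)), class = "fe_fit")
  cohort <- tibble::tibble(
    country_id = rep(c("A", "B", "C"), each = 2),
    year = rep(2025:2026, 3),
    denom_all_age = rep(c(1e6, 2e6, 5e5), each = 2),
    usaid_ref = rep(c(10, 8, 12), each = 2),
    provenance = "extrapolated")
  attr(cohort, "covariates") <- character(0)
  attr(cohort, "outcomes") <- "all_age"
  horizon <- setNames(c(1, 1), 2025:2026)
  res <- run_forecast(fit, cohort,
                      list(scenario_spec("bau", horizon),
                           scenario_spec("cut", horizon * 0)),
                      n_sims = 10, seed = 1)
  # analytic: every country sits in the high band under bau
  mu_bau <- exp(fit$coefficients[paste0("country_", c("A", "B", "C"))]) *
    c(1e6, 2e6, 5e5) / 1000 * rr_high
  expected_excess <- sum(mu_bau * (1 / rr_high - 1))
  ex <- excess_summary(res)
  expect_equal(ex$excess[1], expected_excess, tolerance = 1e-10)
  expect_equal(ex$excess[2], expected_excess, tolerance = 1e-10)
  # zero vcov: every draw identical, intervals collapse
  expect_equal(ex$ui_low, ex$excess, tolerance = 1e-10)
  mrr <- mortality_rate_ratio(res)
  expect_equal(mrr$mrr, rep(1 / rr_high, 2), tolerance = 1e-12)
})

test_that("identical scenarios produce exactly zero excess in every draw", {
  sim <- small_sim()
  f <- fit_fe_poisson(sim$panel, model_spec("all_age"))
  cohort <- build_cohort(sim$panel, horizon = 2024:2027)
  res <- run_forecast(f, cohort,
                      list(scenario_bau(2024:2027), scenario_bau(2024:2027)),
                      n_sims = 50, seed = 3)
  expect_true(all(res$sims[, , 2] == res$sims[, , 1]))
  ex <- excess_summary(res)
  expect_true(all(ex$excess == 0))
  expect_true(all(ex$ui_low == 0) && all(ex$ui_high == 0))
  expect_true(all(mortality_rate_ratio(res)$mrr == 1))
})

test_that("forecasts are seed-deterministic with coherent per-draw identities", {
  sim <- small_sim()
  f <- fit_fe_poisson(sim$panel, model_spec("all_age"))
  cohort <- build_cohort(sim$panel)
  r1 <- run_forecast(f, cohort, n_sims = 100, seed = 11)
  r2 <- run_forecast(f, cohort, n_sims = 100, seed = 11)
  expect_identical(r1, r2)
  # the cumulative row is built from per-draw sums of annual excess
  ex_draws <- r1$sims[, , 2] - r1$sims[, , 1]
  ex <- excess_summary(r1, years = 2025:2030)
  ysel <- match(2025:2030, r1$years)
  expect_equal(ex$excess[7], sum(ex$excess[1:6]), tolerance = 1e-9)
  cum_draws <- rowSums(ex_draws[, ysel])
  expect_equal(unname(ex$ui_low[7]),
               unname(quantile(cum_draws, 0.025, type = 7)), tolerance = 1e-9)
  # weaker funding never reduces projected deaths when fitted RRs < 1
  expect_true(all(rr_table(f)$rr < 1))
  expect_true(all(r1$point[, 2] >= r1$point[, 1]))
  # MRR exceeds 1 exactly where excess is positive (shared denominators)
  mrr <- mortality_rate_ratio(r1)
  ann_ex <- r1$point[, 2] - r1$point[, 1]
  expect_true(all((mrr$mrr > 1) == (ann_ex > 0)))
})

test_that("interval endpoints are stable when doubling the simulation count", {
  sim <- paper_sim()
  f <- fit_fe_poisson(sim$panel, model_spec("all_age", time_controls = "year"))
  cohort <- build_cohort(sim$panel)
  r1 <- run_forecast(f, cohort, n_sims = 1000, seed = 21)
  r2 <- run_forecast(f, cohort, n_sims = 2000, seed = 21)
  e1 <- excess_summary(r1, years = 2025:2030)
  e2 <- excess_summary(r2, years = 2025:2030)
  expect_lt(max(abs(e1$ui_low / e2$ui_low - 1)), 0.02)
  expect_lt(max(abs(e1$ui_high / e2$ui_high - 1)), 0.02)
})

test_that("cumulative rows sum printed-style annual inputs exactly", {
  ann_all <- c(1776539, 2499525, 2477031, 2454816, 2432809, 2411030)
  ann_u5 <- c(689900, 828970, 798188, 768294, 739719, 712098)
  make_result <- function(ann) {
    point <- cbind(baseline = rep(1e7, 6), cut = 1e7 + ann)
    rownames(point) <- 2025:2030
    sims <- array(rep(t(point), each = 4), dim = c(4, 6, 2),
                  dimnames = list(NULL, 2025:2030, c("baseline", "cut")))
    structure(list(outcome = "x", years = 2025:2030,
                   scenarios = c("baseline", "cut"), point = point,
                   sims = sims, denom_year = rep(1e9, 6),
                   n_sims = 4L, seed = 1L), class = "forecast_result")
  }
  ex_all <- excess_summary(make_result(ann_all))
  expect_equal(ex_all$excess[7], 14051750)
  ex_u5 <- excess_summary(make_result(ann_u5))
  # exact summation of the published annual figures (their published
  # cumulative, 4 537 157, differs by 12 deaths of per-row rounding)
  expect_equal(ex_u5$excess[7], 4537169)
  expect_lt(abs(ex_u5$excess[7] - 4537157), 15)
  expect_equal(ex_u5$year[7], "2025-2030")
  fmt <- format_excess_table(list(all_age = ex_all, under5 = ex_u5))
  expect_match(fmt$all_age[7], "^14 051 750")
})
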