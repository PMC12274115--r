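test_that("the 2x2 exposure coefficient equals the closed-form ratio of ratios", {
  panel <- toy_2x2_panel()
  for (engine in c("dummy", "within")) {
    f <- fit_fe_poisson(panel, toy_2x2_spec(), engine = engine)
    expect_equal(unname(f$coefficients["exposure_high"]), log(0.8),
                 tolerance = 1e-8)
  }
})

test_that("dummy-variable and within formulations agree on the coefficients", {
  sim <- generate_panel(generator_config(n_countries = 10,
                                         years = c(2001L, 2012L), seed = 3L))
  spec <- model_spec("all_age")
  f1 <- fit_fe_poisson(sim$panel, spec, engine = "dummy")
  f2 <- fit_fe_poisson(sim$panel, spec, engine = "within")
  expect_lt(max(abs(f1$coefficients[f1$beta_terms] -
                      f2$coefficients[f2$beta_terms])), 1e-6)
  expect_lt(max(abs(sort(f1$coefficients[grep("country", names(f1$coefficients))]) -
                      sort(f2$coefficients[grep("country", names(f2$coefficients))]))),
            1e-6)
})

test_that("cluster vcov matches an explicit matrix computation and sandwich", {
  sim <- generate_panel(generator_config(n_countries = 8,
                                         years = c(2001L, 2012L), seed = 13L))
  f <- fit_fe_poisson(sim$panel, model_spec("all_age"))
  # explicit brute-force sandwich, cluster by cluster
  M <- f$model_matrix
  s <- f$score_residuals
  G <- nlevels(f$cluster)
  meat <- matrix(0, ncol(M), ncol(M))
  for (g in levels(f$cluster)) {
    sg <- colSums(M[f$cluster == g, , drop = FALSE] * s[f$cluster == g])
    meat <- meat + tcrossprod(sg)
  }
  W <- f$weights * f$fitted
  A_inv <- solve(crossprod(M * sqrt(W)))
  V_brute <- A_inv %*% meat %*% A_inv * G / (G - 1)
  expect_equal(unname(f$vcov_cluster), unname((V_brute + t(V_brute)) / 2),
               tolerance = 1e-8)
  # independent implementation as oracle
  skip_if_not_installed("sandwich")
  dfx <- data.frame(f$model_matrix, check.names = TRUE)
  g <- glm(f$y ~ 0 + ., data = dfx, family = quasipoisson, offset = f$offset)
  V_sand <- sandwich::vcovCL(g, cluster = f$cluster, type = "HC0", cadjust = TRUE)
  idx <- make.names(f$exposure_terms)
  expect_equal(unname(sqrt(diag(f$vcov_cluster)[f$exposure_terms])),
               unname(sqrt(diag(V_sand)[idx])), tolerance = 1e-4)
})

test_that("observation-level clustering reduces to the HC sandwich", {
  panel <- toy_2x2_panel()
  f <- fit_fe_poisson(panel, toy_2x2_spec())
  n <- length(f$y)
  V_obs <- cluster_vcov(f, cluster = seq_len(n))
  W <- f$weights * f$fitted
  A_inv <- solve(crossprod(f$model_matrix * sqrt(W)))
  meat <- crossprod(f$model_matrix * f$score_residuals)
  V_hc <- A_inv %*% meat %*% A_inv * n / (n - 1)
  expect_equal(unname(V_obs), unname((V_hc + t(V_hc)) / 2), tolerance = 1e-10)
})

test_that("cluster and model-based SEs agree under correct independence", {
  # both estimate the same asymptotic variance when the Poisson model is
  # correct; the ratio is noisy in any one panel (a few large countries
  # dominate the meat) and needs many clusters, so it is computed on
  # wide panels and averaged over replicates
  ratios <- sapply(1:8, function(s) {
    sim <- generate_panel(generator_config(
      n_countries = 400, years = c(2001L, 2021L),
      outcomes = default_outcome_defs()["all_age"], seed = 6000L + s))
    f <- fit_fe_poisson(sim$panel, model_spec("all_age", time_controls = "year"))
    se_model <- sqrt(diag(f$bread))[f$exposure_terms]
    mean(f$se[f$exposure_terms] / se_model)
  })
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("rate-ratio tables exponentiate with Wald intervals", {
  f0 <- fake_fit(c(exposure_high = 0), c(exposure_high = 0.1))
  t0 <- rr_table(f0)
  expect_equal(t0$rr, 1)
  expect_equal(t0$conf_low * t0$conf_high, 1, tolerance = 1e-12)
  f1 <- fake_fit(c(exposure_high = -0.1625), c(exposure_high = 0.045))
  t1 <- rr_table(f1)
  expect_equal(sprintf("%.2f (%.2f-%.2f)", t1$rr, t1$conf_low, t1$conf_high),
               "0.85 (0.78-0.93)")
  # CI ordering and monotonicity in the SE
  f2 <- fake_fit(c(exposure_high = -0.1625), c(exposure_high = 0.09))
  t2 <- rr_table(f2)
  expect_true(t1$conf_low <= t1$rr && t1$rr <= t1$conf_high)
  expect_gt(t1$conf_low, t2$conf_low)
  expect_lt(t1$conf_high, t2$conf_high)
})

test_that("the offset is invariant to rescaling all denominators", {
  sim <- small_sim()
  spec <- model_spec("all_age")
  f1 <- fit_fe_poisson(sim$panel, spec)
  df <- as.data.frame(sim$panel)
  for (o in panel_outcomes(sim$panel)) {
    df[[paste0("denom_", o)]] <- df[[paste0("denom_", o)]] * 10
    df[[paste0("rate_", o)]] <- 1000 * df[[paste0("deaths_", o)]] /
      df[[paste0("denom_", o)]]
  }
  p10 <- as_panel(df, panel_outcomes(sim$panel), panel_covariates(sim$panel))
  f2 <- fit_fe_poisson(p10, spec)
  expect_equal(f1$coefficients[f1$beta_terms], f2$coefficients[f2$beta_terms],
               tolerance = 1e-6)
})

test_that("population weighting and continuous exposure run and stay sane", {
  sim <- small_sim()
  fw <- fit_fe_poisson(sim$panel, model_spec("all_age", weights = "population"))
  expect_true(all(is.finite(exp(fw$coefficients))))
  fc <- fit_fe_poisson(sim$panel, model_spec("all_age", exposure = "continuous"))
  expect_identical(fc$exposure_terms, "exposure_log1p")
  expect_lt(fc$coefficients["exposure_log1p"], 0)
})

test_that("stratified fits are local and recover effect ordering", {
  sim <- small_sim()
  pan <- dichotomize_covariates(sim$panel)
  spec <- model_spec("all_age")
  ids <- unique(pan$country_id)
  one <- fit_stratified(pan, spec, setNames(rep("all", length(ids)), ids))
  full <- fit_fe_poisson(pan, spec)
  expect_equal(one$all$coefficients[one$all$beta_terms],
               full$coefficients[full$beta_terms], tolerance = 1e-8)
  expect_error(fit_stratified(pan, spec, list()), class = "aidmort_value_error")

  # two generator populations with different true high-band effects
  strong <- default_outcome_defs()["all_age"]
  strong$all_age$rr <- c(low = 0.85, intermediate = 0.75, high = 0.60)
  weak <- default_outcome_defs()["all_age"]
  weak$all_age$rr <- c(low = 0.99, intermediate = 0.98, high = 0.95)
  hits <- 0L
  for (s in 1:5) {
    a <- generate_panel(generator_config(n_countries = 40, years = c(2001L, 2015L),
                                         outcomes = strong, seed = 700L + s))$panel
    b <- generate_panel(generator_config(n_countries = 40, years = c(2001L, 2015L),
                                         outcomes = weak, seed = 800L + s))$panel
    bdf <- as.data.frame(b)
    bdf$country_id <- sub("^C", "D", bdf$country_id)
    comb <- as_panel(rbind(as.data.frame(a), bdf), panel_outcomes(a),
                     panel_covariates(a))
    map <- setNames(ifelse(grepl("^C", unique(comb$country_id)), "strong", "weak"),
                    unique(comb$country_id))
    fits <- fit_stratified(comb, model_spec("all_age", time_controls = "year"), map)
    rr_s <- rr_table(fits$strong); rr_w <- rr_table(fits$weak)
    hits <- hits + (rr_s$rr[rr_s$term == "exposure_high"] <
                      rr_w$rr[rr_w$term == "exposure_high"])
  }
  expect_gte(hits, 4L)
})

test_that("negative-binomial fits agree with Poisson when data are Poisson", {
  base <- list(n_countries = 60L, years = c(2001L, 2012L),
               outcomes = default_outcome_defs()["all_age"], seed = 77L)
  pois <- generate_panel(do.call(generator_config, base))
  spec <- model_spec("all_age", time_controls = "year")
  fp <- fit_fe_poisson(pois$panel, spec)
  fn <- negative_binomial_fit(pois$panel, spec)
  expect_gt(fn$theta, 1000)                 # dispersion at the Poisson boundary
  expect_lt(max(abs(exp(fn$coefficients[fn$exposure_terms]) /
                      exp(fp$coefficients[fp$exposure_terms]) - 1)), 0.02)
})

test_that("negative-binomial fits detect overdispersion in NB data", {
  base <- list(n_countries = 60L, years = c(2001L, 2012L),
               outcomes = default_outcome_defs()["all_age"], seed = 78L,
               dispersion = "nb", nb_size = 50)
  nb <- generate_panel(do.call(generator_config, base))
  spec <- model_spec("all_age", time_controls = "year")
  fp <- fit_fe_poisson(nb$panel, spec)
  fn <- negative_binomial_fit(nb$panel, spec)
  expect_lt(abs(log(fn$theta / 50)), 0.5)   # size parameter recovered
  # point estimates agree within sampling error
  expect_lt(max(abs(fn$coefficients[fn$exposure_terms] -
                      fp$coefficients[fp$exposure_terms])),
            3 * max(fp$se[fp$exposure_terms]))
  # model-based (non-robust) SEs differ strongly across families
  se_model_p <- sqrt(diag(fp$bread))[fp$exposure_terms]
  se_model_n <- sqrt(diag(fn$bread))[fn$exposure_terms]
  expect_gt(mean(se_model_n / se_model_p), 2)
  # truth recovered within the NB fit's own uncertainty
  expect_lt(abs(fn$coefficients["exposure_high"] - log(0.85)),
            3 * fn$se["exposure_high"] + 0.03)
})

test_that("degenerate designs raise informative estimation errors", {
  sim <- small_sim()
  df <- as.data.frame(sim$panel)
  df$usaid_pc <- 0
  df$usaid_total <- 0
  p0 <- as_panel(df, panel_outcomes(sim$panel), panel_covariates(sim$panel))
  # no exposure variation at all: every band indicator is empty and dropped
  f <- fit_fe_poisson(p0, model_spec("all_age"))
  expect_length(f$exposure_terms, 0L)
  expect_identical(nrow(rr_table(f)), 0L)
})
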