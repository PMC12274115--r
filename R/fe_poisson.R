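#' Model specification for the fixed-effects rate regression
#'
#' @param outcome registered outcome name (its `deaths_` / `denom_`
#'   columns are the response and offset).
#' @param scheme exposure-categorization scheme; ignored for continuous
#'   exposure coding.
#' @param exposure `"categorical"` (indicator per non-baseline band) or
#'   `"continuous"` (log(1 + usaid_pc)).
#' @param covariates covariate columns entered as above-median
#'   indicators; `NULL` means the panel's registered set.
#' @param time_controls `"shocks"` (multi-year shock-period dummies),
#'   `"shocks_alt"` (single crisis years), or `"year"` (full year
#'   dummies, first year as reference).
#' @param family `"poisson"` (quasi-likelihood contract, cluster-robust
#'   inference) or `"nb"` (negative binomial with estimated dispersion).
#' @param weights `"none"` or `"population"` (analytic weights on the
#'   score contributions, normalized to mean 1).
#' @export
model_spec <- function(outcome, scheme = exposure_scheme(),
                       exposure = c("categorical", "continuous"),
                       covariates = NULL,
                       time_controls = c("shocks", "shocks_alt", "year"),
                       family = c("poisson", "nb"),
                       weights = c("none", "population")) {
  structure(list(outcome = outcome, scheme = scheme,
                 exposure = match.arg(exposure), covariates = covariates,
                 time_controls = match.arg(time_controls),
                 family = match.arg(family), weights = match.arg(weights)),
            class = "model_spec")
}

time_control_matrix <- function(years, mode) {
  switch(mode,
         shocks = shock_dummies(years, default_shock_periods()),
         shocks_alt = shock_dummies(years, alt_shock_periods()),
         year = shock_dummies(years, "year"))
}

# Assemble response, offset, exposure / covariate / time design columns.
build_design <- function(panel, spec) {
  if (!spec$outcome %in% panel_outcomes(panel)) {
    stop_schema(sprintf("outcome '%s' not registered in panel", spec$outcome))
  }
  covs <- spec$covariates %||% panel_covariates(panel)
  medians <- attr(panel, "medians")
  if (!isTRUE(attr(panel, "dichotomized"))) {
    panel <- dichotomize_covariates(panel, covs)
    medians <- attr(panel, "medians")
  }
  y <- panel[[paste0("deaths_", spec$outcome)]]
  denom <- panel[[paste0("denom_", spec$outcome)]]
  if (spec$exposure == "categorical") {
    cat <- categorize_exposure(panel$usaid_pc, spec$scheme)
    lev <- exposure_levels()[-1L]
    X_exp <- vapply(lev, function(l) as.numeric(cat == l), numeric(nrow(panel)))
    colnames(X_exp) <- paste0("exposure_", lev)
    X_exp <- X_exp[, colSums(X_exp) > 0, drop = FALSE]
  } else {
    X_exp <- matrix(log1p(panel$usaid_pc), ncol = 1,
                    dimnames = list(NULL, "exposure_log1p"))
  }
  X_cov <- as.matrix(panel[, covs, drop = FALSE])
  X_time <- time_control_matrix(panel$year, spec$time_controls)
  X <- cbind(X_exp, X_cov, X_time)
  w <- if (spec$weights == "population") {
    panel$population / mean(panel$population)
  } else rep(1, nrow(panel))

  keep <- complete.cases(X) & !is.na(y) & !is.na(denom) & denom > 0
  n_na <- sum(!keep)
  X <- X[keep, , drop = FALSE]; y <- y[keep]; denom <- denom[keep]
  w <- w[keep]
  cluster <- panel$country_id[keep]
  years <- panel$year[keep]

  zero_ct <- tapply(y, cluster, sum)
  drop_ct <- names(zero_ct)[zero_ct == 0]
  if (length(drop_ct)) {
    keep2 <- !(cluster %in% drop_ct)
    X <- X[keep2, , drop = FALSE]; y <- y[keep2]; denom <- denom[keep2]
    w <- w[keep2]; years <- years[keep2]; cluster <- cluster[keep2]
  }
  if (length(unique(cluster)) < 2L) {
    stop_value("fewer than 2 countries with usable data")
  }
  # columns without within-country variation (shock periods outside the
  # panel window, constant covariates, or indicators that never change
  # inside any country) are absorbed by the country intercepts and are
  # inestimable under fixed effects; drop and log them
  cl_f <- factor(cluster)
  absorbed <- apply(X, 2, function(col) {
    !any(tapply(col, cl_f, function(v) length(unique(v)) > 1L))
  })
  dropped_cols <- colnames(X)[absorbed]
  X <- X[, !absorbed, drop = FALSE]
  list(y = y, X = X, offset = log(denom / 1000), weights = w,
       dropped_columns = dropped_cols,
       cluster = factor(cluster), years = years,
       exposure_cols = intersect(colnames(X_exp), colnames(X)),
       n_dropped_na = n_na,
       dropped_countries = drop_ct, medians = medians)
}

quasi_poisson_loglik <- function(y, mu, w) {
  sum(w * (y * log(mu) - mu - lgamma(y + 1)))
}

#' Cluster-robust sandwich variance
#'
#' Computes `A^{-1} B A^{-1}` where `A` is the observed information
#' (`X' W X` at the fitted working weights) and `B` the outer product of
#' within-cluster summed score contributions, multiplied by the
#' small-sample factor `G / (G - 1)` (`G` clusters).
#'
#' @param fit an `fe_fit`.
#' @param cluster clustering factor; defaults to country. Passing
#'   `seq_along(fit$y)` gives the observation-level (HC) sandwich.
#' @return symmetric matrix over all model coefficients (country
#'   intercepts included).
#' @export
cluster_vcov <- function(fit, cluster = fit$cluster) {
  cluster <- factor(cluster)
  G <- nlevels(cluster)
  if (G < 2L) stop_variance("need at least 2 clusters")
  M <- fit$model_matrix
  s_resid <- fit$score_residuals                 # w * (y - mu) * mu / V(mu)
  S <- rowsum(M * s_resid, cluster)              # G x p summed scores
  A_inv <- fit$bread
  meat <- crossprod(S)
  V <- A_inv %*% meat %*% A_inv * G / (G - 1)
  (V + t(V)) / 2
}

fit_glm_engine <- function(d, family_obj) {
  C_mat <- model_country_matrix(d$cluster)
  M <- cbind(C_mat, d$X)
  res <- suppressWarnings(
    glm.fit(x = M, y = d$y, weights = d$weights, offset = d$offset,
            family = family_obj,
            control = list(epsilon = 1e-8, maxit = 100)))
  if (!res$converged) {
    stop_estimation("IRLS did not converge within 100 iterations",
                    trace = list(deviance = res$deviance, iter = res$iter))
  }
  if (res$rank < ncol(M)) {
    aliased <- colnames(M)[is.na(coef(res))]
    stop_estimation(paste0("design is rank deficient; aliased columns: ",
                           paste(aliased, collapse = ", ")))
  }
  res$model_matrix <- M
  res
}

model_country_matrix <- function(cluster) {
  lev <- levels(cluster)
  C_mat <- vapply(lev, function(l) as.numeric(cluster == l),
                  numeric(length(cluster)))
  colnames(C_mat) <- paste0("country_", lev)
  C_mat
}

#' Fit a fixed-effects Poisson (or negative-binomial) rate model
#'
#' Maximizes the (quasi-)Poisson likelihood of death counts with a log
#' link, `log(denominator / 1000)` offset, one intercept per country,
#' exposure-band indicators, above-median covariate indicators and time
#' controls. Non-integer pseudo-counts (age-standardised rates times
#' denominator) are accepted under the quasi-likelihood contract;
#' inference uses the cluster-robust sandwich by country. Countries with
#' an all-zero outcome are dropped (they contribute nothing to the
#' fixed-effects likelihood) and logged in the result.
#'
#' @param panel an `aid_panel` (dichotomized internally if needed).
#' @param spec a [model_spec()].
#' @param engine `"dummy"` (country indicator columns, IRLS) or
#'   `"within"` (profile/conditional Newton solver absorbing country
#'   effects); both maximize the same likelihood and agree on the
#'   coefficients.
#' @return an `fe_fit` object.
#' @export
fit_fe_poisson <- function(panel, spec, engine = c("dummy", "within")) {
  engine <- match.arg(engine)
  d <- build_design(panel, spec)
  if (spec$family == "nb") return(fit_nb(panel, spec, d))
  fam <- quasipoisson(link = "log")
  if (engine == "within") {
    wres <- fit_within_engine(d)
    beta_full <- c(wres$alpha, wres$beta)
    mu <- wres$mu
    M <- cbind(model_country_matrix(d$cluster), d$X)
    iter <- wres$iter
  } else {
    res <- fit_glm_engine(d, fam)
    beta_full <- coef(res)
    mu <- res$fitted.values
    M <- res$model_matrix
    iter <- res$iter
  }
  finish_fit(d, spec, beta_full, mu, M, iter, family = "poisson",
             var_mu = function(m) m, theta = NULL)
}

finish_fit <- function(d, spec, beta_full, mu, M, iter, family, var_mu, theta) {
  s_resid <- d$weights * (d$y - mu) * mu / var_mu(mu)
  W_work <- d$weights * mu^2 / var_mu(mu)
  A <- crossprod(M * sqrt(W_work))
  A_inv <- tryCatch(solve(A), error = function(e) {
    stop_estimation("information matrix is singular (collinear design)")
  })
  fit <- structure(list(
    coefficients = beta_full,
    beta_terms = colnames(d$X),
    exposure_terms = d$exposure_cols,
    model_matrix = M, y = d$y, offset = d$offset, weights = d$weights,
    fitted = mu, cluster = d$cluster, years = d$years,
    score_residuals = s_resid, bread = A_inv,
    n_obs = length(d$y), n_countries = nlevels(d$cluster),
    loglik = quasi_poisson_loglik(d$y, mu, d$weights),
    converged = TRUE, iterations = iter,
    family = family, theta = theta, spec = spec,
    medians = d$medians,
    dropped = list(n_na = d$n_dropped_na, countries = d$dropped_countries,
                   columns = d$dropped_columns)
  ), class = "fe_fit")
  V <- cluster_vcov(fit)
  dimnames(V) <- list(names(beta_full), names(beta_full))
  fit$vcov_cluster <- V
  fit$se <- sqrt(pmax(diag(V), 0))
  fit
}

fit_nb <- function(panel, spec, d) {
  # alternate IRLS for beta with ML update of the dispersion parameter
  theta <- 10
  res <- fit_glm_engine(d, quasipoisson(link = "log"))
  for (k in 1:25) {
    theta_new <- tryCatch(
      suppressWarnings(MASS::theta.ml(d$y, res$fitted.values, weights = d$weights,
                                      limit = 50)),
      error = function(e) 1e6)
    theta_new <- min(as.numeric(theta_new), 1e6)
    res <- fit_glm_engine(d, MASS::negative.binomial(theta = theta_new))
    if (abs(log(theta_new) - log(theta)) < 1e-6) { theta <- theta_new; break }
    theta <- theta_new
  }
  finish_fit(d, spec, coef(res), res$fitted.values, res$model_matrix,
             res$iter, family = "nb",
             var_mu = function(m) m + m^2 / theta, theta = theta)
}

#' Negative-binomial variant of [fit_fe_poisson()]
#' @inheritParams fit_fe_poisson
#' @export
negative_binomial_fit <- function(panel, spec) {
  spec$family <- "nb"
  fit_fe_poisson(panel, spec)
}

# Profile (conditional) Newton solver: country intercepts are absorbed
# analytically, exp(alpha_i) = sum(w y) / sum(w offset exp(x beta)).
fit_within_engine <- function(d, tol = 1e-8, maxit = 100) {
  X <- d$X; y <- d$y; w <- d$weights; off <- exp(d$offset)
  cl <- d$cluster
  p <- ncol(X)
  beta <- numeric(p)
  Sy <- as.vector(rowsum(w * y, cl))
  wyX <- colSums(w * y * X)
  profile_ll <- function(beta) {
    u <- w * off * exp(drop(X %*% beta))
    Su <- as.vector(rowsum(u, cl))
    sum(X %*% beta * (w * y)) + sum(w * y * d$offset) + sum(Sy * log(Sy / Su)) - sum(Sy)
  }
  ll <- profile_ll(beta)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    u <- w * off * exp(drop(X %*% beta))
    Su <- as.vector(rowsum(u, cl))
    scale_i <- (Sy / Su)[as.integer(cl)]
    wmu <- u * scale_i
    g <- wyX - colSums(wmu * X)
    SuX <- rowsum(wmu * X, cl)                     # G x p: sum_i w mu x
    H <- crossprod(X * sqrt(wmu)) - crossprod(SuX / sqrt(Sy))
    step <- tryCatch(solve(H, g), error = function(e) {
      stop_estimation("within-solver Hessian is singular (collinear design)")
    })
    lam <- 1
    repeat {
      beta_new <- beta + lam * step
      ll_new <- profile_ll(beta_new)
      if (is.finite(ll_new) && (ll_new >= ll - 1e-12)) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    improved <- abs(ll_new - ll) <= tol * (abs(ll) + 1)
    beta <- beta_new; ll <- ll_new
    if ((improved && max(abs(g)) < 1e-6 * (1 + max(abs(wyX)))) || iter >= maxit) break
  }
  if (iter >= maxit) {
    stop_estimation("within solver did not converge within 100 iterations",
                    trace = list(loglik = ll, gradient_max = max(abs(g))))
  }
  u <- w * off * exp(drop(X %*% beta))
  Su <- as.vector(rowsum(u, cl))
  alpha <- log(Sy / Su)
  names(alpha) <- paste0("country_", levels(cl))
  mu <- exp(alpha[as.integer(cl)] + drop(X %*% beta) + d$offset)
  list(beta = setNames(beta, colnames(X)), alpha = alpha, mu = mu,
       iter = iter, loglik = ll)
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects %s fit: %d obs, %d countries, loglik %.2f (%d iter)\n",
              x$family, x$n_obs, x$n_countries, x$loglik, x$iterations))
  if (!is.null(x$theta)) cat(sprintf("  dispersion (NB size): %.3f\n", x$theta))
  print(rr_table(x))
  invisible(x)
}

#' Rate-ratio table with Wald confidence intervals
#'
#' @param fit an `fe_fit`.
#' @param level confidence level.
#' @param terms `"exposure"` for the funding bands only, `"all"` for
#'   every non-country coefficient.
#' @return tibble with term, log rate ratio, cluster-robust SE, RR,
#'   CI bounds and two-sided Wald p-value.
#' @export
rr_table <- function(fit, level = 0.95, terms = c("exposure", "all")) {
  terms <- match.arg(terms)
  sel <- if (terms == "exposure") fit$exposure_terms else fit$beta_terms
  b <- fit$coefficients[sel]
  se <- fit$se[sel]
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = sel, log_rr = unname(b), se = unname(se),
    rr = exp(unname(b)),
    conf_low = exp(unname(b - z * se)), conf_high = exp(unname(b + z * se)),
    p = 2 * pnorm(-abs(unname(b) / unname(se)))
  )
}

#' Render a rate-ratio table in the fixed "RR (low-high)" style
#' @param fit an `fe_fit`.
#' @param level confidence level.
#' @export
format_rr_table <- function(fit, level = 0.95) {
  tab <- rr_table(fit, level, terms = "all")
  paste0(format(tab$term, width = max(nchar(tab$term))), "  ",
         sprintf("%.2f (%.2f-%.2f)", tab$rr, tab$conf_low, tab$conf_high),
         collapse = "\n")
}

#' Subset a panel keeping its metadata attributes
#' @param panel an `aid_panel`.
#' @param rows logical or integer row index.
#' @export
subset_panel <- function(panel, rows) {
  out <- panel[rows, ]
  for (a in c("outcomes", "covariates", "year_range", "medians", "dichotomized")) {
    attr(out, a) <- attr(panel, a)
  }
  class(out) <- class(panel)
  out
}

#' Fit the model separately within country strata
#'
#' @param panel an `aid_panel`.
#' @param spec a [model_spec()].
#' @param strata either `"income"` (stratify by income group), the name
#'   of a covariate (countries split at the median of their country
#'   means), or a named character vector mapping country_id to stratum.
#' @return list of `fe_fit` objects (or `NULL` with a `skipped`
#'   attribute message for strata too small to fit).
#' @export
fit_stratified <- function(panel, spec, strata) {
  if (length(strata) == 0L) stop_value("empty strata definition")
  if (!isTRUE(attr(panel, "dichotomized"))) {
    panel <- dichotomize_covariates(panel)
  }
  if (is.character(strata) && length(strata) == 1L) {
    if (strata == "income") {
      assign_map <- tapply(panel$income_group, panel$country_id, function(x) x[1])
    } else {
      if (!strata %in% names(panel)) {
        stop_value(sprintf("no column '%s' to stratify on", strata))
      }
      cm <- tapply(panel[[strata]], panel$country_id, mean, na.rm = TRUE)
      assign_map <- ifelse(cm > median(cm, na.rm = TRUE),
                           paste0("high_", strata), paste0("low_", strata))
      names(assign_map) <- names(cm)
    }
  } else {
    assign_map <- strata
  }
  out <- list()
  for (s in sort(unique(assign_map))) {
    ids <- names(assign_map)[assign_map == s]
    sub <- subset_panel(panel, panel$country_id %in% ids)
    out[[s]] <- tryCatch(fit_fe_poisson(sub, spec),
                         error = function(e) {
                           structure(list(), skipped = conditionMessage(e))
                         })
  }
  out
}
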