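#' Country-level treatment assignment for the matched analysis
#'
#' A country counts as "medium/high coverage" (treated) when its mean
#' per-capita funding over the study window reaches the low/intermediate
#' cut of the exposure scheme.
#'
#' @param panel an `aid_panel`.
#' @param scheme an [exposure_scheme()].
#' @return tibble with country_id, mean_pc, treated.
#' @export
assign_coverage_treatment <- function(panel, scheme = exposure_scheme()) {
  mean_pc <- tapply(panel$usaid_pc, panel$country_id, mean, na.rm = TRUE)
  tibble::tibble(country_id = names(mean_pc),
                 mean_pc = unname(mean_pc),
                 treated = unname(mean_pc) >= scheme$cuts["intermediate"])
}

#' Logistic propensity model for treatment on baseline covariates
#'
#' @param data one row per country with the covariate columns.
#' @param treated logical treatment indicator (same length).
#' @param covariates covariate column names.
#' @return list with `scores` (fitted probabilities), `coefficients`,
#'   and the `glm` object.
#' @export
propensity_model <- function(data, treated, covariates) {
  if (!any(treated) || !any(!treated)) {
    stop_value("both treatment groups must be non-empty")
  }
  X <- as.data.frame(data[, covariates, drop = FALSE])
  if (any(!complete.cases(X))) stop_value("propensity covariates must be complete")
  df <- cbind(.treated = as.numeric(treated), X)
  fit <- suppressWarnings(
    stats::glm(.treated ~ ., data = df, family = binomial()))
  co <- coef(fit)[-1L]
  if (!fit$converged || any(abs(co) > 15, na.rm = TRUE) ||
      all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)) {
    worst <- names(co)[which.max(abs(co))]
    abort_aidmort(paste0("perfect or near-perfect separation in propensity model",
                         " (covariate: ", worst, ")"),
                  "aidmort_separation_error")
  }
  list(scores = unname(fit$fitted.values), coefficients = coef(fit), model = fit)
}

#' Greedy 1:1 propensity-score matching with a caliper
#'
#' Matches on the logit of the propensity score, nearest neighbour
#' without replacement, processing treated units in descending score
#' order; ties between equally distant controls are broken by id order.
#'
#' @param scores propensity scores in (0,1).
#' @param treated logical treatment indicator.
#' @param ids unit identifiers.
#' @param caliper caliper as a multiple of the SD of the logit scores.
#' @return a `matched_set`: tibble of pairs plus metadata.
#' @export
ps_match <- function(scores, treated, ids, caliper = 0.2) {
  if (length(scores) != length(treated) || length(scores) != length(ids)) {
    stop_value("scores, treated and ids must have equal length")
  }
  lg <- logit(clamp(scores, 1e-12, 1 - 1e-12))
  cal <- caliper * sd(lg)
  if (!is.finite(cal) || cal == 0) cal <- Inf
  t_idx <- which(treated)[order(-lg[treated], ids[treated])]
  avail <- which(!treated)
  pairs <- list()
  unmatched <- character(0)
  for (ti in t_idx) {
    if (!length(avail)) { unmatched <- c(unmatched, ids[ti]); next }
    dist <- abs(lg[avail] - lg[ti])
    ord <- order(dist, ids[avail])
    if (dist[ord[1]] <= cal) {
      ci <- avail[ord[1]]
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        treated_id = ids[ti], control_id = ids[ci],
        distance = dist[ord[1]])
      avail <- setdiff(avail, ci)
    } else {
      unmatched <- c(unmatched, ids[ti])
    }
  }
  if (!length(pairs)) {
    stop_value("no treated unit has a control within the caliper")
  }
  structure(list(pairs = do.call(rbind, pairs),
                 scores = setNames(scores, ids),
                 caliper_logit = cal, n_unmatched = length(unmatched),
                 unmatched = unmatched),
            class = "matched_set")
}

#' Standardized mean difference between treatment groups
#' @param x covariate values.
#' @param treated logical indicator.
#' @export
smd <- function(x, treated) {
  m1 <- mean(x[treated], na.rm = TRUE); m0 <- mean(x[!treated], na.rm = TRUE)
  s <- sqrt((var(x[treated], na.rm = TRUE) + var(x[!treated], na.rm = TRUE)) / 2)
  if (!is.finite(s) || s == 0) return(0)
  (m1 - m0) / s
}

#' Covariate balance before and after matching
#'
#' @param data one row per unit with covariate columns (same order as
#'   used for matching).
#' @param treated logical indicator.
#' @param ids unit ids.
#' @param matched a `matched_set`.
#' @param covariates covariate names.
#' @export
balance_table <- function(data, treated, ids, matched, covariates) {
  keep <- ids %in% c(matched$pairs$treated_id, matched$pairs$control_id)
  rows <- lapply(covariates, function(cv) {
    tibble::tibble(covariate = cv,
                   smd_pre = smd(data[[cv]], treated),
                   smd_post = smd(data[[cv]][keep], treated[keep]))
  })
  do.call(rbind, rows)
}

#' Difference-in-differences on log mortality rates over matched pairs
#'
#' For each matched pair, the double difference
#' `(log y_treated_post - log y_treated_pre) - (log y_control_post -
#' log y_control_pre)` is computed; the effect is its mean with a SE
#' from the pair-level distribution. `exp(effect)` is the ratio-scale
#' estimate, aligned with the Poisson log link. Pairs with a zero rate
#' in any cell are dropped and logged.
#'
#' @param panel an `aid_panel`.
#' @param matched a `matched_set` over country ids.
#' @param outcome outcome name.
#' @param pre,post the two comparison years.
#' @param level CI level.
#' @return a `did_result`.
#' @export
did_estimate <- function(panel, matched, outcome, pre = 2001, post = 2021,
                         level = 0.95) {
  rate_col <- paste0("rate_", outcome)
  get_rate <- function(cid, yr) {
    r <- panel[[rate_col]][panel$country_id == cid & panel$year == yr]
    if (!length(r)) NA_real_ else r[1]
  }
  dd <- numeric(0)
  dropped <- character(0)
  for (k in seq_len(nrow(matched$pairs))) {
    tid <- matched$pairs$treated_id[k]; cid <- matched$pairs$control_id[k]
    r <- c(get_rate(tid, pre), get_rate(tid, post),
           get_rate(cid, pre), get_rate(cid, post))
    if (anyNA(r)) stop_value(sprintf("pair (%s, %s) lacks both years", tid, cid))
    if (any(r == 0)) { dropped <- c(dropped, tid); next }
    dd <- c(dd, (log(r[2]) - log(r[1])) - (log(r[4]) - log(r[3])))
  }
  if (!length(dd)) stop_value("no pair with positive rates in both years")
  est <- mean(dd)
  se <- if (length(dd) > 1) sd(dd) / sqrt(length(dd)) else NA_real_
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(effect_log = est, se = se,
                 ci_low = est - z * se, ci_high = est + z * se,
                 ratio = exp(est), n_pairs = length(dd),
                 dropped_pairs = dropped),
            class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("Matched DiD on log rates: %.4f (SE %.4f), ratio %.3f, %d pairs\n",
              x$effect_log, x$se, x$ratio, x$n_pairs))
  invisible(x)
}

#' Negative-control outcome check
#'
#' Refits the primary model with a negative-control outcome (injury
#' mortality by default) and reports PASS when every exposure-band CI
#' covers 1 -- a detected "effect" on the control flags residual bias.
#' A failing check is a report, not an error.
#'
#' @param panel an `aid_panel`.
#' @param spec the primary [model_spec()]; its outcome is replaced.
#' @param control_outcome negative-control outcome name.
#' @param level CI level.
#' @param primary_fit optional primary `fe_fit` whose RRs are echoed
#'   next to the control's for side-by-side display.
#' @return a `negative_control_report`.
#' @export
negative_control_check <- function(panel, spec, control_outcome = "injuries",
                                   level = 0.95, primary_fit = NULL) {
  if (!control_outcome %in% panel_outcomes(panel)) {
    stop_schema(sprintf("outcome '%s' not present in panel", control_outcome))
  }
  spec$outcome <- control_outcome
  fit <- fit_fe_poisson(panel, spec)
  tab <- rr_table(fit, level = level)
  pass <- all(tab$conf_low <= 1 & tab$conf_high >= 1)
  report <- list(pass = pass, control_outcome = control_outcome,
                 control_rr = tab,
                 primary_rr = if (!is.null(primary_fit)) rr_table(primary_fit, level))
  class(report) <- "negative_control_report"
  report
}

#' @export
print.negative_control_report <- function(x, ...) {
  cat(sprintf("Negative control (%s): %s\n", x$control_outcome,
              if (x$pass) "PASS (all exposure CIs cover 1)" else "FAIL"))
  print(x$control_rr)
  if (!is.null(x$primary_rr)) {
    cat("Primary outcome for comparison:\n")
    print(x$primary_rr)
  }
  invisible(x)
}
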