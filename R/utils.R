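#' @importFrom stats quantile median qnorm pnorm rnorm rpois rlnorm rbinom
#' @importFrom stats rnbinom runif coef glm.fit quasipoisson binomial lm sd
#' @importFrom stats setNames complete.cases uniroot predict var aggregate
#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_aidmort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "aidmort_error"), ...)
}

stop_value <- function(message, ...) abort_aidmort(message, "aidmort_value_error", ...)
stop_schema <- function(message, ...) abort_aidmort(message, "aidmort_schema_error", ...)
stop_integrity <- function(message, ...) abort_aidmort(message, "aidmort_integrity_error", ...)
stop_config <- function(message, ...) abort_aidmort(message, "aidmort_config_error", ...)
stop_estimation <- function(message, ...) abort_aidmort(message, "aidmort_estimation_error", ...)
stop_variance <- function(message, ...) abort_aidmort(message, "aidmort_variance_error", ...)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_value(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
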