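#' Exposure band labels, in increasing order of funding intensity
#'
#' The dose-response analysis uses four per-capita funding bands:
#' an unexposed baseline and low / intermediate / high intensity bands.
#' @export
exposure_levels <- function() c("baseline", "low", "intermediate", "high")

#' Default per-capita funding cut points (USD per person-year)
#'
#' Quartile cut points of the per-capita funding distribution among
#' low-income countries; values below the first cut are the unexposed
#' baseline band.
#' @export
default_cuts <- function() c(low = 1.97, intermediate = 3.97, high = 7.10)

#' Default shock-period dummies (global economic / health crises)
#' @export
default_shock_periods <- function() {
  list(`2008_09` = 2008:2009, `2013_14` = 2013:2014,
       `2015_16` = 2015:2016, `2020_21` = 2020:2021)
}

#' Alternative shock-period set (single crisis years)
#' @export
alt_shock_periods <- function() {
  list(`2007_08` = 2007:2008, `2015` = 2015L, `2020` = 2020L, `2021` = 2021L)
}

income_levels <- function() c("low", "lower-middle", "upper-middle", "high")

#' Registered outcome / covariate names of a panel
#' @param panel an `aid_panel`.
#' @export
panel_outcomes <- function(panel) attr(panel, "outcomes")

#' @rdname panel_outcomes
#' @export
panel_covariates <- function(panel) attr(panel, "covariates")

#' Construct a validated country-year panel
#'
#' A panel is a tibble with one row per (country, year) carrying, for each
#' registered outcome `o`, columns `deaths_o`, `denom_o` and `rate_o`
#' (rate per 1000 of the denominator), plus funding (`usaid_total`,
#' `usaid_pc`), `population`, `live_births`, `income_group` and the named
#' covariates. Rows violating the internal consistency rules
#' (`rate == 1000 * deaths / denom`, `usaid_pc == usaid_total / population`)
#' are rejected with row-addressed diagnostics.
#'
#' @param df data frame of country-year records.
#' @param outcomes character vector of outcome names.
#' @param covariates character vector of covariate column names.
#' @param year_range inclusive integer range of admissible years.
#' @return an `aid_panel` tibble.
#' @export
as_panel <- function(df, outcomes, covariates, year_range = c(2001L, 2030L)) {
  df <- tibble::as_tibble(df)
  required <- c("country_id", "year", "income_group", "population",
                "usaid_total", "usaid_pc", covariates,
                paste0("deaths_", outcomes), paste0("denom_", outcomes),
                paste0("rate_", outcomes))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_schema(paste0("missing required columns: ",
                       paste(missing_cols, collapse = ", ")))
  }
  key <- paste(df$country_id, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("country_id", "year")][1L, ]
    stop_integrity(sprintf("duplicate (country, year) pair: (%s, %d)",
                           dup$country_id, dup$year))
  }
  if (length(unique(df$country_id)) < 2L || length(unique(df$year)) < 2L) {
    stop_integrity("panel needs at least 2 countries and 2 years")
  }
  if (any(df$year < year_range[1] | df$year > year_range[2])) {
    bad <- which(df$year < year_range[1] | df$year > year_range[2])[1L]
    stop_value(sprintf("row %d: year %d outside configured range [%d, %d]",
                       bad, df$year[bad], year_range[1], year_range[2]))
  }
  if (any(df$usaid_total < 0, na.rm = TRUE) || any(df$usaid_pc < 0, na.rm = TRUE)) {
    stop_value("negative funding values present")
  }
  for (o in outcomes) {
    d <- df[[paste0("deaths_", o)]]
    if (any(d < 0, na.rm = TRUE)) {
      stop_value(sprintf("row %d: negative deaths for outcome '%s'",
                         which(d < 0)[1L], o))
    }
    den <- df[[paste0("denom_", o)]]
    if (any(den <= 0, na.rm = TRUE)) {
      stop_value(sprintf("row %d: non-positive denominator for outcome '%s'",
                         which(den <= 0)[1L], o))
    }
    r <- df[[paste0("rate_", o)]]
    ok <- is.na(d) | is.na(den) | is.na(r) |
      abs(r - 1000 * d / den) <= 1e-9 * pmax(1, abs(r))
    if (!all(ok)) {
      stop_integrity(sprintf(
        "row %d: rate_%s inconsistent with 1000 * deaths / denominator",
        which(!ok)[1L], o))
    }
  }
  pc_ok <- is.na(df$usaid_pc) | is.na(df$usaid_total) | is.na(df$population) |
    abs(df$usaid_pc - df$usaid_total / df$population) <=
      1e-9 * pmax(1, abs(df$usaid_pc))
  if (!all(pc_ok)) {
    stop_integrity(sprintf(
      "row %d: usaid_pc inconsistent with usaid_total / population",
      which(!pc_ok)[1L]))
  }
  df$year <- as.integer(df$year)
  structure(df,
            outcomes = outcomes, covariates = covariates,
            year_range = as.integer(year_range),
            class = c("aid_panel", class(df)))
}

#' Panel schema: column mapping for delimited files
#'
#' @param outcomes,covariates names used both in the file (as
#'   `deaths_<outcome>` etc.) and in the panel.
#' @param sep field delimiter.
#' @param year_range admissible years.
#' @export
panel_schema <- function(outcomes, covariates, sep = ",",
                         year_range = c(2001L, 2030L)) {
  list(outcomes = outcomes, covariates = covariates, sep = sep,
       year_range = year_range)
}

#' Read a country-year panel from a delimited text file
#'
#' @param path file path.
#' @param schema a [panel_schema()].
#' @return an `aid_panel`.
#' @export
load_panel <- function(path, schema) {
  if (!file.exists(path)) stop_value(paste0("no such file: ", path))
  df <- utils::read.table(path, header = TRUE, sep = schema$sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop_integrity("empty panel file (fewer than 2 countries)")
  as_panel(df, schema$outcomes, schema$covariates, schema$year_range)
}

#' Write a panel back to delimited text
#'
#' Round-trips bit-identically with [load_panel()] on valid files (numbers
#' are written at full precision).
#' @param panel an `aid_panel`.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_panel <- function(panel, path, sep = ",") {
  df <- as.data.frame(panel)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-capita funding from total disbursement and population
#'
#' @param usaid_total total disbursement, constant USD.
#' @param population persons.
#' @return USD per person-year.
#' @export
compute_usaid_pc <- function(usaid_total, population) {
  if (any(population <= 0)) stop_value("population must be positive")
  if (any(usaid_total < 0)) stop_value("usaid_total must be non-negative")
  usaid_total / population
}

#' An exposure-categorization scheme (three increasing cut points)
#'
#' @param cuts numeric vector (c1, c2, c3), strictly increasing, positive.
#' @param percentile_definition recorded in metadata; quartile estimation
#'   uses linear interpolation between order statistics (R type 7).
#' @export
exposure_scheme <- function(cuts = default_cuts(),
                            percentile_definition = "linear interpolation (type 7)") {
  cuts <- as.numeric(cuts)
  if (length(cuts) != 3L || any(!is.finite(cuts)) || any(cuts <= 0) ||
      any(diff(cuts) <= 0)) {
    stop_value("cuts must be three strictly increasing positive numbers")
  }
  structure(list(cuts = setNames(cuts, c("low", "intermediate", "high")),
                 labels = exposure_levels(),
                 percentile_definition = percentile_definition),
            class = "exposure_scheme")
}

#' @export
print.exposure_scheme <- function(x, ...) {
  cat("Exposure scheme (USD per capita):\n")
  cat(sprintf("  baseline  [0, %.2f)\n  low       [%.2f, %.2f)\n", x$cuts[1],
              x$cuts[1], x$cuts[2]))
  cat(sprintf("  intermed. [%.2f, %.2f)\n  high      [%.2f, Inf)\n",
              x$cuts[2], x$cuts[3], x$cuts[3]))
  invisible(x)
}

#' Funding quartile cut points from a reference income-group subset
#'
#' Computes the 25th/50th/75th percentiles of per-capita funding over the
#' country-years of a reference subset (by default the low-income
#' countries), using linear interpolation between order statistics.
#'
#' @param panel an `aid_panel`.
#' @param reference income groups defining the reference distribution.
#' @return an [exposure_scheme()].
#' @export
quartile_thresholds <- function(panel, reference = "low") {
  x <- panel$usaid_pc[panel$income_group %in% reference]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop_value("reference subset is empty")
  if (length(unique(x)) < 4L) {
    stop_value("degenerate funding distribution in reference subset (< 4 distinct values)")
  }
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  if (any(diff(q) <= 0)) {
    stop_value("degenerate funding distribution: non-increasing quartiles")
  }
  exposure_scheme(q)
}

#' Categorize per-capita funding into exposure bands
#'
#' Bands are half-open: `[0, c1)` baseline, `[c1, c2)` low, `[c2, c3)`
#' intermediate, `[c3, Inf)` high; a value equal to a cut point falls in
#' the upper band.
#'
#' @param usaid_pc non-negative per-capita funding values.
#' @param scheme an [exposure_scheme()].
#' @return ordered factor with levels [exposure_levels()].
#' @export
categorize_exposure <- function(usaid_pc, scheme = exposure_scheme()) {
  if (any(usaid_pc < 0, na.rm = TRUE)) stop_value("usaid_pc must be non-negative")
  idx <- findInterval(usaid_pc, scheme$cuts) + 1L
  factor(exposure_levels()[idx], levels = exposure_levels(), ordered = TRUE)
}

#' Dichotomize covariates at their pooled median
#'
#' Each covariate is replaced by `indicator(value > median)`, the median
#' being computed once over all country-years of the panel (the whole
#' study window). Values exactly equal to the median map to 0.
#'
#' @param panel an `aid_panel`.
#' @param covariates covariates to dichotomize; defaults to the panel's
#'   registered covariate set.
#' @param medians optional named numeric vector of frozen medians (used
#'   when projecting future records with retrospective medians).
#' @return the panel with indicator covariates and a `medians` attribute.
#' @export
dichotomize_covariates <- function(panel, covariates = panel_covariates(panel),
                                   medians = NULL) {
  out <- panel
  med <- setNames(numeric(length(covariates)), covariates)
  for (cv in covariates) {
    x <- panel[[cv]]
    if (all(is.na(x))) stop_value(sprintf("covariate '%s' is all-missing", cv))
    if (sum(!is.na(x)) < 2L) {
      stop_value(sprintf("covariate '%s' has fewer than 2 non-missing values", cv))
    }
    m <- if (!is.null(medians)) {
      if (is.na(medians[cv])) stop_value(sprintf("no frozen median for '%s'", cv))
      medians[[cv]]
    } else {
      median(x, na.rm = TRUE)
    }
    ind <- as.integer(x > m)
    if (is.null(medians) && length(unique(ind[!is.na(ind)])) < 2L) {
      warning(sprintf("covariate '%s' has no variation after dichotomization", cv))
    }
    med[cv] <- m
    out[[cv]] <- ind
  }
  attr(out, "medians") <- med
  attr(out, "dichotomized") <- TRUE
  out
}

#' Shock-period indicator columns
#'
#' @param years integer vector of calendar years.
#' @param periods named list of integer year vectors (one indicator per
#'   period), or the string `"year"` for a full year-dummy set with the
#'   first year as reference.
#' @return a numeric matrix with one column per indicator.
#' @export
shock_dummies <- function(years, periods = default_shock_periods()) {
  if (identical(periods, "year")) {
    yrs <- sort(unique(years))
    if (length(yrs) < 2L) return(matrix(numeric(0), nrow = length(years)))
    m <- vapply(yrs[-1L], function(y) as.numeric(years == y), numeric(length(years)))
    colnames(m) <- paste0("year_", yrs[-1L])
    return(m)
  }
  if (length(periods) == 0L) return(matrix(numeric(0), nrow = length(years)))
  m <- vapply(periods, function(p) as.numeric(years %in% p), numeric(length(years)))
  m <- matrix(m, nrow = length(years),
              dimnames = list(NULL, paste0("shock_", names(periods))))
  m
}
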