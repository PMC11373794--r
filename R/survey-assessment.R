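INDICATORS <- c("haz", "whz", "waz")
SURVEY_COLUMNS <- c("age", "haz", "whz", "waz", "wt")

new_survey_table <- function(df, survey_id) {
  structure(df, survey_id = as.character(survey_id),
            class = c("survey_table", "data.frame"))
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("Survey '%s': %d children\n", survey_id(x), nrow(x)))
  NextMethod()
}

#' Survey identifier of a survey table
#' @param table A `survey_table`.
#' @return Character survey id.
#' @export
survey_id <- function(table) {
  attr(table, "survey_id", exact = TRUE)
}

#' Read a per-child anthropometry survey file
#'
#' Reads a CSV with columns named exactly `age` (months), `haz`, `whz`,
#' `waz` (z-scores, possibly missing) and `wt` (positive survey weight) —
#' one row per child. Missing z-scores are preserved as `NA`; rows are
#' never dropped at read time.
#'
#' @param path CSV file path.
#' @param survey_id Label for the survey; defaults to the file name
#'   without extension.
#' @param plausibility_filter If `TRUE`, set z-scores outside the WHO
#'   biological-plausibility windows to missing (see
#'   [plausibility_filter()]). Off by default.
#'
#' @return A `survey_table` (a data frame with the five columns and a
#'   `survey_id` attribute).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(age = c(10, 24), haz = c(-1.2, NA),
#'                      whz = c(0.1, -0.5), waz = c(-0.7, -1.1),
#'                      wt = c(1, 1.5)), f, row.names = FALSE)
#' read_survey(f)
#' @export
read_survey <- function(path, survey_id = NULL,
                        plausibility_filter = FALSE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(survey_id)) {
    survey_id <- tools::file_path_sans_ext(basename(path))
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"),
                         check.names = FALSE)
  missing_cols <- setdiff(SURVEY_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(SURVEY_COLUMNS, function(col) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s' at row %d: \"%s\"",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    num
  })
  names(cols) <- SURVEY_COLUMNS
  df <- as.data.frame(cols)
  if (anyNA(df$wt) || any(df$wt <= 0)) {
    stop("column 'wt' must contain positive survey weights for all rows",
         call. = FALSE)
  }
  if (anyNA(df$age) || any(df$age < 0)) {
    stop("column 'age' must contain non-negative ages in months",
         call. = FALSE)
  }
  tbl <- new_survey_table(df, survey_id)
  if (isTRUE(plausibility_filter)) tbl <- plausibility_filter(tbl)
  tbl
}

#' Flag biologically implausible z-scores as missing
#'
#' Applies the WHO flagging windows (haz outside \[-6, 6\], whz outside
#' \[-5, 5\], waz outside \[-6, 5\]) by setting flagged values to `NA`.
#' Not applied by default anywhere in the package: the assessment is of
#' the distribution as collected.
#'
#' @param table A `survey_table`.
#' @param limits Named list of `c(lower, upper)` windows per indicator.
#' @return The table with flagged values set to `NA`; the per-indicator
#'   flag counts are attached as attribute `n_flagged` and reported via
#'   `message()`.
#' @export
plausibility_filter <- function(table,
                                limits = list(haz = c(-6, 6),
                                              whz = c(-5, 5),
                                              waz = c(-6, 5))) {
  stopifnot(inherits(table, "survey_table"))
  n_flagged <- integer(0)
  for (ind in names(limits)) {
    z <- table[[ind]]
    bad <- !is.na(z) & (z < limits[[ind]][1] | z > limits[[ind]][2])
    table[[ind]][bad] <- NA_real_
    n_flagged[ind] <- sum(bad)
  }
  if (sum(n_flagged) > 0) {
    message("plausibility filter flagged ",
            paste(sprintf("%s: %d", names(n_flagged), n_flagged),
                  collapse = ", "))
  }
  attr(table, "n_flagged") <- n_flagged
  table
}

check_indicator <- function(indicator) {
  match.arg(indicator, INDICATORS)
}

#' Survey-weighted mean and standard deviation of a z-score indicator
#'
#' Weighted moments over the non-missing records of one indicator:
#' mean \eqn{\sum w_i z_i / \sum w_i} and the population-form SD
#' \eqn{\sqrt{\sum w_i (z_i - \bar z_w)^2 / \sum w_i}}. Survey weights
#' are expansion weights, so the population (no finite-sample
#' correction) form is used; both moments are invariant to rescaling all
#' weights by a constant. Missing values are dropped per indicator, not
#' listwise.
#'
#' @param table A `survey_table`.
#' @param indicator One of `"haz"`, `"whz"`, `"waz"`.
#'
#' @return List with `weighted_mean`, `weighted_sd`, `n_used`.
#' @examples
#' tbl <- generate_survey(synthetic_survey_spec(n_children = 500, seed = 1))
#' weighted_moments(tbl, "haz")
#' @export
weighted_moments <- function(table, indicator) {
  stopifnot(inherits(table, "survey_table"))
  indicator <- check_indicator(indicator)
  z <- table[[indicator]]
  keep <- !is.na(z)
  if (sum(keep) < 2L) {
    stop(sprintf(
      "insufficient data: indicator '%s' has %d non-missing value(s); need >= 2",
      indicator, sum(keep)), call. = FALSE)
  }
  z <- z[keep]
  w <- table$wt[keep]
  m <- sum(w * z) / sum(w)
  s <- sqrt(sum(w * (z - m)^2) / sum(w))
  list(weighted_mean = m, weighted_sd = s, n_used = length(z))
}

#' Assess one indicator of one survey
#'
#' Composes the weighted moments with the bias relationship: the
#' estimated prevalence below the cutoff at the observed (mean, SD), the
#' point bias against the reference SD, and the likely-bias interval
#' against the realistic reference range.
#'
#' @inheritParams weighted_moments
#' @param threshold Prevalence cutoff; default -2.
#' @param reference_sd Point-estimate reference SD; default 1.0.
#' @param sd_references Low/high reference SDs for the bias interval;
#'   default `c(0.8, 1.2)`.
#'
#' @return An object of class `indicator_summary`: `indicator`,
#'   `weighted_mean`, `weighted_sd`, `estimated_prevalence`,
#'   `bias_point`, `bias_interval`, `n_used`, `n_missing`.
#' @examples
#' tbl <- generate_survey(synthetic_survey_spec(n_children = 2000,
#'                                              noise_sd = 1, seed = 1))
#' assess_indicator(tbl, "haz")
#' @export
assess_indicator <- function(table, indicator, threshold = -2,
                             reference_sd = 1.0,
                             sd_references = c(0.8, 1.2)) {
  stopifnot(inherits(table, "survey_table"))
  indicator <- check_indicator(indicator)
  mom <- weighted_moments(table, indicator)
  rng <- realistic_bias_range(mom$weighted_mean, mom$weighted_sd,
                              threshold, sd_references)
  structure(
    list(indicator = indicator,
         weighted_mean = mom$weighted_mean,
         weighted_sd = mom$weighted_sd,
         estimated_prevalence = prevalence_closed_form(
           normal_params(mom$weighted_mean, mom$weighted_sd),
           threshold)$value,
         bias_point = estimate_bias(mom$weighted_mean, mom$weighted_sd,
                                    threshold, reference_sd),
         bias_interval = rng$interval,
         threshold = threshold,
         reference_sd = reference_sd,
         sd_references = sd_references,
         n_used = mom$n_used,
         n_missing = sum(is.na(table[[indicator]]))),
    class = "indicator_summary"
  )
}

#' @export
print.indicator_summary <- function(x, ...) {
  cat(sprintf(
    "%s: weighted mean %.3f, SD %.3f (n = %d, missing %d)\n",
    x$indicator, x$weighted_mean, x$weighted_sd, x$n_used, x$n_missing))
  cat(sprintf(
    "  prevalence below %.4g: %.1f%%; bias vs SD %.2g: %+.1f pp; likely range [%+.1f, %+.1f] pp\n",
    x$threshold, 100 * x$estimated_prevalence, x$reference_sd,
    100 * x$bias_point, 100 * x$bias_interval[1],
    100 * x$bias_interval[2]))
  invisible(x)
}

#' Age heaping ratio
#'
#' Fraction of surveyed children whose reported age lies within one
#' month (inclusive, after rounding to the nearest integer month) of 24,
#' 36 or 48 months. Clustering at these whole-year ages is a signature
#' of age estimation rather than recorded birth dates, i.e. of
#' non-directional measurement error entering through age. Under a
#' uniform 0-59-month age distribution the expected ratio is 9/60 = 15%.
#' The 12-month cluster is excluded from the default targets (young
#' infants are often handled under different eligibility rules); the
#' target set is configurable. The ratio is defined on raw counts and
#' ignores survey weights.
#'
#' @param table A `survey_table`, or a numeric vector of ages in months.
#' @param target_ages Heaping targets in months; default
#'   `c(24, 36, 48)`.
#' @param window Half-width of each target window in months; default 1.
#' @param age_range Integer month range `c(min, max)` used for the
#'   uniform expectation; default `c(0, 59)`.
#'
#' @return An object of class `heaping_result`: `ratio`,
#'   `qualifying_count`, `total_count`, `target_ages`,
#'   `window_halfwidth`, `uniform_expectation`.
#' @examples
#' age_heaping_ratio(c(24, 25, 10, 40, 48))   # 3 of 5 within windows
#' @export
age_heaping_ratio <- function(table, target_ages = c(24, 36, 48),
                              window = 1, age_range = c(0, 59)) {
  ages <- if (inherits(table, "survey_table")) table$age else table
  if (!is.numeric(ages) || length(ages) == 0L) {
    stop("no age values supplied", call. = FALSE)
  }
  window <- check_scalar(window, "window")
  months <- round(ages)
  qualifying_months <- unique(unlist(lapply(target_ages, function(t) {
    seq(round(t - window), round(t + window))
  })))
  qualifying <- months %in% qualifying_months
  eligible_months <- seq(age_range[1], age_range[2])
  structure(
    list(ratio = mean(qualifying),
         qualifying_count = sum(qualifying),
         total_count = length(ages),
         target_ages = target_ages,
         window_halfwidth = window,
         uniform_expectation =
           sum(eligible_months %in% qualifying_months) /
             length(eligible_months)),
    class = "heaping_result"
  )
}

#' @export
print.heaping_result <- function(x, ...) {
  cat(sprintf(
    "Age heaping ratio: %.1f%% (%d / %d within +/-%g months of {%s}; %.0f%% expected if uniform)\n",
    100 * x$ratio, x$qualifying_count, x$total_count,
    x$window_halfwidth, paste(x$target_ages, collapse = ", "),
    100 * x$uniform_expectation))
  invisible(x)
}

#' Digit preference test
#'
#' Chi-square goodness-of-fit of recorded-value digits against a uniform
#' null, a simple screen for rounding habits in field measurements. Two
#' kinds: `"terminal_digit"` tabulates the first decimal digit (0-9) of
#' each value, appropriate for heights and weights recorded to 0.1
#' units; `"integer_month"` tabulates rounded ages over the observed
#' month range, appropriate for age distributions. The construction of
#' the test (digit extraction and uniform null) is this package's stated
#' choice of a simple screen.
#'
#' @param values Numeric vector of recorded measurements; `NA` dropped.
#' @param kind `"terminal_digit"` or `"integer_month"`.
#'
#' @return An object of class `digit_preference_test`: `kind`, named
#'   `observed` counts, `statistic`, `df`, `p_value`, `n`. Warns below
#'   30 values, where the chi-square approximation is unreliable.
#' @examples
#' h <- round(runif(200, 65, 110), 1)
#' digit_preference_test(h, "terminal_digit")
#' @export
digit_preference_test <- function(values,
                                  kind = c("terminal_digit",
                                           "integer_month")) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (!is.numeric(values) || length(values) == 0L) {
    stop("no non-missing values supplied", call. = FALSE)
  }
  if (length(values) < 30L) {
    warning("fewer than 30 values; digit test is unreliable",
            call. = FALSE)
  }
  if (kind == "terminal_digit") {
    digits <- round(abs(values) * 10) %% 10
    observed <- table(factor(digits, levels = 0:9))
  } else {
    months <- round(values)
    observed <- table(factor(months, levels = seq(min(months),
                                                  max(months))))
  }
  if (length(observed) < 2L) {
    # a single occupied bin: maximal preference, chi-square undefined
    stop("all values fall in a single bin; widen the input range",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(as.vector(observed)))
  structure(
    list(kind = kind,
         observed = stats::setNames(as.integer(observed),
                                    names(observed)),
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value,
         n = length(values)),
    class = "digit_preference_test"
  )
}

#' @export
print.digit_preference_test <- function(x, ...) {
  cat(sprintf(
    "Digit preference (%s, n = %d): X-squared = %.2f on %d df, p = %.3g\n",
    x$kind, x$n, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cross-survey correlation between age heaping and HAZ dispersion
#'
#' Pearson product-moment correlation between per-survey age-heaping
#' ratios and height-for-age weighted SDs. A strong positive correlation
#' indicates that inflated SDs track age-estimation quality rather than
#' genuine nutritional heterogeneity.
#'
#' @param x Numeric vector of age-heaping ratios, or a data frame with
#'   columns `heaping_ratio` and `haz_sd` (as produced by
#'   [assess_survey_collection()]).
#' @param y Numeric vector of HAZ weighted SDs (ignored when `x` is a
#'   data frame).
#' @param x_label,y_label Axis labels carried in the result.
#'
#' @return An object of class `correlation_result`: `rho`, `n_surveys`,
#'   `x_label`, `y_label`.
#' @examples
#' heaping_sd_correlation(c(0.1, 0.2, 0.4), c(1.0, 1.2, 1.5))
#' @export
heaping_sd_correlation <- function(x, y = NULL,
                                   x_label = "age heaping ratio",
                                   y_label = "haz weighted SD") {
  if (is.data.frame(x)) {
    if (!all(c("heaping_ratio", "haz_sd") %in% names(x))) {
      stop("data frame input needs columns 'heaping_ratio' and 'haz_sd'",
           call. = FALSE)
    }
    y <- x$haz_sd
    x <- x$heaping_ratio
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) {
    stop("insufficient data: need >= 3 surveys with both statistics",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in one of the variables",
         call. = FALSE)
  }
  structure(
    list(rho = stats::cor(x, y), n_surveys = length(x),
         x_label = x_label, y_label = y_label),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson rho(%s, %s) = %.2f over %d surveys\n",
              x$x_label, x$y_label, x$rho, x$n_surveys))
  invisible(x)
}

#' Full data-quality assessment of one survey
#'
#' Runs the three indicator assessments, the age-heaping ratio, and the
#' digit-preference screen on the age distribution. An indicator with
#' fewer than two non-missing values yields `NA` moments rather than an
#' error, so one sparse indicator does not abort a multi-survey run.
#'
#' @inheritParams assess_indicator
#' @param heap_targets,heap_window Passed to [age_heaping_ratio()].
#'
#' @return An object of class `survey_assessment`: `survey_id`,
#'   `indicators` (data frame, one row per indicator), `heaping`
#'   and `age_digit_test`.
#' @examples
#' tbl <- generate_survey(synthetic_survey_spec(n_children = 1000,
#'                                              seed = 42))
#' assess_survey(tbl)
#' @export
assess_survey <- function(table, threshold = -2, reference_sd = 1.0,
                          sd_references = c(0.8, 1.2),
                          heap_targets = c(24, 36, 48),
                          heap_window = 1) {
  stopifnot(inherits(table, "survey_table"))
  rows <- lapply(INDICATORS, function(ind) {
    s <- tryCatch(
      assess_indicator(table, ind, threshold, reference_sd,
                       sd_references),
      error = function(e) NULL)
    if (is.null(s)) {
      data.frame(indicator = ind, weighted_mean = NA_real_,
                 weighted_sd = NA_real_, estimated_prevalence = NA_real_,
                 bias_point = NA_real_, bias_low = NA_real_,
                 bias_high = NA_real_, n_used = 0L,
                 n_missing = sum(is.na(table[[ind]])))
    } else {
      data.frame(indicator = ind, weighted_mean = s$weighted_mean,
                 weighted_sd = s$weighted_sd,
                 estimated_prevalence = s$estimated_prevalence,
                 bias_point = s$bias_point,
                 bias_low = s$bias_interval[1],
                 bias_high = s$bias_interval[2],
                 n_used = s$n_used, n_missing = s$n_missing)
    }
  })
  structure(
    list(survey_id = survey_id(table),
         indicators = do.call(rbind, rows),
         heaping = age_heaping_ratio(table, heap_targets, heap_window),
         age_digit_test = tryCatch(
           suppressWarnings(
             digit_preference_test(table$age, "integer_month")),
           error = function(e) NULL)),
    class = "survey_assessment"
  )
}

#' @export
print.survey_assessment <- function(x, ...) {
  cat(sprintf("Survey '%s' data-quality assessment\n", x$survey_id))
  print(x$indicators, row.names = FALSE, digits = 3)
  print(x$heaping)
  if (!is.null(x$age_digit_test)) print(x$age_digit_test)
  invisible(x)
}

#' Assess a collection of surveys and correlate heaping with HAZ SD
#'
#' Applies [assess_survey()] to each table, builds the cross-survey
#' summary (one row per survey: heaping ratio, per-indicator weighted
#' moments and point biases) and computes the Pearson correlation
#' between the age-heaping ratio and the HAZ weighted SD.
#'
#' @param tables List of `survey_table` objects (>= 3 for the
#'   correlation).
#' @param ... Passed to [assess_survey()].
#'
#' @return An object of class `survey_collection_assessment`: `surveys`
#'   (list of per-survey assessments), `summary` (cross-survey data
#'   frame) and `correlation` (a `correlation_result`, or `NULL` with a
#'   warning when it cannot be computed).
#' @examples
#' tabs <- generate_survey_collection(k = 5, n_children = 400, seed = 3)
#' assess_survey_collection(tabs)$correlation
#' @export
assess_survey_collection <- function(tables, ...) {
  if (!is.list(tables) || length(tables) == 0L ||
      !all(vapply(tables, inherits, logical(1), "survey_table"))) {
    stop("`tables` must be a non-empty list of survey_table objects",
         call. = FALSE)
  }
  assessments <- lapply(tables, assess_survey, ...)
  one_row <- function(a) {
    ind <- a$indicators
    out <- data.frame(survey_id = a$survey_id,
                      n_children = a$heaping$total_count,
                      heaping_ratio = a$heaping$ratio)
    for (k in seq_len(nrow(ind))) {
      nm <- ind$indicator[k]
      out[[paste0(nm, "_mean")]] <- ind$weighted_mean[k]
      out[[paste0(nm, "_sd")]] <- ind$weighted_sd[k]
      out[[paste0(nm, "_bias_point")]] <- ind$bias_point[k]
      out[[paste0(nm, "_bias_low")]] <- ind$bias_low[k]
      out[[paste0(nm, "_bias_high")]] <- ind$bias_high[k]
    }
    out
  }
  summary_df <- do.call(rbind, lapply(assessments, one_row))
  correlation <- tryCatch(
    heaping_sd_correlation(summary_df),
    error = function(e) {
      warning("heaping-SD correlation unavailable: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  structure(
    list(surveys = assessments, summary = summary_df,
         correlation = correlation),
    class = "survey_collection_assessment"
  )
}

#' @export
print.survey_collection_assessment <- function(x, ...) {
  cat(sprintf("Assessment of %d surveys\n", nrow(x$summary)))
  print(x$summary[, c("survey_id", "n_children", "heaping_ratio",
                      "haz_mean", "haz_sd", "haz_bias_point")],
        row.names = FALSE, digits = 3)
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}

#' Write a survey assessment to JSON or CSV
#'
#' JSON keeps the full nested structure at machine precision; CSV writes
#' the per-indicator table (single survey) or the cross-survey summary
#' (collection).
#'
#' @param assessment A `survey_assessment` or
#'   `survey_collection_assessment`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(assessment, path,
                             format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(assessment, "survey_assessment")) {
    tab <- assessment$indicators
  } else if (inherits(assessment, "survey_collection_assessment")) {
    tab <- assessment$summary
  } else {
    stop("`assessment` must come from assess_survey() or assess_survey_collection()",
         call. = FALSE)
  }
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    x <- unclass(assessment)
    if (!is.null(x$surveys)) x$surveys <- lapply(x$surveys, unclass_deep)
    if (!is.null(x$heaping)) x$heaping <- unclass(x$heaping)
    if (!is.null(x$age_digit_test)) {
      x$age_digit_test <- unclass(x$age_digit_test)
    }
    if (!is.null(x$correlation)) x$correlation <- unclass(x$correlation)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  }
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x) && !is.data.frame(x)) x <- lapply(x, unclass_deep)
  x
}
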