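#' Specification for a synthetic anthropometry survey
#'
#' Describes the generative model used to emulate a per-child survey
#' file: a latent z-score distribution per indicator, additive
#' non-directional measurement error, age heaping towards whole-year
#' ages, log-normal survey weights and independent per-indicator
#' missingness. The defaults describe a clean mid-sized LMIC survey:
#' latent SD 1.0 for every indicator, no added error, no heaping, and
#' latent means of -1.5 (haz), -0.3 (whz) and -1.0 (waz).
#'
#' @param n_children Number of children.
#' @param true_mean Named numeric (haz/whz/waz) of latent means; a
#'   single number is recycled to all three.
#' @param true_sd Latent SDs, recycled likewise; default 1.0.
#' @param noise_sd SD of the additive non-directional error per
#'   indicator (the total from all sources), recycled; default 0.
#' @param heaping_fraction Proportion of children aged >= 18 months
#'   whose recorded age snaps to the nearest of `heap_targets`.
#' @param heap_targets Heaping target ages in months; default
#'   `c(24, 36, 48)`.
#' @param age_range Age range `c(min, max)` in integer months; true ages
#'   are uniform on `[min, max + 1)`. Default `c(0, 59)`.
#' @param weight_dispersion Coefficient of variation of the log-normal
#'   survey weights (normalized to mean 1); default 0.3.
#' @param missing_rate Independent per-indicator missingness
#'   probability, recycled; default 0.02.
#' @param seed Integer seed; required (all generation is deterministic
#'   under it).
#'
#' @return An object of class `synthetic_survey_spec`.
#' @examples
#' synthetic_survey_spec(n_children = 500, noise_sd = 1, seed = 1)
#' @export
synthetic_survey_spec <- function(n_children = 1000,
                                  true_mean = c(haz = -1.5, whz = -0.3,
                                                waz = -1.0),
                                  true_sd = 1.0,
                                  noise_sd = 0,
                                  heaping_fraction = 0,
                                  heap_targets = c(24, 36, 48),
                                  age_range = c(0, 59),
                                  weight_dispersion = 0.3,
                                  missing_rate = 0.02,
                                  seed = NULL) {
  n_children <- check_count(n_children, "n_children")
  per_ind <- function(x, name, min = -Inf) {
    if (length(x) == 1L) x <- rep(x, 3L)
    if (length(x) != 3L || !is.numeric(x) || any(!is.finite(x))) {
      stop("`", name, "` must be 1 or 3 finite values", call. = FALSE)
    }
    if (any(x < min)) {
      stop("`", name, "` must be >= ", min, call. = FALSE)
    }
    stats::setNames(as.numeric(x), INDICATORS)
  }
  true_mean <- per_ind(true_mean, "true_mean")
  true_sd <- per_ind(true_sd, "true_sd")
  if (any(true_sd <= 0)) stop("`true_sd` must be positive", call. = FALSE)
  noise_sd <- per_ind(noise_sd, "noise_sd", min = 0)
  missing_rate <- per_ind(missing_rate, "missing_rate", min = 0)
  if (any(missing_rate >= 1)) {
    stop("`missing_rate` must be < 1", call. = FALSE)
  }
  heaping_fraction <- check_scalar(heaping_fraction, "heaping_fraction")
  if (heaping_fraction < 0 || heaping_fraction > 1) {
    stop("`heaping_fraction` must be in [0, 1]", call. = FALSE)
  }
  weight_dispersion <- check_scalar(weight_dispersion,
                                    "weight_dispersion")
  if (weight_dispersion < 0) {
    stop("`weight_dispersion` must be >= 0", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] < 0 ||
      age_range[2] <= age_range[1]) {
    stop("`age_range` must be c(min, max) with 0 <= min < max",
         call. = FALSE)
  }
  seed <- check_seed(seed)
  structure(
    list(n_children = n_children, true_mean = true_mean,
         true_sd = true_sd, noise_sd = noise_sd,
         heaping_fraction = heaping_fraction,
         heap_targets = heap_targets, age_range = age_range,
         weight_dispersion = weight_dispersion,
         missing_rate = missing_rate, seed = seed),
    class = "synthetic_survey_spec"
  )
}

#' Generate a synthetic per-child survey table
#'
#' Per child: a true age uniform over the age range; a recorded age that
#' with probability `heaping_fraction` (children >= 18 months only, the
#' group for which whole-year age estimation is typical) snaps to the
#' nearest heaping target; latent z-scores Normal(true_mean, true_sd^2)
#' per indicator; recorded z-scores equal to the latent values plus
#' independent Normal(0, noise_sd^2) error; log-normal survey weights
#' normalized to mean 1; and independent per-indicator missingness.
#' Observed per-indicator SDs therefore concentrate around
#' `sqrt(true_sd^2 + noise_sd^2)`.
#'
#' @param spec A [synthetic_survey_spec()].
#' @param survey_id Label; default `"synthetic"`.
#'
#' @return A `survey_table` with attribute `true_params` (the spec), so
#'   parameter-recovery checks can compare estimates against truth.
#' @examples
#' tbl <- generate_survey(synthetic_survey_spec(n_children = 200,
#'                                              seed = 9))
#' head(tbl)
#' @export
generate_survey <- function(spec, survey_id = "synthetic") {
  if (!inherits(spec, "synthetic_survey_spec")) {
    stop("`spec` must be a `synthetic_survey_spec` object", call. = FALSE)
  }
  n <- spec$n_children
  df <- local_seed(spec$seed, {
    true_age <- stats::runif(n, spec$age_range[1], spec$age_range[2] + 1)
    heaped <- stats::runif(n) < spec$heaping_fraction & true_age >= 18
    snap <- vapply(true_age, function(a) {
      spec$heap_targets[which.min(abs(spec$heap_targets - a))]
    }, numeric(1))
    age <- ifelse(heaped, snap, true_age)
    z <- lapply(INDICATORS, function(ind) {
      latent <- stats::rnorm(n, spec$true_mean[ind], spec$true_sd[ind])
      recorded <- latent + stats::rnorm(n, 0, spec$noise_sd[ind])
      recorded[stats::runif(n) < spec$missing_rate[ind]] <- NA_real_
      recorded
    })
    names(z) <- INDICATORS
    if (spec$weight_dispersion > 0) {
      sdlog <- sqrt(log(1 + spec$weight_dispersion^2))
      wt <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      wt <- rep(1, n)
    }
    data.frame(age = age, haz = z$haz, whz = z$whz, waz = z$waz,
               wt = wt / mean(wt))
  })
  tbl <- new_survey_table(df, survey_id)
  attr(tbl, "true_params") <- spec
  tbl
}

#' Generate a collection of synthetic surveys with linked heaping and
#' noise
#'
#' Produces `k` surveys whose age-heaping fraction rises across the
#' collection and whose non-directional HAZ noise SD is a monotone
#' function of it, so the collection carries a positive heaping-SD
#' association by construction — the structure needed to exercise the
#' cross-survey correlation. The default link `noise_sd = 2 * heaping`
#' over heaping fractions 0-0.5 spans observed HAZ SDs of about
#' 1.0-1.4.
#'
#' @param k Number of surveys (>= 3).
#' @param n_children Children per survey.
#' @param heaping_fractions Numeric vector of length `k` (or a
#'   `c(min, max)` pair expanded to an even grid) of heaping fractions.
#' @param noise_link Function mapping a heaping fraction to the HAZ
#'   noise SD.
#' @param base_spec Optional [synthetic_survey_spec()] supplying every
#'   other field (its seed, heaping and haz noise are overridden per
#'   survey).
#' @param seed Integer seed; per-survey seeds are derived from it.
#'
#' @return List of `k` `survey_table` objects, ids `"synthetic-01"` ...
#' @examples
#' tabs <- generate_survey_collection(k = 5, n_children = 300, seed = 2)
#' length(tabs)
#' @export
generate_survey_collection <- function(k = 21, n_children = 1000,
                                       heaping_fractions = c(0, 0.5),
                                       noise_link = function(h) 2 * h,
                                       base_spec = NULL, seed) {
  k <- check_count(k, "k")
  if (k < 3L) stop("`k` must be >= 3", call. = FALSE)
  seed <- check_seed(seed)
  if (length(heaping_fractions) == 2L && k != 2L) {
    heaping_fractions <- seq(heaping_fractions[1], heaping_fractions[2],
                             length.out = k)
  }
  if (length(heaping_fractions) != k) {
    stop("`heaping_fractions` must have length k (or be a min/max pair)",
         call. = FALSE)
  }
  if (!is.function(noise_link)) {
    stop("`noise_link` must be a function", call. = FALSE)
  }
  lapply(seq_len(k), function(i) {
    h <- heaping_fractions[i]
    args <- if (is.null(base_spec)) {
      list(n_children = n_children)
    } else {
      s <- unclass(base_spec)
      s[c("seed", "heaping_fraction")] <- NULL
      s
    }
    args$heaping_fraction <- h
    args$noise_sd <- if (is.null(base_spec)) {
      c(haz = noise_link(h), whz = 0, waz = 0)
    } else {
      stats::setNames(
        c(noise_link(h), args$noise_sd[c("whz", "waz")]), INDICATORS)
    }
    args$seed <- derive_seed(seed, i)
    spec <- do.call(synthetic_survey_spec, args)
    generate_survey(spec, survey_id = sprintf("synthetic-%02d", i))
  })
}

#' Write a survey table as CSV in the per-child schema
#'
#' Writes the five columns `age,haz,whz,waz,wt` exactly. For synthetic
#' tables, a `<path>.json` sidecar records the true generating
#' parameters for parameter-recovery checks.
#'
#' @param table A `survey_table`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar when true parameters are
#'   available; default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path, sidecar = TRUE) {
  stopifnot(inherits(table, "survey_table"))
  utils::write.csv(as.data.frame(table)[SURVEY_COLUMNS], path,
                   row.names = FALSE)
  truth <- attr(table, "true_params", exact = TRUE)
  if (isTRUE(sidecar) && !is.null(truth)) {
    meta <- unclass(truth)
    # keep per-indicator names in the JSON objects
    for (f in c("true_mean", "true_sd", "noise_sd", "missing_rate")) {
      meta[[f]] <- as.list(meta[[f]])
    }
    meta$survey_id <- survey_id(table)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
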