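#' Grid specification for a prevalence/bias surface
#'
#' Defines the uniformly-spaced (mean, SD) grid over which prevalence and
#' bias surfaces are computed. The default bounds cover the parameter
#' ranges relevant to LMIC child anthropometry: means in \[-4.5, 0.5\]
#' (symmetric around the cutoff -2) and SDs in \[0.8, 2.0\]; the
#' reference SD of 1.0 is the midpoint of the high-quality range
#' 0.8-1.2. Default steps are 0.25 in mean and 0.1 in SD, so the
#' reference anchors 0.8/1.0/1.2 and the bias-extremum means fall on grid
#' points.
#'
#' @param mean_min,mean_max,mean_step Mean-axis bounds and spacing
#'   (z-score units).
#' @param sd_min,sd_max,sd_step SD-axis bounds and spacing (z-score
#'   units, positive).
#' @param threshold Prevalence cutoff; default -2.
#' @param reference_sd SD the distribution would have absent
#'   non-directional error; default 1.0.
#' @param engine `"closed_form"` (exact, default) or `"monte_carlo"`
#'   (per-cell simulation, as in the original exercise).
#' @param n_samples Observations per cell for the Monte Carlo engine;
#'   default 500000.
#' @param seed Integer seed, required for the Monte Carlo engine.
#'
#' @return An object of class `bias_grid_spec`.
#' @examples
#' bias_grid_spec()
#' @export
bias_grid_spec <- function(mean_min = -4.5, mean_max = 0.5,
                           sd_min = 0.8, sd_max = 2.0,
                           mean_step = 0.25, sd_step = 0.1,
                           threshold = -2, reference_sd = 1.0,
                           engine = c("closed_form", "monte_carlo"),
                           n_samples = 500000L, seed = NULL) {
  engine <- match.arg(engine)
  mean_min <- check_scalar(mean_min, "mean_min")
  mean_max <- check_scalar(mean_max, "mean_max")
  sd_min <- check_scalar(sd_min, "sd_min")
  sd_max <- check_scalar(sd_max, "sd_max")
  mean_step <- check_scalar(mean_step, "mean_step")
  sd_step <- check_scalar(sd_step, "sd_step")
  threshold <- check_scalar(threshold, "threshold")
  reference_sd <- check_scalar(reference_sd, "reference_sd")
  if (mean_step <= 0 || sd_step <= 0) {
    stop("grid steps must be positive", call. = FALSE)
  }
  if (mean_max < mean_min || sd_max < sd_min) {
    stop("grid bounds must satisfy min <= max", call. = FALSE)
  }
  if (sd_min <= 0) stop("`sd_min` must be positive", call. = FALSE)
  if (reference_sd <= 0) {
    stop("`reference_sd` must be positive", call. = FALSE)
  }
  if (engine == "monte_carlo") {
    n_samples <- check_count(n_samples, "n_samples")
    seed <- check_seed(seed)
  }
  structure(
    list(mean_min = mean_min, mean_max = mean_max,
         sd_min = sd_min, sd_max = sd_max,
         mean_step = mean_step, sd_step = sd_step,
         threshold = threshold, reference_sd = reference_sd,
         engine = engine,
         n_samples = if (engine == "monte_carlo") n_samples else NULL,
         seed = if (engine == "monte_carlo") seed else NULL),
    class = "bias_grid_spec"
  )
}

grid_axis <- function(from, to, by) {
  # seq() accumulates; snap back to exact multiples of the step
  k <- floor((to - from) / by + 1e-9)
  from + by * (0:k)
}

#' Build the prevalence and bias surfaces over a (mean, SD) grid
#'
#' For every grid cell, computes the prevalence of z-scores below the
#' cutoff and the prevalence *bias*: the difference between that
#' prevalence and the prevalence at the same mean but at the reference
#' SD. The bias is zero along the reference-SD column and along the
#' mean-equal-to-threshold row, antisymmetric about that row, and its
#' magnitude grows with SD.
#'
#' @param spec A [bias_grid_spec()].
#'
#' @return An object of class `bias_map`: list with `mean_axis`,
#'   `sd_axis`, matrices `prevalence` and `bias` (rows index means,
#'   columns SDs), `mc_standard_error` (Monte Carlo engine only) and the
#'   `spec`. Convert to long format with `as.data.frame()`.
#' @examples
#' m <- build_bias_map(bias_grid_spec())
#' head(as.data.frame(m))
#' @export
build_bias_map <- function(spec = bias_grid_spec()) {
  if (!inherits(spec, "bias_grid_spec")) {
    stop("`spec` must be a `bias_grid_spec` object", call. = FALSE)
  }
  mean_axis <- grid_axis(spec$mean_min, spec$mean_max, spec$mean_step)
  sd_axis <- grid_axis(spec$sd_min, spec$sd_max, spec$sd_step)
  if (length(mean_axis) == 0L || length(sd_axis) == 0L) {
    stop("grid has zero cells", call. = FALSE)
  }
  nm <- length(mean_axis)
  ns <- length(sd_axis)
  mc_se <- NULL

  if (spec$engine == "closed_form") {
    prevalence <- outer(mean_axis, sd_axis, function(m, s) {
      stats::pnorm((spec$threshold - m) / s)
    })
    ref_prev <- stats::pnorm((spec$threshold - mean_axis) /
                               spec$reference_sd)
  } else {
    prevalence <- matrix(NA_real_, nm, ns)
    mc_se <- matrix(NA_real_, nm, ns)
    for (i in seq_len(nm)) {
      for (j in seq_len(ns)) {
        cell_seed <- derive_seed(spec$seed, (i - 1L) * ns + (j - 1L))
        x <- simulate_normal(normal_params(mean_axis[i], sd_axis[j]),
                             spec$n_samples, seed = cell_seed)
        est <- prevalence_empirical(x, spec$threshold)
        prevalence[i, j] <- est$value
        mc_se[i, j] <- est$mc_standard_error
      }
    }
    # reference prevalence per mean with the same engine; reuse the grid
    # column when the reference SD is itself a grid point so the bias
    # there is exactly zero
    ref_j <- which(abs(sd_axis - spec$reference_sd) < 1e-9)
    if (length(ref_j) == 1L) {
      ref_prev <- prevalence[, ref_j]
    } else {
      ref_prev <- vapply(seq_len(nm), function(i) {
        cell_seed <- derive_seed(spec$seed, nm * ns + i)
        x <- simulate_normal(
          normal_params(mean_axis[i], spec$reference_sd),
          spec$n_samples, seed = cell_seed)
        prevalence_empirical(x, spec$threshold)$value
      }, numeric(1))
    }
  }

  bias <- prevalence - ref_prev
  dimnames(prevalence) <- dimnames(bias) <-
    list(mean = formatC(mean_axis), sd = formatC(sd_axis))
  structure(
    list(mean_axis = mean_axis, sd_axis = sd_axis,
         prevalence = prevalence, bias = bias,
         mc_standard_error = mc_se, spec = spec),
    class = "bias_map"
  )
}

#' @export
print.bias_map <- function(x, ...) {
  cat(sprintf(
    "Prevalence-bias map (%s engine): %d means x %d SDs, threshold %.4g, reference SD %.4g\n",
    x$spec$engine, length(x$mean_axis), length(x$sd_axis),
    x$spec$threshold, x$spec$reference_sd))
  cat(sprintf("  bias range: [%+.4f, %+.4f]\n", min(x$bias), max(x$bias)))
  invisible(x)
}

#' @export
as.data.frame.bias_map <- function(x, ...) {
  d <- expand.grid(mean = x$mean_axis, sd = x$sd_axis,
                   KEEP.OUT.ATTRS = FALSE)
  d$prevalence <- as.vector(x$prevalence)
  d$bias <- as.vector(x$bias)
  if (!is.null(x$mc_standard_error)) {
    d$mc_standard_error <- as.vector(x$mc_standard_error)
  }
  d
}

#' Write a bias map as CSV with a JSON metadata sidecar
#'
#' Serializes the map in long format (mean, sd, prevalence, bias) plus a
#' `<path>.json` sidecar recording the grid specification, engine and
#' seed, so a map can be diffed, re-plotted and reproduced.
#'
#' @param map A [build_bias_map()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bias_map <- function(map, path) {
  if (!inherits(map, "bias_map")) {
    stop("`map` must be a `bias_map` object", call. = FALSE)
  }
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  meta <- map$spec
  class(meta) <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Point estimate of prevalence bias from non-directional error
#'
#' The bias in a threshold prevalence attributable to SD inflation is the
#' difference between the prevalence at the observed (mean, sd) and the
#' prevalence the same mean would give at the reference SD:
#' \eqn{\Phi((T-\mu)/\sigma) - \Phi((T-\mu)/\sigma_{ref})}. It is a
#' diagnostic of vulnerability to non-directional measurement error, not
#' a correction to apply to the reported prevalence.
#'
#' @param mean,sd Observed distribution mean and SD (z-score units);
#'   vectorized.
#' @param threshold Cutoff; default -2.
#' @param reference_sd Reference SD; default 1.0.
#'
#' @return Signed proportion(s): positive when the prevalence is
#'   overestimated.
#' @examples
#' estimate_bias(-1, 1.4)   # ~ +0.08: stunting inflated by ~8 points
#' estimate_bias(-3, 1.4)   # ~ -0.08: underestimated by ~8 points
#' @export
estimate_bias <- function(mean, sd, threshold = -2, reference_sd = 1.0) {
  if (!is.numeric(mean) || !is.numeric(sd)) {
    stop("`mean` and `sd` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(mean)) || any(!is.finite(sd)) || any(sd <= 0)) {
    stop("`mean` must be finite and `sd` finite and positive",
         call. = FALSE)
  }
  threshold <- check_scalar(threshold, "threshold")
  reference_sd <- check_scalar(reference_sd, "reference_sd")
  if (reference_sd <= 0) {
    stop("`reference_sd` must be positive", call. = FALSE)
  }
  stats::pnorm((threshold - mean) / sd) -
    stats::pnorm((threshold - mean) / reference_sd)
}

#' Range of likely prevalence biases under realistic heterogeneity
#'
#' Genuine nutritional heterogeneity means a clean survey's SD can
#' plausibly sit anywhere in 0.8-1.2, not exactly at 1.0. Anchoring the
#' bias at both ends of that range turns the point estimate into an
#' interval of likely biases for the observed (mean, sd).
#'
#' @inheritParams estimate_bias
#' @param references Length-2 vector of low and high reference SDs;
#'   default `c(0.8, 1.2)`.
#'
#' @return An object of class `realistic_bias_range`: list with `mean`,
#'   `sd`, `bias_vs_low_ref`, `bias_vs_high_ref` and the sorted
#'   `interval`.
#' @examples
#' realistic_bias_range(-1, 1.6)
#' @export
realistic_bias_range <- function(mean, sd, threshold = -2,
                                 references = c(0.8, 1.2)) {
  mean <- check_scalar(mean, "mean")
  sd <- check_scalar(sd, "sd")
  if (sd <= 0) stop("`sd` must be positive", call. = FALSE)
  if (!is.numeric(references) || length(references) != 2L ||
      any(references <= 0)) {
    stop("`references` must be two positive SD values", call. = FALSE)
  }
  lo <- estimate_bias(mean, sd, threshold, reference_sd = references[1])
  hi <- estimate_bias(mean, sd, threshold, reference_sd = references[2])
  structure(
    list(mean = mean, sd = sd, threshold = threshold,
         references = references,
         bias_vs_low_ref = lo, bias_vs_high_ref = hi,
         interval = sort(c(lo, hi))),
    class = "realistic_bias_range"
  )
}

#' @export
print.realistic_bias_range <- function(x, ...) {
  cat(sprintf(
    "Likely prevalence bias at mean %.3g, sd %.3g (refs %.2g-%.2g): [%+.1f, %+.1f] pp\n",
    x$mean, x$sd, x$references[1], x$references[2],
    100 * x$interval[1], 100 * x$interval[2]))
  invisible(x)
}

#' Locate the bias extrema on a map
#'
#' Finds the grid cells with the largest overestimate (most positive
#' bias) and the largest underestimate (most negative bias). On the
#' default grid both occur on the upper SD boundary, at means symmetric
#' about the cutoff. Requires the closed-form engine: Monte Carlo noise
#' can flip a near-flat argmax between neighbouring cells.
#'
#' @param spec A [bias_grid_spec()] with `engine = "closed_form"`, or an
#'   already-built closed-form [build_bias_map()].
#'
#' @return An object of class `bias_extrema`: `overestimate` and
#'   `underestimate` (each a list of `mean`, `sd`, `bias`) and `by_sd`, a
#'   data frame of per-SD-slice extremum means.
#' @examples
#' locate_bias_extrema(bias_grid_spec())
#' @export
locate_bias_extrema <- function(spec = bias_grid_spec()) {
  map <- if (inherits(spec, "bias_map")) spec else build_bias_map(spec)
  if (map$spec$engine != "closed_form") {
    stop("extremum location requires the closed_form engine",
         call. = FALSE)
  }
  b <- map$bias
  at <- function(idx) {
    ij <- arrayInd(idx, dim(b))
    list(mean = map$mean_axis[ij[1]], sd = map$sd_axis[ij[2]],
         bias = b[idx])
  }
  by_sd <- data.frame(
    sd = map$sd_axis,
    mean_at_max = map$mean_axis[apply(b, 2, which.max)],
    max_bias = apply(b, 2, max),
    mean_at_min = map$mean_axis[apply(b, 2, which.min)],
    min_bias = apply(b, 2, min)
  )
  structure(
    list(overestimate = at(which.max(b)),
         underestimate = at(which.min(b)),
         by_sd = by_sd),
    class = "bias_extrema"
  )
}

#' @export
print.bias_extrema <- function(x, ...) {
  cat(sprintf(
    "Max overestimate  %+.4f at mean %.3g (sd %.3g)\nMax underestimate %+.4f at mean %.3g (sd %.3g)\n",
    x$overestimate$bias, x$overestimate$mean, x$overestimate$sd,
    x$underestimate$bias, x$underestimate$mean, x$underestimate$sd))
  invisible(x)
}
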