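#' Specification of additive measurement noise
#'
#' Non-directional measurement error is modelled as an independent
#' additive normal draw per observation with mean 0: it leaves the
#' distribution mean unchanged and inflates the SD from `s` to
#' `sqrt(s^2 + error_sd^2)`. A nonzero `error_mean` is exposed for
#' exploring directional error, but the default is the non-directional
#' case.
#'
#' @param error_sd Noise standard deviation, z-score units, >= 0.
#' @param error_mean Noise mean, z-score units; default 0
#'   (non-directional).
#'
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(1)      # total non-directional error of 1 z-score SD
#' @export
noise_spec <- function(error_sd, error_mean = 0) {
  error_sd <- check_scalar(error_sd, "error_sd")
  if (error_sd < 0) stop("`error_sd` must be >= 0", call. = FALSE)
  error_mean <- check_scalar(error_mean, "error_mean")
  structure(list(error_sd = error_sd, error_mean = error_mean),
            class = "noise_spec")
}

as_noise_spec <- function(x) {
  if (inherits(x, "noise_spec")) return(x)
  stop("`noise` must be a `noise_spec` object; see noise_spec()",
       call. = FALSE)
}

#' Add simulated measurement error to a sample
#'
#' Element-wise sum of the input observations and independent noise
#' draws. Order is preserved, so each observation can be paired with its
#' perturbed value for threshold-crossing bookkeeping. The noise stream
#' takes its own seed, independent of the stream that produced the base
#' sample, so the same sample can be re-perturbed reproducibly.
#'
#' @param samples Numeric vector of z-score observations (non-empty).
#' @param noise A [noise_spec()].
#' @param seed Integer seed for the noise draws.
#'
#' @return Numeric vector, same length and order as `samples`.
#' @examples
#' z <- simulate_normal(normal_params(-1, 1), 100, seed = 1)
#' zz <- inject_noise(z, noise_spec(1), seed = 2)
#' @export
inject_noise <- function(samples, noise, seed) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  noise <- as_noise_spec(noise)
  seed <- check_seed(seed)
  eps <- local_seed(seed, stats::rnorm(length(samples),
                                       mean = noise$error_mean,
                                       sd = noise$error_sd))
  as.numeric(samples) + eps
}

#' Tally threshold crossings between paired samples
#'
#' Classifies each (before, after) pair relative to the cutoff. Naming
#' follows the error-injection framing, not the screening-test
#' convention: a *false positive* is an observation pushed from at-or-
#' above the threshold to below it purely by the added error (spuriously
#' flagged), and a *false negative* is the reverse. True positives stay
#' below in both; true negatives stay at-or-above in both.
#'
#' @param before Numeric vector of original observations.
#' @param after Numeric vector of perturbed observations, positionally
#'   paired with `before`.
#' @param threshold Cutoff in z-score units.
#'
#' @return An object of class `classification_counts` with fields
#'   `true_positive`, `false_positive`, `true_negative`,
#'   `false_negative` and `n`.
#' @examples
#' classify_crossings(c(-3, -1), c(-1, -3))  # one FN, one FP
#' @export
classify_crossings <- function(before, after, threshold = -2) {
  if (!is.numeric(before) || !is.numeric(after)) {
    stop("`before` and `after` must be numeric vectors", call. = FALSE)
  }
  if (length(before) != length(after)) {
    stop("`before` and `after` must have equal length", call. = FALSE)
  }
  threshold <- check_scalar(threshold, "threshold")
  b <- before < threshold
  a <- after < threshold
  structure(
    list(true_positive = sum(b & a),
         false_positive = sum(!b & a),
         true_negative = sum(!b & !a),
         false_negative = sum(b & !a),
         n = length(before),
         threshold = threshold),
    class = "classification_counts"
  )
}

#' @export
print.classification_counts <- function(x, ...) {
  cat(sprintf(
    "Threshold crossings at %.4g (n = %d):\n  TP %d  FP %d  TN %d  FN %d\n",
    x$threshold, x$n, x$true_positive, x$false_positive,
    x$true_negative, x$false_negative))
  invisible(x)
}

#' Run a full error-injection experiment
#'
#' Simulates an ideal z-score sample, adds non-directional measurement
#' error, and accounts exactly for the resulting prevalence shift: the
#' change in prevalence equals (false positives - false negatives) / n to
#' machine precision, since only crossings can move the count. The sign
#' of the expected net bias is set by the distribution mean relative to
#' the cutoff: positive above it, negative below it, zero at the cutoff.
#'
#' @param params A [normal_params()] for the ideal (error-free)
#'   distribution.
#' @param noise A [noise_spec()].
#' @param n Number of observations.
#' @param seed Integer seed. Base-sample and noise draws use independent
#'   sub-streams derived from it.
#' @param threshold Cutoff in z-score units.
#'
#' @return An object of class `injection_result`: list with
#'   `before`/`after` ([prevalence_empirical()] estimates), `counts`
#'   ([classify_crossings()]), `sd_before`, `sd_after` and `net_bias`
#'   (a signed proportion).
#' @examples
#' r <- run_injection_experiment(normal_params(-1, 1), noise_spec(1),
#'                               n = 50000, seed = 7)
#' r$net_bias   # ~ +0.08: prevalence spuriously inflated
#' @export
run_injection_experiment <- function(params, noise, n, seed,
                                     threshold = -2) {
  params <- as_normal_params(params)
  noise <- as_noise_spec(noise)
  n <- check_count(n, "n")
  seed <- check_seed(seed)
  base <- simulate_normal(params, n, seed = derive_seed(seed, 0L))
  perturbed <- inject_noise(base, noise, seed = derive_seed(seed, 1L))
  counts <- classify_crossings(base, perturbed, threshold)
  before <- prevalence_empirical(base, threshold)
  after <- prevalence_empirical(perturbed, threshold)
  structure(
    list(params = params, noise = noise, seed = seed,
         before = before, after = after, counts = counts,
         sd_before = stats::sd(base), sd_after = stats::sd(perturbed),
         net_bias = (counts$false_positive - counts$false_negative) / n),
    class = "injection_result"
  )
}

#' @export
print.injection_result <- function(x, ...) {
  cat(sprintf(
    paste0("Error-injection experiment (mean %.4g, sd %.4g, ",
           "noise sd %.4g, n = %d)\n"),
    x$params$mean, x$params$sd, x$noise$error_sd, x$counts$n))
  cat(sprintf("  prevalence below %.4g: %.1f%% -> %.1f%%  (net bias %+.2f pp)\n",
              x$before$threshold, 100 * x$before$value,
              100 * x$after$value, 100 * x$net_bias))
  cat(sprintf("  sample SD: %.3f -> %.3f\n", x$sd_before, x$sd_after))
  cat(sprintf("  crossings: FP %d, FN %d\n",
              x$counts$false_positive, x$counts$false_negative))
  invisible(x)
}
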