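#' Calibrate the de novo initiation rate to a target ribosome load
#'
#' Finds the initiation rate `alpha` at which the lifetime-averaged ribosome
#' count on a reference transcript equals a target (the usual normalization:
#' 6 ribosomes on a 400-codon transcript, held constant across reinitiation
#' levels so that different levels are compared at equal ribosome usage).
#'
#' The mean count is monotone non-decreasing in `alpha`, so the search is a
#' bisection on `log10(alpha)`.  Every evaluation reuses the same root seed
#' (common random numbers), which makes the count-versus-alpha curve smooth
#' in the search and prevents stalls from Monte-Carlo noise.
#'
#' @param reference a [transcript_spec()]; its `alpha` slot is ignored.
#' @param target_count target lifetime-averaged ribosome count (default 6).
#' @param n_runs replicates per evaluation (default 1000).
#' @param seed integer root seed shared by all evaluations.
#' @param tolerance acceptable |mean count - target| in ribosomes.
#' @param bracket initial `alpha` search interval in 1/s, expanded on demand.
#' @param max_iter bisection iteration cap.
#' @return List of class `"alpha_calibration"`: `alpha`, `achieved_count`,
#'   `target_count`, `n_runs`, `iterations`.
#' @examples
#' ref <- transcript_spec(L = 60, elong_rates = 10, alpha = 0,
#'                        reinit_rate = 5, release_rate = 5, lifetime = 100,
#'                        footprint = 10)
#' cal <- calibrate_alpha(ref, target_count = 2, n_runs = 100, seed = 1,
#'                        tolerance = 0.1)
#' @export
calibrate_alpha <- function(reference, target_count = 6, n_runs = 1000L, seed,
                            tolerance = 0.05, bracket = c(1e-6, 1e2),
                            max_iter = 60L) {
  stopifnot(inherits(reference, "transcript_spec"))
  max_pack <- reference$L / reference$footprint
  if (target_count >= max_pack)
    stop(sprintf("target_count %.3g is at or beyond maximum packing %.3g",
                 target_count, max_pack))
  if (target_count < 0) stop("target_count must be >= 0")
  if (n_runs < 1) stop("n_runs must be >= 1")

  mk <- function(alpha) {
    s <- reference
    s$alpha <- alpha
    s
  }
  count_at <- function(alpha) {
    simulate_translation(mk(alpha), n_runs = n_runs, seed = seed)$mean_ribosomes
  }

  if (target_count == 0)
    return(structure(list(alpha = 0, achieved_count = 0,
                          target_count = 0, n_runs = as.integer(n_runs),
                          iterations = 0L), class = "alpha_calibration"))

  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- count_at(lo)
  if (f_lo > target_count + tolerance) {
    # expand downwards a few decades before giving up
    for (i in 1:6) {
      lo <- lo / 10
      f_lo <- count_at(lo)
      if (f_lo <= target_count) break
    }
    if (f_lo > target_count + tolerance)
      stop(sprintf("target unreachable: count %.3f at alpha = %.3g already exceeds target %.3g",
                   f_lo, lo, target_count))
  }
  f_hi <- count_at(hi)
  if (f_hi < target_count - tolerance) {
    for (i in 1:6) {
      hi <- hi * 10
      f_hi <- count_at(hi)
      if (f_hi >= target_count) break
    }
    if (f_hi < target_count - tolerance)
      stop(sprintf("target unreachable: count %.3f at saturating alpha = %.3g below target %.3g (lifetime too short?)",
                   f_hi, hi, target_count))
  }

  iter <- 0L
  mid <- sqrt(lo * hi)
  f_mid <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    mid <- 10^((log10(lo) + log10(hi)) / 2)
    f_mid <- count_at(mid)
    if (abs(f_mid - target_count) <= tolerance) break
    if (f_mid < target_count) lo <- mid else hi <- mid
  }
  structure(list(alpha = mid, achieved_count = f_mid,
                 target_count = target_count, n_runs = as.integer(n_runs),
                 iterations = iter), class = "alpha_calibration")
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat(sprintf("Calibrated alpha = %.5g /s (mean count %.3f, target %.3g, %d runs, %d iterations)\n",
              x$alpha, x$achieved_count, x$target_count, x$n_runs, x$iterations))
  invisible(x)
}
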