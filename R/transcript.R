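#' Specify a transcript for simulation
#'
#' A transcript is a lattice of `L` sites (one per codon); site `L` is the
#' termination site occupied by the stop codon.  Sites `1..L-1` carry
#' elongation rates; the termination site carries only the release and
#' reinitiation channels.
#'
#' @param L lattice length in codons (termination site included).
#' @param elong_rates per-site elongation rates in 1/s, length `L - 1`, all
#'   positive.  A single value is recycled (uniform elongation).
#' @param alpha de novo initiation rate in 1/s.
#' @param reinit_rate reinitiation rate in 1/s (terminating ribosome returns
#'   to the start codon of the same transcript).
#' @param release_rate release rate in 1/s (terminating ribosome returns to
#'   the cytoplasmic pool).
#' @param lifetime transcript lifetime in s; simulation covers `[0, lifetime]`.
#' @param footprint exclusion span in codons: consecutive A-sites must differ
#'   by at least this many sites.  Default 10, the ribosome footprint.
#' @param id optional text label.
#'
#' @return An object of class `"transcript_spec"`.
#' @examples
#' spec <- transcript_spec(L = 400, elong_rates = 10, alpha = 0.005,
#'                         reinit_rate = 9.99, release_rate = 0.01,
#'                         lifetime = 1553)
#' spec
#' @export
transcript_spec <- function(L, elong_rates, alpha, reinit_rate, release_rate,
                            lifetime, footprint = 10L, id = "transcript") {
  L <- as.integer(L)
  footprint <- as.integer(footprint)
  if (length(elong_rates) == 1L && L > 1L) elong_rates <- rep(elong_rates, L - 1L)
  spec <- structure(
    list(id = as.character(id), L = L, elong_rates = as.numeric(elong_rates),
         alpha = as.numeric(alpha), reinit_rate = as.numeric(reinit_rate),
         release_rate = as.numeric(release_rate),
         footprint = footprint, lifetime = as.numeric(lifetime)),
    class = "transcript_spec")
  validate_transcript_spec(spec)
  spec
}

#' Validate a transcript specification
#'
#' Checks the structural invariants of a [transcript_spec()]; errors name the
#' violated invariant.
#'
#' @param spec a `"transcript_spec"`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_transcript_spec <- function(spec) {
  stopifnot(inherits(spec, "transcript_spec"))
  with(spec, {
    if (!(is.finite(L) && L >= 1L)) stop("L must be a positive integer")
    if (!(footprint >= 1L)) stop("footprint must be >= 1")
    if (!(L > footprint)) stop("L must exceed the footprint (L > footprint)")
    if (length(elong_rates) != L - 1L)
      stop(sprintf("elong_rates must have exactly L - 1 = %d entries (got %d)",
                   L - 1L, length(elong_rates)))
    if (any(!is.finite(elong_rates)) || any(elong_rates <= 0))
      stop("all elongation rates must be finite and > 0")
    for (nm in c("alpha", "reinit_rate", "release_rate"))
      if (!is.finite(get(nm)) || get(nm) < 0)
        stop(sprintf("%s must be finite and >= 0", nm))
    if (reinit_rate + release_rate <= 0)
      stop("reinit_rate + release_rate must be > 0 (the termination site needs an exit channel)")
    if (!(is.finite(lifetime) && lifetime >= 0)) stop("lifetime must be finite and >= 0")
  })
  invisible(spec)
}

#' @export
print.transcript_spec <- function(x, ...) {
  er <- x$elong_rates
  er_txt <- if (length(unique(er)) == 1L) {
    sprintf("uniform %.3g /s", er[1])
  } else {
    sprintf("per-site, mean %.3g /s (range %.3g-%.3g)", mean(er), min(er), max(er))
  }
  lev <- level_from_rates(x$reinit_rate, x$release_rate)
  cat(sprintf("Transcript '%s': %d codons (footprint %d)\n", x$id, x$L, x$footprint))
  cat(sprintf("  elongation:    %s\n", er_txt))
  cat(sprintf("  initiation:    alpha = %.4g /s\n", x$alpha))
  cat(sprintf("  termination:   reinit %.4g /s, release %.4g /s (reinitiation level %.1f%%)\n",
              x$reinit_rate, x$release_rate, 100 * lev))
  cat(sprintf("  lifetime:      %.4g s\n", x$lifetime))
  invisible(x)
}
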