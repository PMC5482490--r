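#' Split a total termination rate into reinitiation and release rates
#'
#' The reinitiation level is the probability that a terminating ribosome
#' returns to the start codon rather than to the cytoplasmic pool:
#' `level = r / (r + beta)`.  Given a level and the total termination rate
#' `r + beta`, this returns the implied `(r, beta)` pair.
#'
#' @param level reinitiation level, a probability in `[0, 1]`.
#' @param termination_total total termination rate `r + beta` in 1/s.  The
#'   absolute termination timescale is not pinned down by the level alone;
#'   the default 10/s matches the transcriptome-average elongation rate so
#'   that termination is not limiting.
#' @return Named numeric vector `c(reinit_rate =, release_rate =)`.
#' @examples
#' rates_from_level(0.999, 10)
#' @export
rates_from_level <- function(level, termination_total = 10) {
  if (!is.finite(level) || level < 0 || level > 1)
    stop("level must be a probability in [0, 1]")
  if (!is.finite(termination_total) || termination_total <= 0)
    stop("termination_total must be > 0")
  c(reinit_rate = level * termination_total,
    release_rate = (1 - level) * termination_total)
}

#' Reinitiation level implied by a rate pair
#'
#' Inverse of [rates_from_level()]: `level = r / (r + beta)`.
#'
#' @param reinit_rate reinitiation rate in 1/s.
#' @param release_rate release rate in 1/s.
#' @return The reinitiation level in `[0, 1]`.
#' @export
level_from_rates <- function(reinit_rate, release_rate) {
  tot <- reinit_rate + release_rate
  if (!is.finite(tot) || tot <= 0) stop("reinit_rate + release_rate must be > 0")
  reinit_rate / tot
}

#' Reinitiation level after scaling the reinitiation rate
#'
#' Multiplying the reinitiation rate by `factor` while holding the release
#' rate fixed moves the level `p` to `factor * p / (factor * p + (1 - p))`.
#' Doubling the rate at a 90% level, for example, gives 94.7%; halving it
#' gives 81.8%.  The endpoints 0 and 1 are fixed points for any factor.
#'
#' @param level reinitiation level in `[0, 1]`.
#' @param factor positive multiplier applied to the reinitiation rate.
#' @return The shifted reinitiation level.
#' @examples
#' scale_reinitiation_level(0.90, 2)    # 0.947
#' scale_reinitiation_level(0.90, 0.5)  # 0.818
#' @export
scale_reinitiation_level <- function(level, factor) {
  if (any(!is.finite(level)) || any(level < 0) || any(level > 1))
    stop("level must be a probability in [0, 1]")
  if (any(!is.finite(factor)) || any(factor <= 0)) stop("factor must be > 0")
  factor * level / (factor * level + (1 - level))
}

#' Length-dependent reinitiation level
#'
#' A simple declining rule in which short transcripts reinitiate almost
#' always and the level falls linearly to zero at 4000 codons:
#' `max(0, 1 - L / 4000)`.
#'
#' @param L CDS length in codons.
#' @return Reinitiation level(s) in `[0, 1]`.
#' @examples
#' length_dependent_level(c(400, 2000, 4000))
#' @export
length_dependent_level <- function(L) {
  if (any(L < 1)) stop("L must be >= 1")
  pmax(0, 1 - L / 4000)
}

#' Uniform per-site elongation rates
#'
#' @param L lattice length in codons.
#' @param rate elongation rate in 1/s applied to every site `1..L-1`.
#' @return Numeric vector of length `L - 1`.
#' @export
uniform_rates <- function(L, rate = 10) {
  if (L < 2) stop("L must be >= 2")
  if (rate <= 0) stop("rate must be > 0")
  rep(as.numeric(rate), L - 1L)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Per-site elongation rates from a coding sequence
#'
#' Maps each codon of a CDS to its decoding rate.  The lattice has one site
#' per codon including the stop codon, which occupies the termination site
#' and carries no elongation rate; sites `1..L-1` get the table rate of
#' codons `1..L-1`.
#'
#' @param cds DNA coding sequence (character scalar, `ACGT`; `U` is accepted
#'   and converted).  Length must be a multiple of 3.
#' @param table a rate table as returned by [read_rate_table()] or
#'   [synthetic_rate_table()]: named numeric vector, codon -> rate in 1/s.
#' @param require_stop if `TRUE` (default) the final codon must be a stop
#'   codon (TAA/TAG/TGA); set `FALSE` for sequences without a terminal stop,
#'   in which case the last codon still occupies the termination site.
#' @return Numeric vector of `L - 1` rates with attribute `L` (codon count).
#' @examples
#' tab <- synthetic_rate_table()
#' r <- build_elongation_rates(paste0("ATG", "GGT", "GAA", "TAA"), tab)
#' @export
build_elongation_rates <- function(cds, table, require_stop = TRUE) {
  cds <- toupper(gsub("U", "T", as.character(cds)[1], fixed = FALSE))
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS contains characters outside ACGT/U")
  n_codon <- nchar(cds) / 3
  if (n_codon < 2) stop("CDS must contain at least 2 codons")
  codons <- substring(cds, seq(1, nchar(cds) - 2, by = 3),
                      seq(3, nchar(cds), by = 3))
  internal_stop <- which(codons[-n_codon] %in% STOP_CODONS)
  if (length(internal_stop) > 0)
    stop(sprintf("internal stop codon %s at codon %d",
                 codons[internal_stop[1]], internal_stop[1]))
  if (require_stop && !(codons[n_codon] %in% STOP_CODONS))
    stop("final codon is not a stop codon (use require_stop = FALSE if intended)")
  body <- codons[-n_codon]
  unknown <- setdiff(body, names(table))
  if (length(unknown) > 0)
    stop(sprintf("codon(s) not in rate table: %s",
                 paste(unique(unknown), collapse = ", ")))
  rates <- unname(table[body])
  attr(rates, "L") <- as.integer(n_codon)
  rates
}

#' Introduce a single slow elongation step
#'
#' Replaces the rate of one site with `slow_rate`.  Positions follow the
#' usual experiment design: `"start"` is site 1 (the start codon),
#' `"middle"` is site `ceiling((L - 1) / 2)`, `"final"` is site `L - 1`
#' (the codon immediately before the stop codon); a numeric index in
#' `1..L-1` is also accepted.
#'
#' @param rates per-site elongation rates (length `L - 1`).
#' @param position `"start"`, `"middle"`, `"final"`, or a site index.
#' @param slow_rate the replacement rate in 1/s (e.g. 1, 0.1 or 0.01).
#' @return A copy of `rates` with one site replaced.
#' @export
with_slow_step <- function(rates, position, slow_rate) {
  n <- length(rates)
  idx <- if (is.character(position)) {
    switch(match.arg(position, c("start", "middle", "final")),
           start = 1L, middle = as.integer(ceiling(n / 2)), final = n)
  } else {
    as.integer(position)
  }
  if (idx < 1L || idx > n)
    stop(sprintf("position index %d outside elongation sites 1..%d", idx, n))
  if (!is.finite(slow_rate) || slow_rate <= 0) stop("slow_rate must be > 0")
  rates[idx] <- slow_rate
  rates
}
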