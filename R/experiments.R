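#' Log-log slope with a t-interval
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`; the 95% confidence
#' interval uses the t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y positive numeric vectors of equal length (>= 3 points).
#' @param conf confidence level (default 0.95).
#' @return List with `slope`, `ci` (length-2), `intercept`, `n`.
#' @export
loglog_slope <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points for a slope interval")
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be strictly positive")
  fit <- lm(log10(y) ~ log10(x))
  ci <- suppressWarnings(confint(fit, level = conf)[2, ])
  list(slope = unname(coef(fit)[2]), ci = unname(ci),
       intercept = unname(coef(fit)[1]), n = length(x))
}

resolve_level_policy <- function(policy, L) {
  # policy: list(level =, termination_total =) or list(length_dependent = TRUE, ...)
  tot <- if (!is.null(policy$termination_total)) policy$termination_total else 10
  lev <- if (isTRUE(policy$length_dependent)) length_dependent_level(L) else policy$level
  if (is.null(lev)) stop("level policy must supply `level` or `length_dependent = TRUE`")
  rates_from_level(lev, tot)
}

#' Reinitiation policy helper
#'
#' Bundles a reinitiation level (or the length-dependent rule) with the
#' total termination rate `r + beta` that fixes the absolute timescale.
#'
#' @param level reinitiation level in `[0, 1]`; ignored when
#'   `length_dependent = TRUE`.
#' @param termination_total total termination rate in 1/s (default 10).
#' @param length_dependent use [length_dependent_level()] per transcript.
#' @return A list understood by the experiment drivers.
#' @export
reinitiation_policy <- function(level = NULL, termination_total = 10,
                                length_dependent = FALSE) {
  if (!length_dependent) {
    if (is.null(level)) stop("supply `level` or set length_dependent = TRUE")
    if (level < 0 || level > 1) stop("level must be in [0, 1]")
  }
  if (termination_total <= 0) stop("termination_total must be > 0")
  list(level = level, termination_total = termination_total,
       length_dependent = length_dependent)
}

#' Sweep CDS length and summarize translation
#'
#' Simulates a set of transcript lengths under a common initiation rate,
#' lifetime and reinitiation policy, and estimates the log-log slope of
#' each read-out (density, effective initiation rate, yield) against
#' length.  Under perfect reinitiation with a collision-free initiation
#' rate the density slope is -1; with no reinitiation and a long lifetime
#' all slopes are about 0.
#'
#' @param lengths CDS lengths in codons (>= 3 for slopes).
#' @param level_policy a [reinitiation_policy()].
#' @param alpha de novo initiation rate in 1/s.
#' @param elong_rate uniform elongation rate in 1/s, or a function
#'   `function(L)` returning per-site rates of length `L - 1`.
#' @param lifetime transcript lifetime in s.
#' @param n_runs replicates per length.
#' @param seed integer root seed; length `k` uses stream `seed` with a
#'   distinct replicate offset via its own summary call.
#' @param footprint exclusion span in codons.
#' @return Object of class `"sweep_result"`: `$table` (one row per length)
#'   and `$slopes` (one row per measure, `NA` CI bounds when fewer than 3
#'   usable lengths).
#' @export
length_sweep <- function(lengths, level_policy, alpha, elong_rate = 10,
                         lifetime, n_runs = 1000L, seed, footprint = 10L) {
  lengths <- sort(as.integer(lengths))
  if (any(lengths <= footprint)) stop("all lengths must exceed the footprint")
  rows <- vector("list", length(lengths))
  for (k in seq_along(lengths)) {
    L <- lengths[k]
    rb <- resolve_level_policy(level_policy, L)
    er <- if (is.function(elong_rate)) elong_rate(L) else uniform_rates(L, elong_rate)
    spec <- transcript_spec(L = L, elong_rates = er, alpha = alpha,
                            reinit_rate = rb[["reinit_rate"]],
                            release_rate = rb[["release_rate"]],
                            lifetime = lifetime, footprint = footprint,
                            id = sprintf("L%d", L))
    sm <- simulate_translation(spec, n_runs = n_runs, seed = seed + k)
    rows[[k]] <- data.frame(L = L,
                            level = level_from_rates(rb[["reinit_rate"]],
                                                     rb[["release_rate"]]),
                            density = sm$density, se_density = sm$se_density,
                            eff_init_rate = sm$eff_init_rate,
                            se_eff_init_rate = sm$se_eff_init_rate,
                            yield = sm$yield, se_yield = sm$se_yield)
  }
  tab <- do.call(rbind, rows)
  slopes <- lapply(c(density = "density", eff_init_rate = "eff_init_rate",
                     yield = "yield"), function(m) {
    y <- tab[[m]]
    ok <- y > 0
    if (sum(ok) < 3)
      return(data.frame(measure = m, slope = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n = sum(ok)))
    sl <- loglog_slope(tab$L[ok], y[ok])
    data.frame(measure = m, slope = sl$slope, ci_lo = sl$ci[1],
               ci_hi = sl$ci[2], n = sl$n)
  })
  structure(list(table = tab, slopes = do.call(rbind, slopes)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Length sweep over %d lengths (%d-%d codons)\n",
              nrow(x$table), min(x$table$L), max(x$table$L)))
  print(x$table, row.names = FALSE, digits = 4)
  cat("log-log slopes vs CDS length (95% CI):\n")
  print(x$slopes, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Transcript-specific perturbation
#'
#' Scales one parameter of a single transcript species (its reinitiation
#' rate, de novo initiation rate, or all elongation rates) by `factor`, and
#' returns the read-outs of the altered transcript relative to the
#' unaltered one.  Paired root seeds are used for both arms, so
#' `factor = 1` returns ratios of exactly 1.
#'
#' @param spec the unaltered [transcript_spec()] (background parameters at
#'   their transcriptome-wide calibrated values).
#' @param which `"reinit_rate"`, `"alpha"`, or `"elong_all"`.
#' @param factor positive multiplier.
#' @param n_runs replicates per arm.
#' @param seed integer root seed shared by the paired arms.
#' @return Data frame with the ratio (altered / unaltered) of density,
#'   effective initiation rate and yield, plus both arms' values.
#' @export
perturb_transcript <- function(spec, which = c("reinit_rate", "alpha", "elong_all"),
                               factor, n_runs = 1000L, seed) {
  which <- match.arg(which)
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  altered <- spec
  if (which == "reinit_rate") altered$reinit_rate <- spec$reinit_rate * factor
  if (which == "alpha") altered$alpha <- spec$alpha * factor
  if (which == "elong_all") altered$elong_rates <- spec$elong_rates * factor
  base <- simulate_translation(spec, n_runs = n_runs, seed = seed)
  alt <- simulate_translation(altered, n_runs = n_runs, seed = seed)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  data.frame(which = which, factor = factor, L = spec$L,
             density_ratio = ratio(alt$density, base$density),
             eff_init_ratio = ratio(alt$eff_init_rate, base$eff_init_rate),
             yield_ratio = ratio(alt$yield, base$yield),
             density_base = base$density, density_alt = alt$density,
             eff_init_base = base$eff_init_rate, eff_init_alt = alt$eff_init_rate,
             yield_base = base$yield, yield_alt = alt$yield,
             se_yield_base = base$se_yield, se_yield_alt = alt$se_yield,
             se_eff_init_base = base$se_eff_init_rate,
             se_eff_init_alt = alt$se_eff_init_rate,
             se_density_base = base$se_density, se_density_alt = alt$se_density)
}

#' Single slow-codon scan
#'
#' Introduces one slow elongation step (at the start, middle or final
#' coding position) into otherwise uniform transcripts of several lengths
#' and reports each read-out relative to the unaltered transcript, with
#' paired seeds.
#'
#' @param lengths CDS lengths in codons.
#' @param positions subset of `c("start", "middle", "final")`.
#' @param slow_rates slow-step rates in 1/s (default `c(1, 0.1, 0.01)`).
#' @param level reinitiation level (default 0.999).
#' @param alpha de novo initiation rate in 1/s.
#' @param elong_rate background uniform elongation rate in 1/s.
#' @param lifetime transcript lifetime in s.
#' @param termination_total total termination rate in 1/s.
#' @param n_runs replicates per arm.
#' @param seed integer root seed.
#' @param footprint exclusion span in codons.
#' @return Data frame with one row per (length, position, slow rate):
#'   ratios of density, effective initiation rate and yield versus the
#'   unaltered transcript.
#' @export
slow_step_scan <- function(lengths, positions = c("start", "middle", "final"),
                           slow_rates = c(1, 0.1, 0.01), level = 0.999,
                           alpha, elong_rate = 10, lifetime,
                           termination_total = 10, n_runs = 1000L, seed,
                           footprint = 10L) {
  positions <- match.arg(positions, several.ok = TRUE)
  rb <- rates_from_level(level, termination_total)
  out <- list()
  for (L in sort(as.integer(lengths))) {
    base_rates <- uniform_rates(L, elong_rate)
    base_spec <- transcript_spec(L = L, elong_rates = base_rates, alpha = alpha,
                                 reinit_rate = rb[["reinit_rate"]],
                                 release_rate = rb[["release_rate"]],
                                 lifetime = lifetime, footprint = footprint,
                                 id = sprintf("L%d", L))
    base <- simulate_translation(base_spec, n_runs = n_runs, seed = seed)
    for (pos in positions) {
      for (sr in slow_rates) {
        alt_spec <- base_spec
        alt_spec$elong_rates <- with_slow_step(base_rates, pos, sr)
        alt <- simulate_translation(alt_spec, n_runs = n_runs, seed = seed)
        out[[length(out) + 1L]] <- data.frame(
          L = L, position = pos, slow_rate = sr,
          density_ratio = alt$density / base$density,
          eff_init_ratio = alt$eff_init_rate / base$eff_init_rate,
          yield_ratio = alt$yield / base$yield,
          yield_base = base$yield, yield_alt = alt$yield,
          se_yield_base = base$se_yield, se_yield_alt = alt$se_yield)
      }
    }
  }
  do.call(rbind, out)
}

#' Steady-state diagnostics
#'
#' Runs long simulations (lifetime set to `run_time`), samples the mean
#' instantaneous ribosome count across runs on a fixed time grid, and
#' reports (i) the steady-state density, averaged over the final `window`
#' seconds, (ii) whether the final window shows directional drift (in which
#' case the steady state was not attained), and (iii) the first-passage
#' time: the earliest grid time at which the across-run mean density equals
#' or exceeds the steady-state density.
#'
#' @param spec a [transcript_spec()]; its `lifetime` is replaced by
#'   `run_time`.
#' @param run_time total simulated time in s (default 3e5).
#' @param window averaging window for the steady-state density in s
#'   (default 1e4).
#' @param n_runs replicates (default 1000).
#' @param seed integer root seed.
#' @param grid_dt sampling-grid spacing in s (default 10).
#' @param drift_p p-value threshold for the drift (slope) test on the final
#'   window; smaller = stricter evidence required to flag drift.
#' @return List: `ss_density`, `first_passage` (s, `NA` if never attained),
#'   `attained` (logical: no directional drift over the final window),
#'   `drift_p_value`, and the sampled `series` (time, mean count, density).
#' @export
steady_state_diagnostics <- function(spec, run_time = 3e5, window = 1e4,
                                     n_runs = 1000L, seed, grid_dt = 10,
                                     drift_p = 0.01) {
  if (window >= run_time) stop("window must be smaller than run_time")
  s <- spec
  s$lifetime <- run_time
  grid <- seq(0, run_time, by = grid_dt)
  sm <- simulate_translation(s, n_runs = n_runs, seed = seed,
                             sample_times = grid)
  series <- sm$grid
  series$density <- series$mean_count / (spec$L / spec$footprint)
  in_window <- series$time >= run_time - window
  ss_density <- mean(series$density[in_window])
  # directional drift over the final window: OLS slope significantly nonzero
  attained <- TRUE
  drift_p_value <- NA_real_
  yw <- series$density[in_window]
  if (ss_density > 0 && length(unique(yw)) > 1) {
    fit <- lm(yw ~ series$time[in_window])
    drift_p_value <- summary(fit)$coefficients[2, 4]
    attained <- drift_p_value >= drift_p
  }
  first_passage <- if (ss_density == 0) 0 else {
    hit <- which(series$density >= ss_density)
    if (length(hit) == 0) NA_real_ else series$time[min(hit)]
  }
  if (!attained) first_passage <- NA_real_
  list(ss_density = ss_density, first_passage = first_passage,
       attained = attained, drift_p_value = drift_p_value, series = series)
}

#' Simulate a whole translatome
#'
#' One [simulate_translation()] per coding sequence, with codon-specific
#' elongation rates from a decoding-rate table and either a fixed lifetime
#' or per-transcript lifetimes.  When per-transcript lifetimes are supplied,
#' transcripts with lifetimes below `min_lifetime` (default 400 s) are
#' excluded and counted.  Each transcript's RNG stream is derived
#' deterministically from the root seed and its id, so results do not
#' depend on the order of records.  Per-record validation failures are
#' collected, not fatal.
#'
#' @param cds named character vector (or list) of CDS sequences, or a path
#'   to a FASTA file (read with [read_cds_fasta()]).
#' @param rate_table codon decoding-rate table (named numeric vector).
#' @param lifetime fixed lifetime in s (default 1553), or a named numeric
#'   vector of per-transcript lifetimes keyed by id.
#' @param level reinitiation level, or `NULL` with `length_dependent = TRUE`
#'   via `policy`.
#' @param policy optional [reinitiation_policy()] overriding `level`.
#' @param alpha de novo initiation rate in 1/s.
#' @param n_runs replicates per transcript.
#' @param seed integer root seed.
#' @param footprint exclusion span in codons.
#' @param min_lifetime exclusion threshold in s applied to per-transcript
#'   lifetimes.
#' @param require_stop require a terminal stop codon on every CDS.
#' @param chunk_size transcripts per checkpoint chunk.
#' @param checkpoint_dir optional directory; finished chunks are written
#'   there as TSV and reused on rerun.
#' @return List of class `"translatome_result"`: `$table` (one row per
#'   simulated transcript), `$excluded` (ids dropped by the lifetime rule),
#'   `$failures` (id + message for invalid records).
#' @export
translatome_run <- function(cds, rate_table, lifetime = 1553, level = 0.999,
                            policy = NULL, alpha, n_runs = 1000L, seed,
                            footprint = 10L, min_lifetime = 400,
                            require_stop = TRUE, chunk_size = 200L,
                            checkpoint_dir = NULL) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- read_cds_fasta(cds)
  cds <- unlist(as.list(cds))
  if (is.null(names(cds)) || any(names(cds) == ""))
    stop("all coding sequences must be named")
  if (anyDuplicated(names(cds))) stop("duplicate CDS ids")

  per_transcript_lifetime <- length(lifetime) > 1L || !is.null(names(lifetime))
  excluded <- character()
  if (per_transcript_lifetime) {
    missing_lt <- setdiff(names(cds), names(lifetime))
    if (length(missing_lt) > 0)
      stop(sprintf("no lifetime for id(s): %s",
                   paste(head(missing_lt, 5), collapse = ", ")))
    lt <- lifetime[names(cds)]
    excluded <- names(cds)[lt < min_lifetime]
    cds <- cds[!(names(cds) %in% excluded)]
  }

  if (is.null(policy)) policy <- reinitiation_policy(level = level)

  ids <- names(cds)
  failures <- list()
  rows <- list()
  chunks <- split(ids, ceiling(seq_along(ids) / chunk_size))
  for (ci in seq_along(chunks)) {
    chunk_ids <- chunks[[ci]]
    cp_file <- if (!is.null(checkpoint_dir))
      file.path(checkpoint_dir, sprintf("translatome_chunk_%04d.tsv", ci)) else NULL
    if (!is.null(cp_file) && file.exists(cp_file)) {
      rows[[ci]] <- read.delim(cp_file, stringsAsFactors = FALSE)
      next
    }
    chunk_rows <- list()
    for (id in chunk_ids) {
      row <- tryCatch({
        rates <- build_elongation_rates(cds[[id]], rate_table,
                                        require_stop = require_stop)
        L <- attr(rates, "L")
        rb <- resolve_level_policy(policy, L)
        this_lt <- if (per_transcript_lifetime) unname(lifetime[[id]]) else lifetime
        spec <- transcript_spec(L = L, elong_rates = as.numeric(rates),
                                alpha = alpha,
                                reinit_rate = rb[["reinit_rate"]],
                                release_rate = rb[["release_rate"]],
                                lifetime = this_lt, footprint = footprint,
                                id = id)
        sm <- simulate_translation(spec, n_runs = n_runs,
                                   seed = derive_seed(seed, id))
        as.data.frame(sm)
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- data.frame(id = id,
                                                         message = conditionMessage(e))
        NULL
      })
      if (!is.null(row)) chunk_rows[[length(chunk_rows) + 1L]] <- row
    }
    rows[[ci]] <- if (length(chunk_rows) > 0) do.call(rbind, chunk_rows) else NULL
    if (!is.null(cp_file) && !is.null(rows[[ci]])) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      write.table(rows[[ci]], cp_file, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
                 excluded = excluded,
                 failures = if (length(failures) > 0) do.call(rbind, failures)
                            else data.frame(id = character(), message = character())),
            class = "translatome_result")
}

#' @export
print.translatome_result <- function(x, ...) {
  cat(sprintf("Translatome run: %d transcripts simulated, %d excluded (short lifetime), %d failed\n",
              if (is.null(x$table)) 0L else nrow(x$table),
              length(x$excluded), nrow(x$failures)))
  invisible(x)
}

# Deterministic 31-bit stream seed from a root seed and a transcript id.
derive_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}
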