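#' Construct a lattice state
#'
#' The instantaneous configuration of a transcript: the strictly increasing
#' A-site positions, the elapsed time, the event counters and the running
#' time-integral of the ribosome count.
#'
#' @param a_sites integer vector of A-site positions (ascending).
#' @param t elapsed time in s.
#' @param de_novo,reinits,releases,completions event tallies.
#' @param occupancy_integral time-integral of the ribosome count (ribosome*s).
#' @return An object of class `"lattice_state"`.
#' @export
lattice_state <- function(a_sites = integer(), t = 0, de_novo = 0L,
                          reinits = 0L, releases = 0L, completions = 0L,
                          occupancy_integral = 0) {
  a_sites <- as.integer(a_sites)
  if (is.unsorted(a_sites, strictly = TRUE)) stop("a_sites must be strictly increasing")
  structure(list(a_sites = a_sites, t = t, de_novo = de_novo, reinits = reinits,
                 releases = releases, completions = completions,
                 occupancy_integral = occupancy_integral),
            class = "lattice_state")
}

#' Enumerate the enabled reaction channels of a configuration
#'
#' Applies the closed-loop TASEP rules: de novo initiation at rate `alpha`
#' iff no A-site lies in sites `1..footprint`; elongation of the ribosome at
#' site `i < L` at `elong_rates[i]` iff the next A-site downstream is more
#' than `footprint` sites away; and, when a ribosome occupies the
#' termination site `L`, release at the release rate always plus
#' reinitiation at the reinitiation rate iff the entry region is free.
#'
#' @param state a [lattice_state()] (a bare integer vector of A-sites is
#'   also accepted).
#' @param spec a [transcript_spec()].
#' @return A data frame with columns `reaction` (`"init"`, `"elong"`,
#'   `"release"`, `"reinit"`), `site` (the moving A-site, `NA` for init)
#'   and `rate`; zero rows when the state is frozen.
#' @export
enabled_reactions <- function(state, spec) {
  a <- if (inherits(state, "lattice_state")) state$a_sites else as.integer(state)
  L <- spec$L; fp <- spec$footprint
  entry_free <- length(a) == 0L || a[1] > fp
  out <- list()
  if (entry_free && spec$alpha > 0)
    out[[length(out) + 1L]] <- data.frame(reaction = "init", site = NA_integer_,
                                          rate = spec$alpha)
  n <- length(a)
  if (n > 0) {
    gap_ok <- c(if (n > 1) diff(a) > fp, TRUE)
    movable <- which(a < L & gap_ok)
    for (i in movable)
      out[[length(out) + 1L]] <- data.frame(reaction = "elong", site = a[i],
                                            rate = spec$elong_rates[a[i]])
    if (a[n] == L) {
      if (spec$release_rate > 0)
        out[[length(out) + 1L]] <- data.frame(reaction = "release", site = L,
                                              rate = spec$release_rate)
      if (entry_free && spec$reinit_rate > 0)
        out[[length(out) + 1L]] <- data.frame(reaction = "reinit", site = L,
                                              rate = spec$reinit_rate)
    }
  }
  if (length(out) == 0)
    return(data.frame(reaction = character(), site = integer(), rate = numeric()))
  do.call(rbind, out)
}

#' Advance a lattice state by one Gillespie event
#'
#' Reference implementation of the Monte Carlo step, drawing two uniforms
#' from R's RNG in the order (waiting time, channel): the waiting time is
#' `Exponential(total rate)` by inversion (`-log(u)/R`), and the channel is
#' chosen with probability proportional to its rate, walking the channels in
#' the order returned by [enabled_reactions()].
#'
#' @param state a [lattice_state()].
#' @param spec a [transcript_spec()].
#' @return List with elements `state` (the post-event [lattice_state()]),
#'   `dt` (the waiting time) and `reaction` (one row of the channel table).
#'   Errors with class `"riboloop_frozen"` when no channel is enabled.
#' @export
gillespie_step <- function(state, spec) {
  ch <- enabled_reactions(state, spec)
  total <- sum(ch$rate)
  if (nrow(ch) == 0 || total <= 0)
    stop(structure(class = c("riboloop_frozen", "error", "condition"),
                   list(message = "frozen state: no enabled reactions",
                        call = sys.call())))
  u <- runif(2)
  dt <- -log(u[1]) / total
  pick <- findInterval(u[2] * total, cumsum(ch$rate), left.open = TRUE) + 1L
  pick <- min(pick, nrow(ch))
  rx <- ch[pick, ]
  a <- state$a_sites
  n_pre <- length(a)
  de_novo <- state$de_novo; reinits <- state$reinits
  releases <- state$releases; completions <- state$completions
  if (rx$reaction == "init") {
    a <- c(1L, a); de_novo <- de_novo + 1L
  } else if (rx$reaction == "elong") {
    i <- match(rx$site, a)
    a[i] <- a[i] + 1L
    if (a[i] == spec$L) completions <- completions + 1L
  } else if (rx$reaction == "release") {
    a <- a[-length(a)]; releases <- releases + 1L
  } else {  # reinit: completion was counted on arrival at L, not here
    a <- c(1L, a[-length(a)]); reinits <- reinits + 1L
  }
  new_state <- lattice_state(a, t = state$t + dt, de_novo = de_novo,
                             reinits = reinits, releases = releases,
                             completions = completions,
                             occupancy_integral = state$occupancy_integral + n_pre * dt)
  list(state = new_state, dt = dt, reaction = rx)
}

trajectory_stats <- function(occupancy_integral, lifetime, de_novo, reinits,
                             releases, completions, final_n = NA_integer_,
                             terminal_occupied = NA) {
  structure(list(
    mean_ribosomes = if (lifetime > 0) occupancy_integral / lifetime else 0,
    occupancy_integral = occupancy_integral, lifetime = lifetime,
    de_novo = de_novo, reinits = reinits, releases = releases,
    completions = completions, final_n = final_n,
    terminal_occupied = terminal_occupied), class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf(paste0("Trajectory over %.4g s: mean ribosomes %.3f | de novo %d,",
                     " reinit %d, release %d, completions %d\n"),
              x$lifetime, x$mean_ribosomes, x$de_novo, x$reinits, x$releases,
              x$completions))
  invisible(x)
}

#' Simulate one transcript lifetime (compiled engine)
#'
#' Runs the Gillespie algorithm from an empty lattice at `t = 0` until the
#' next event would fall beyond the transcript lifetime; the final partial
#' interval still contributes to the occupancy integral.  Deterministic
#' given `(spec, seed, replicate)`: replicate `k` of [simulate_translation()]
#' with the same root seed reproduces `simulate_transcript(spec, seed, k)`
#' exactly.
#'
#' @param spec a [transcript_spec()].
#' @param seed integer root seed.
#' @param replicate replicate index (>= 1) selecting the RNG stream.
#' @return A `"trajectory_stats"` object: `mean_ribosomes` (time-averaged
#'   ribosome count), counts of de novo initiations, reinitiations,
#'   releases and completions (arrivals at the termination site), and the
#'   final occupancy.
#' @export
simulate_transcript <- function(spec, seed, replicate = 1L) {
  validate_transcript_spec(spec)
  res <- .cpp_simulate_batch(spec$L, spec$elong_rates, spec$alpha,
                             spec$reinit_rate, spec$release_rate,
                             spec$footprint, spec$lifetime,
                             1L, as.double(seed), as.integer(replicate),
                             numeric(), FALSE, FALSE)
  trajectory_stats(res$occupancy_integral[1], spec$lifetime,
                   as.integer(res$de_novo[1]), as.integer(res$reinits[1]),
                   as.integer(res$releases[1]), as.integer(res$completions[1]),
                   as.integer(res$final_n[1]), res$terminal_occupied[1])
}

#' Simulate one transcript lifetime (pure-R reference stepper)
#'
#' Same dynamics as [simulate_transcript()] but advanced event by event with
#' [gillespie_step()] using R's RNG.  Used for auditing and cross-checks;
#' orders of magnitude slower than the compiled engine.
#'
#' @param spec a [transcript_spec()].
#' @param seed integer seed passed to [set.seed()].
#' @param check_invariants assert A-site spacing and counter bookkeeping
#'   after every event.
#' @return A `"trajectory_stats"` object.
#' @export
simulate_transcript_r <- function(spec, seed, check_invariants = FALSE) {
  validate_transcript_spec(spec)
  set.seed(seed)
  st <- lattice_state()
  lt <- spec$lifetime
  repeat {
    step <- tryCatch(gillespie_step(st, spec), riboloop_frozen = function(e) NULL)
    if (is.null(step)) break                      # frozen: jump to end of life
    if (step$state$t > lt) break                  # event past end of life: discard
    st_new <- step$state
    if (check_invariants) {
      a <- st_new$a_sites
      if (length(a) > 1 && any(diff(a) < spec$footprint))
        stop("spacing invariant violated")
      if (st_new$de_novo != st_new$releases + length(a))
        stop("conservation bookkeeping violated")
      arrived_at_L <- as.integer(length(a) > 0 && a[length(a)] == spec$L)
      if (st_new$completions != st_new$releases + st_new$reinits + arrived_at_L)
        stop("completion bookkeeping violated")
    }
    st <- st_new
  }
  occ <- st$occupancy_integral + length(st$a_sites) * (lt - st$t)
  trajectory_stats(occ, lt, st$de_novo, st$reinits, st$releases, st$completions,
                   length(st$a_sites),
                   length(st$a_sites) > 0 &&
                     st$a_sites[length(st$a_sites)] == spec$L)
}

#' Simulate many independent lifetimes and summarize translation
#'
#' Averages the three read-outs over `n_runs` independent replicates:
#' ribosome density (lifetime-averaged ribosome count divided by the maximum
#' packing `L / footprint`), effective initiation rate (de novo initiations
#' plus reinitiations per second of lifetime) and protein yield (ribosomes
#' reaching the termination site per lifetime), each with its standard
#' error.  Replicate `k` uses an RNG stream derived from `(seed, k)`, so the
#' summary is reproducible and replicates are independent.
#'
#' @param spec a [transcript_spec()].
#' @param n_runs number of replicates (default 1000).
#' @param seed integer root seed.
#' @param sample_times optional ascending time grid; when supplied the mean
#'   instantaneous ribosome count across runs is returned at those times
#'   (component `grid`).
#' @return An object of class `"translation_summary"`.
#' @examples
#' spec <- transcript_spec(L = 40, elong_rates = 10, alpha = 0.05,
#'                         reinit_rate = 5, release_rate = 5, lifetime = 200,
#'                         footprint = 10)
#' simulate_translation(spec, n_runs = 50, seed = 1)
#' @export
simulate_translation <- function(spec, n_runs = 1000L, seed, sample_times = NULL) {
  validate_transcript_spec(spec)
  if (n_runs < 1) stop("n_runs must be >= 1")
  res <- .cpp_simulate_batch(spec$L, spec$elong_rates, spec$alpha,
                             spec$reinit_rate, spec$release_rate,
                             spec$footprint, spec$lifetime,
                             as.integer(n_runs), as.double(seed), 1L,
                             if (is.null(sample_times)) numeric() else as.double(sample_times),
                             FALSE, FALSE)
  mean_rib <- if (spec$lifetime > 0) res$occupancy_integral / spec$lifetime else
    rep(0, n_runs)
  max_pack <- spec$L / spec$footprint
  dens <- mean_rib / max_pack
  eff_init <- if (spec$lifetime > 0) (res$de_novo + res$reinits) / spec$lifetime else
    rep(0, n_runs)
  yield <- res$completions
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  out <- structure(list(
    id = spec$id, L = spec$L, footprint = spec$footprint,
    lifetime = spec$lifetime, n_runs = as.integer(n_runs), seed = seed,
    mean_ribosomes = mean(mean_rib), se_mean_ribosomes = se(mean_rib),
    density = mean(dens), se_density = se(dens),
    eff_init_rate = mean(eff_init), se_eff_init_rate = se(eff_init),
    yield = mean(yield), se_yield = se(yield),
    de_novo = mean(res$de_novo), reinits = mean(res$reinits),
    releases = mean(res$releases),
    runs = data.frame(mean_ribosomes = mean_rib, density = dens,
                      eff_init_rate = eff_init, yield = yield,
                      de_novo = res$de_novo, reinits = res$reinits,
                      releases = res$releases, final_n = res$final_n,
                      terminal_occupied = res$terminal_occupied)),
    class = "translation_summary")
  if (!is.null(sample_times))
    out$grid <- data.frame(time = as.double(sample_times),
                           mean_count = res$grid_count_sum / n_runs)
  out
}

#' @export
print.translation_summary <- function(x, ...) {
  cat(sprintf("Translation summary for '%s' (%d codons, %d runs, lifetime %.4g s)\n",
              x$id, x$L, x$n_runs, x$lifetime))
  cat(sprintf("  ribosome density:     %.4g (SE %.2g)  [mean count %.3f]\n",
              x$density, x$se_density, x$mean_ribosomes))
  cat(sprintf("  eff. initiation rate: %.4g /s (SE %.2g)\n",
              x$eff_init_rate, x$se_eff_init_rate))
  cat(sprintf("  protein yield:        %.4g (SE %.2g)\n", x$yield, x$se_yield))
  invisible(x)
}

#' @export
as.data.frame.translation_summary <- function(x, ...) {
  data.frame(id = x$id, L = x$L, lifetime = x$lifetime, n_runs = x$n_runs,
             mean_ribosomes = x$mean_ribosomes,
             density = x$density, se_density = x$se_density,
             eff_init_rate = x$eff_init_rate, se_eff_init_rate = x$se_eff_init_rate,
             yield = x$yield, se_yield = x$se_yield)
}

#' Pioneer-round traversal times
#'
#' Places a single ribosome at site 1 of an empty lattice, disables further
#' initiation, and simulates until its A-site reaches the termination site.
#' The expected traversal time is the sum of the reciprocal elongation rates
#' (about 400 s for 4000 codons at a uniform 10/s).
#'
#' @param spec a [transcript_spec()]; `alpha` and the termination rates are
#'   ignored for the traversal itself.
#' @param n_runs number of independent traversals.
#' @param seed integer root seed.
#' @return List with `mean_time`, `se_time` and the per-run `times` (s).
#' @export
pioneer_traversal <- function(spec, n_runs = 1000L, seed) {
  validate_transcript_spec(spec)
  res <- .cpp_simulate_batch(spec$L, spec$elong_rates, 0.0, 0.0, 1.0,
                             spec$footprint, Inf, as.integer(n_runs),
                             as.double(seed), 1L, numeric(), TRUE, TRUE)
  times <- res$first_arrival
  list(mean_time = mean(times),
       se_time = sd(times) / sqrt(length(times)),
       times = times)
}
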