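test_that("enabled_reactions applies the exclusion and entry rules", {
  spec <- transcript_spec(L = 30, elong_rates = 10, alpha = 0.1,
                          reinit_rate = 4, release_rate = 1, lifetime = 10,
                          footprint = 10)
  # empty lattice: only de novo initiation
  ch <- enabled_reactions(lattice_state(), spec)
  expect_identical(ch$reaction, "init")
  expect_identical(ch$rate, 0.1)

  # A-sites {1, 11}: gap exactly 10 blocks the trailing ribosome (needs > 10),
  # the entry region is occupied, so only the ribosome at 11 can step
  ch <- enabled_reactions(lattice_state(c(1L, 11L)), spec)
  expect_identical(ch$reaction, "elong")
  expect_identical(ch$site, 11L)
  expect_identical(ch$rate, 10)

  # single ribosome at the termination site: initiation, release, reinitiation
  ch <- enabled_reactions(lattice_state(30L), spec)
  expect_setequal(ch$reaction, c("init", "release", "reinit"))
  expect_equal(ch$rate[match(c("init", "release", "reinit"), ch$reaction)],
               c(0.1, 1, 4))

  # entry region occupied: reinitiation disabled, release stays active
  ch <- enabled_reactions(lattice_state(c(5L, 30L)), spec)
  expect_setequal(ch$reaction, c("elong", "release"))
})

test_that("gillespie_step samples the waiting time by inversion", {
  spec <- transcript_spec(L = 30, elong_rates = 10, alpha = 2,
                          reinit_rate = 4, release_rate = 1, lifetime = 10,
                          footprint = 10)
  # empty lattice: single channel (init) with rate 2
  set.seed(42)
  u <- runif(2)
  set.seed(42)
  step <- gillespie_step(lattice_state(), spec)
  expect_equal(step$dt, -log(u[1]) / 2)
  expect_identical(step$reaction$reaction, "init")
  expect_identical(step$state$a_sites, 1L)
  expect_identical(step$state$de_novo, 1L)
})

test_that("gillespie_step errors on a frozen state", {
  spec <- transcript_spec(L = 30, elong_rates = 10, alpha = 0,
                          reinit_rate = 4, release_rate = 1, lifetime = 10,
                          footprint = 10)
  expect_error(gillespie_step(lattice_state(), spec),
               class = "riboloop_frozen")
})

test_that("reinitiation keeps completions fixed and moves the A-site to 1", {
  spec <- transcript_spec(L = 30, elong_rates = 10, alpha = 0,
                          reinit_rate = 100, release_rate = 1e-9, lifetime = 10,
                          footprint = 10)
  st <- lattice_state(c(15L, 30L), completions = 2L)
  # with reinit rate >> everything else the next event is almost surely reinit
  set.seed(7)
  step <- gillespie_step(st, spec)
  expect_identical(step$reaction$reaction, "reinit")
  expect_identical(step$state$a_sites, c(1L, 15L))
  expect_identical(step$state$reinits, 1L)
  expect_identical(step$state$completions, 2L)  # counted at arrival, not exit
})

test_that("terminal channel frequencies follow the rate ratio", {
  # a single recirculating ribosome choosing reinit:release = 4:1 at the stop
  # codon; alpha is tiny so a second ribosome essentially never blocks the
  # entry region (which would disable reinitiation and bias the ratio)
  spec <- transcript_spec(L = 11, elong_rates = 50, alpha = 0.001,
                          reinit_rate = 4, release_rate = 1, lifetime = 3000,
                          footprint = 10)
  sm <- simulate_translation(spec, n_runs = 400, seed = 3)
  n_exit <- sum(sm$runs$reinits) + sum(sm$runs$releases)
  p_hat <- sum(sm$runs$reinits) / n_exit
  expect_gt(n_exit, 2000)
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / n_exit))
})

test_that("counters satisfy conservation and completion bookkeeping", {
  set.seed(99)
  for (i in 1:25) {
    spec <- transcript_spec(
      L = sample(11:40, 1), elong_rates = runif(1, 1, 20),
      alpha = runif(1, 0, 1), reinit_rate = runif(1, 0, 5),
      release_rate = runif(1, 0.1, 5), lifetime = runif(1, 1, 60),
      footprint = sample(3:10, 1))
    if (spec$L <= spec$footprint) next
    tr <- simulate_transcript(spec, seed = i)
    expect_identical(tr$de_novo, tr$releases + tr$final_n)
    expect_identical(tr$completions,
                     tr$releases + tr$reinits + as.integer(tr$terminal_occupied))
    expect_gte(tr$mean_ribosomes, 0)
  }
})

test_that("the pure-R stepper maintains spacing and bookkeeping every event", {
  spec <- tiny_spec(alpha = 0.5, lifetime = 40)
  # check_invariants = TRUE asserts spacing >= footprint and the counter
  # identities after every single event
  for (s in 1:5) {
    tr <- simulate_transcript_r(spec, seed = s, check_invariants = TRUE)
    expect_gte(tr$mean_ribosomes, 0)
  }
})

test_that("compiled engine and R reference stepper agree in distribution", {
  spec <- tiny_spec(alpha = 0.4, lifetime = 40)
  sm <- simulate_translation(spec, n_runs = 2000, seed = 5)
  r_runs <- vapply(1:150, function(s)
    simulate_transcript_r(spec, seed = s)$mean_ribosomes, numeric(1))
  se <- sqrt(sd(r_runs)^2 / 150 + sm$se_mean_ribosomes^2)
  expect_lt(abs(mean(r_runs) - sm$mean_ribosomes), 3 * se)
})

test_that("zero lifetime and zero initiation give empty trajectories", {
  spec0 <- tiny_spec(alpha = 0, reinit_rate = 0, release_rate = 1)
  tr <- simulate_transcript(spec0, seed = 1)
  expect_identical(tr$completions, 0L)
  expect_identical(tr$mean_ribosomes, 0)

  spec_lt0 <- tiny_spec(lifetime = 0)
  tr2 <- simulate_transcript(spec_lt0, seed = 1)
  expect_identical(tr2$mean_ribosomes, 0)
  expect_identical(tr2$de_novo, 0L)
})

test_that("summaries are bit-identical for identical (spec, seed, n_runs)", {
  spec <- tiny_spec()
  a <- simulate_translation(spec, n_runs = 200, seed = 123)
  b <- simulate_translation(spec, n_runs = 200, seed = 123)
  expect_identical(a$runs, b$runs)
  expect_identical(a$density, b$density)
  c_ <- simulate_translation(spec, n_runs = 200, seed = 124)
  expect_false(identical(a$density, c_$density))
})

test_that("replicate k of a summary reproduces simulate_transcript(spec, seed, k)", {
  spec <- tiny_spec()
  sm <- simulate_translation(spec, n_runs = 10, seed = 77)
  for (k in c(1L, 4L, 10L)) {
    tr <- simulate_transcript(spec, seed = 77, replicate = k)
    expect_identical(sm$runs$mean_ribosomes[k], tr$mean_ribosomes)
    expect_identical(sm$runs$yield[k], as.numeric(tr$completions))
  }
})

test_that("single-ribosome traversal time matches the sum of inverse rates", {
  set.seed(11)
  rates <- runif(49, 2, 20)
  spec <- transcript_spec(L = 50, elong_rates = rates, alpha = 0,
                          reinit_rate = 0, release_rate = 1, lifetime = 1,
                          footprint = 10)
  pt <- pioneer_traversal(spec, n_runs = 1000, seed = 21)
  expect_within_3se(pt$mean_time, pt$se_time, sum(1 / rates))
})

test_that("with no reinitiation the process reduces to the linear TASEP", {
  # yield equals releases when no ribosome can recirculate
  spec <- level_spec(L = 30, level = 0, alpha = 0.3, lifetime = 100)
  sm <- simulate_translation(spec, n_runs = 300, seed = 9)
  expect_identical(sum(sm$runs$reinits), 0)
  expect_equal(sm$runs$yield,
               sm$runs$releases + as.numeric(sm$runs$terminal_occupied))
})
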