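test_that("loglog_slope recovers exact power laws", {
  x <- c(1, 2, 4, 8, 16)
  sl <- loglog_slope(x, 1 / x)
  expect_equal(sl$slope, -1)
  expect_equal(unname(diff(sl$ci)), 0, tolerance = 1e-10)
  sl0 <- loglog_slope(x, rep(3.5, 5))
  expect_equal(sl0$slope, 0)
  expect_error(loglog_slope(x[1:2], x[1:2]), "at least 3 points")
  expect_error(loglog_slope(x, c(-1, 1, 1, 1, 1)), "strictly positive")
})

test_that("loglog_slope confidence intervals have near-nominal coverage", {
  set.seed(123)
  x <- exp(seq(log(1), log(100), length.out = 20))
  hits <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    y <- 2 * x^2.5 * exp(rnorm(20, sd = 0.01))
    sl <- loglog_slope(x, y)
    if (sl$ci[1] <= 2.5 && 2.5 <= sl$ci[2]) hits <- hits + 1L
  }
  # 95% nominal; 3-sigma binomial band around 0.95 at 300 reps is ~0.04
  expect_gt(hits / n_rep, 0.91)
})

test_that("length_sweep returns one row per length and flags short sweeps", {
  sw <- length_sweep(c(20, 40, 80), reinitiation_policy(0.5), alpha = 0.1,
                     elong_rate = 10, lifetime = 60, n_runs = 50, seed = 1)
  expect_s3_class(sw, "sweep_result")
  expect_identical(sw$table$L, c(20L, 40L, 80L))
  expect_identical(nrow(sw$slopes), 3L)
  # single usable length: slope undefined
  sw1 <- length_sweep(c(20, 40), reinitiation_policy(0.5), alpha = 0.1,
                      elong_rate = 10, lifetime = 60, n_runs = 30, seed = 1)
  expect_true(all(is.na(sw1$slopes$slope)))
})

test_that("length-dependent level policy resolves per transcript", {
  sw <- length_sweep(c(400, 2000), reinitiation_policy(length_dependent = TRUE),
                     alpha = 0.05, elong_rate = 10, lifetime = 30,
                     n_runs = 20, seed = 2)
  expect_equal(sw$table$level, c(0.9, 0.5))
})

test_that("perturbation with factor 1 returns ratios of exactly 1", {
  spec <- level_spec(L = 40, level = 0.9, alpha = 0.05, lifetime = 80)
  for (w in c("reinit_rate", "alpha", "elong_all")) {
    pr <- perturb_transcript(spec, w, factor = 1, n_runs = 40, seed = 4)
    expect_identical(pr$density_ratio, 1)
    expect_identical(pr$eff_init_ratio, 1)
    expect_identical(pr$yield_ratio, 1)
  }
})

test_that("scaling the reinit rate at level 0 changes nothing", {
  spec <- level_spec(L = 40, level = 0, alpha = 0.05, lifetime = 80)
  pr <- perturb_transcript(spec, "reinit_rate", factor = 2, n_runs = 40,
                           seed = 4)
  expect_identical(pr$density_ratio, 1)
  expect_identical(pr$yield_ratio, 1)
})

test_that("without reinitiation, faster elongation leaves yield unchanged", {
  # elongation is not limiting under slow initiation, so doubling it mostly
  # shortens transit (lower density) without adding completions
  spec <- level_spec(L = 100, level = 0, alpha = 0.02, lifetime = 2000)
  pr <- perturb_transcript(spec, "elong_all", factor = 2, n_runs = 300,
                           seed = 14)
  se_ratio <- pr$yield_ratio *
    sqrt((pr$se_yield_alt / pr$yield_alt)^2 +
         (pr$se_yield_base / pr$yield_base)^2)
  expect_lt(abs(pr$yield_ratio - 1), 3 * se_ratio + 0.02)
  expect_lt(pr$density_ratio, 1)  # less time on board per ribosome
})

test_that("slow_step_scan at the background rate is the identity", {
  sc <- slow_step_scan(lengths = 40, positions = "start", slow_rates = 10,
                       level = 0.9, alpha = 0.05, lifetime = 60,
                       n_runs = 30, seed = 6)
  expect_identical(sc$density_ratio, 1)
  expect_identical(sc$yield_ratio, 1)
})

test_that("steady-state diagnostics handle the trivial and drifting cases", {
  # alpha = 0: empty forever
  spec0 <- level_spec(L = 30, level = 0.5, alpha = 0, lifetime = 1)
  ss0 <- steady_state_diagnostics(spec0, run_time = 100, window = 50,
                                  n_runs = 20, seed = 1, grid_dt = 5)
  expect_equal(ss0$ss_density, 0)
  expect_equal(ss0$first_passage, 0)

  # no reinitiation, brisk initiation: stationary well before the window,
  # first passage on the order of the pioneer round
  spec <- level_spec(L = 30, level = 0, alpha = 0.5, lifetime = 1)
  ss <- steady_state_diagnostics(spec, run_time = 2000, window = 500,
                                 n_runs = 200, seed = 2, grid_dt = 5)
  expect_true(ss$attained)
  expect_gt(ss$ss_density, 0)
  expect_lt(ss$first_passage, 300)

  # perfect reinitiation keeps accumulating ribosomes: directional drift
  # over the final window, so the steady state is flagged as not attained
  spec_d <- level_spec(L = 200, level = 1, alpha = 0.2, lifetime = 1)
  ss_d <- steady_state_diagnostics(spec_d, run_time = 60, window = 40,
                                   n_runs = 150, seed = 3, grid_dt = 2)
  expect_false(ss_d$attained)
  expect_true(is.na(ss_d$first_passage))
})

test_that("translatome runs are deterministic and order-independent", {
  tab <- synthetic_rate_table()
  seqs <- make_transcriptome(6, c(20, 40), seed = 42)
  tr1 <- translatome_run(seqs, tab, lifetime = 100, level = 0.9, alpha = 0.05,
                         n_runs = 20, seed = 9)
  expect_identical(nrow(tr1$table), 6L)
  tr2 <- translatome_run(seqs, tab, lifetime = 100, level = 0.9, alpha = 0.05,
                         n_runs = 20, seed = 9)
  expect_identical(tr1$table, tr2$table)
  # permuting the input order leaves each transcript's result unchanged
  tr3 <- translatome_run(rev(seqs), tab, lifetime = 100, level = 0.9,
                         alpha = 0.05, n_runs = 20, seed = 9)
  reord <- tr3$table[match(tr1$table$id, tr3$table$id), ]
  rownames(reord) <- NULL
  t1 <- tr1$table
  rownames(t1) <- NULL
  expect_identical(t1, reord)
})

test_that("identical coding sequences give exchangeable summaries", {
  tab <- synthetic_rate_table()
  cds <- make_transcriptome(1, c(30, 30), seed = 5)[[1]]
  seqs <- c(gene_a = cds, gene_b = cds)
  tr <- translatome_run(seqs, tab, lifetime = 150, level = 0.9, alpha = 0.05,
                        n_runs = 150, seed = 10)
  a <- tr$table[tr$table$id == "gene_a", ]
  b <- tr$table[tr$table$id == "gene_b", ]
  expect_within_3se(a$yield, sqrt(a$se_yield^2 + b$se_yield^2), b$yield)
  expect_within_3se(a$density, sqrt(a$se_density^2 + b$se_density^2), b$density)
})

test_that("short-lifetime transcripts are excluded and failures are collected", {
  tab <- synthetic_rate_table()
  seqs <- make_transcriptome(3, c(20, 30), seed = 7)
  lifetimes <- setNames(c(1000, 300, 800), names(seqs))
  tr <- translatome_run(seqs, tab, lifetime = lifetimes, level = 0.9,
                        alpha = 0.05, n_runs = 10, seed = 3)
  expect_identical(tr$excluded, names(seqs)[2])
  expect_identical(nrow(tr$table), 2L)

  # a record with an internal stop is reported as a failure, run continues
  seqs_bad <- seqs
  seqs_bad[[1]] <- paste0("ATG", "TAA", substring(seqs_bad[[1]], 7))
  tr2 <- translatome_run(seqs_bad, tab, lifetime = 1000, level = 0.9,
                         alpha = 0.05, n_runs = 10, seed = 3)
  expect_identical(nrow(tr2$table), 2L)
  expect_identical(tr2$failures$id, names(seqs)[1])
  expect_match(tr2$failures$message, "internal stop")
})
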