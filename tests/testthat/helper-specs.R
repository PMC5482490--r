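# small builders shared across tests

tiny_spec <- function(alpha = 0.3, reinit_rate = 4, release_rate = 1,
                      lifetime = 50, L = 12L, footprint = 3L, elong = 10) {
  transcript_spec(L = L, elong_rates = elong, alpha = alpha,
                  reinit_rate = reinit_rate, release_rate = release_rate,
                  lifetime = lifetime, footprint = footprint, id = "tiny")
}

level_spec <- function(L, level, alpha, lifetime, elong = 10, footprint = 10L,
                       termination_total = 10, id = "spec") {
  rb <- rates_from_level(level, termination_total)
  transcript_spec(L = L, elong_rates = elong, alpha = alpha,
                  reinit_rate = rb[["reinit_rate"]],
                  release_rate = rb[["release_rate"]],
                  lifetime = lifetime, footprint = footprint, id = id)
}

# 3-sigma Monte-Carlo band check
expect_within_3se <- function(est, se, truth) {
  expect_lt(abs(est - truth), 3 * se + 1e-12)
}
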