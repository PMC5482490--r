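---
title: "Closed-loop translation as a finite-lifetime TASEP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop translation as a finite-lifetime TASEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboloop)
```

## The model

`riboloop` simulates translation of a single mRNA as a totally asymmetric
simple exclusion process (TASEP) with extended particles on a lattice of
$L$ sites, one site per codon, with site $L$ the termination site (the stop
codon).  Ribosomes are tracked by the position of their A-site, and two
A-sites must always be at least one footprint apart (default 10 codons, the
physical span of a ribosome).  Four reactions drive the dynamics:

* **de novo initiation** at rate $\alpha$ places an A-site at site 1,
  enabled only while no A-site occupies sites $1..10$ (the entry region);
* **elongation** moves the A-site at site $i < L$ to $i+1$ at the per-site
  rate $k_i$, enabled only while the next A-site downstream is more than a
  footprint away;
* **release** removes the ribosome at site $L$ at rate $\beta$;
* **reinitiation** moves the ribosome at site $L$ directly back to site 1
  at rate $r$ — the closed-loop channel created by mRNA circularization.
  While the entry region is occupied, reinitiation is disabled but release
  stays active: the terminating ribosome waits or leaves.

The *reinitiation level* $p = r/(r+\beta)$ is the probability that a
terminating ribosome recirculates rather than returns to the cytoplasmic
pool.  Scaling the reinitiation rate by a factor $f$ with $\beta$ fixed
moves the level to $f p/(f p + 1 - p)$ (`scale_reinitiation_level()`).

Crucially, nothing is assumed about the steady state.  Each simulation
starts from an empty lattice and covers the whole finite lifetime $T$ of
the transcript, so the pioneer round, the acceleration of initiation as
ribosomes start to recirculate, and any eventual stationary phase all
contribute in their natural proportions.  Under strong reinitiation the
time to stationarity can exceed biological lifetimes by orders of
magnitude, which is exactly why the transient matters.

Three read-outs summarize each transcript (`simulate_translation()`):

* **ribosome density** — the lifetime-averaged ribosome count divided by
  the maximum packing $L/10$;
* **effective initiation rate** — de novo initiations plus reinitiations
  per second of lifetime;
* **protein yield** — the number of ribosomes reaching the termination
  site during the lifetime.

## Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `footprint` | A-site exclusion span (codons) | 10 | ribosome footprint; parameterized so exact small-lattice oracles are possible |
| `elong_rates` | per-site decoding rates (1/s) | uniform 10 | transcriptome-average decoding rate |
| `alpha` | de novo initiation rate (1/s) | calibrated | set by `calibrate_alpha()` so a 400-codon transcript carries 6 ribosomes, keeping ribosome usage comparable across reinitiation levels |
| `termination_total` | $r + \beta$ (1/s) | 10 | only the ratio $p$ is biologically constrained; choosing the transcriptome-average elongation rate makes termination non-limiting, so results are governed by $p$, not by an arbitrary termination timescale |
| `lifetime` | transcript lifetime (s) | 1553 | a representative average mRNA lifetime in budding yeast |
| `level` | reinitiation level | experiment-specific | the central unknown being explored (0–100%) |

The absolute magnitudes of $r$ and $\beta$ are genuinely unidentified by
the level alone; `termination_total` is therefore exposed everywhere and
recorded in every CLI manifest.  A length-dependent alternative to a fixed
level, $p(L) = \max(0, 1 - L/4000)$, is available as
`length_dependent_level()` / `reinitiation_policy(length_dependent = TRUE)`.

## The stochastic engine

Simulation is an exact Gillespie algorithm: at each step the enabled
channels and their total rate $R$ are enumerated, the waiting time is drawn
as $-\log(u_1)/R$, and the channel is chosen by walking the cumulative
rates with $u_2 R$ — two draws per event, in that order, with the channel
order fixed as (initiation, elongation 5′→3′, release, reinitiation).  An
event whose sampled time falls beyond the lifetime is discarded and the
occupancy integral is closed at exactly $t = T$.  A frozen configuration
(total rate zero, possible only with zero rates) jumps straight to the end
of life.  Completions are counted when an A-site *arrives* at site $L$, so
each reinitiation cycle contributes exactly one completion and the identity
`completions = releases + reinits + [terminal site occupied]` holds at all
times, as does conservation `de_novo = releases + ribosomes on board`.

Replicate $k$ of a summary uses an independent xoshiro256++ stream seeded
by `splitmix64(splitmix64(seed) XOR k·golden_ratio)`, making every run
reproducible and individually addressable (`simulate_transcript(spec,
seed, k)` reproduces replicate $k$ exactly).  The same rules are
implemented twice: once in compiled code for throughput and once as a
pure-R stepper (`gillespie_step()`, `simulate_transcript_r()`) that the
test suite uses for auditing — the two agree in distribution, and both
agree with an exact oracle (below).

## Calibration

Changing the reinitiation level changes global ribosome usage, so
comparisons across levels are made at a fixed ribosome load:
`calibrate_alpha()` finds the $\alpha$ at which the lifetime-averaged
ribosome count on a 400-codon reference transcript equals 6.  The count is
monotone in $\alpha$, so the search is bisection on $\log_{10}\alpha$ over
a bracket of $[10^{-6}, 10^{2}]$ 1/s (expanded on demand), with every
evaluation reusing the same root seed (common random numbers) so the
count–$\alpha$ curve is smooth and the bisection cannot stall on
Monte-Carlo noise.  The default tolerance of 0.05 ribosomes at 1000 runs
sits comfortably above the standard error of the mean count.  An
unreachable target (e.g. a lifetime too short to ever hold 6 ribosomes)
raises an explicit error with the achieved bound.

## Experiments

* `length_sweep()` simulates a length grid under a common $\alpha$,
  lifetime and level policy, and fits $\log_{10}$–$\log_{10}$ slopes of
  each read-out against CDS length by ordinary least squares with
  $t$-based 95% intervals ($n-2$ df); the CI method is a package choice.
  Under perfect reinitiation with a collision-free $\alpha$ the expected
  density slope is $-1$ (all transcripts of a given age carry the same
  ribosome count); without reinitiation and with lifetimes long relative
  to the pioneer round, length dependence vanishes.
* `perturb_transcript()` scales one parameter of a single transcript
  species (reinitiation rate, $\alpha$, or all elongation rates) and
  reports each read-out relative to the unaltered transcript with paired
  root seeds, so a factor of 1 returns exactly 1.
* `slow_step_scan()` plants a single slow codon (1, 0.1 or 0.01 1/s) at
  the start, middle ($\lceil (L-1)/2 \rceil$ among coding sites — an
  unambiguous choice for even $L$) or final coding position.
* `steady_state_diagnostics()` runs long simulations (default
  $3\times10^5$ s), samples the across-run mean ribosome count on a fixed
  grid (default 10 s — a common grid is needed because event times differ
  across runs; event-resolution interpolation would change nothing
  detectable at this grid), averages the final $10^4$ s into a
  steady-state density, checks the final window for directional drift
  (OLS slope test; drift means "steady state not attained"), and reports
  the first grid time at which the mean density reaches the steady-state
  value.
* `translatome_run()` maps `simulate_translation()` over a FASTA of coding
  sequences with codon-specific rates, a fixed or per-transcript lifetime
  table (transcripts below 400 s are excluded and counted when
  per-transcript lifetimes are used), per-id derived seeds (so results are
  independent of record order), chunked checkpointing, and non-fatal
  per-record validation.

The default length grid is 13 log-spaced points in [100, 4000] codons,
matching the range over which length dependence is biologically
interesting.

## The exact oracle

`exact_ctmc_summary()` enumerates every admissible configuration of a
small lattice (sets of A-sites with spacing ≥ footprint; the count is
capped at ~2000 states), builds the exact transition structure from the
same `enabled_reactions()` rule table, and integrates the master equation
from the empty state, augmented with three expected counting functionals
(occupancy integral, completions, initiations).  The augmented system is
linear, so it is solved two independent ways: stiff ODE integration
(`lsoda`, rtol $10^{-8}$/atol $10^{-10}$ — integration rather than a
matrix exponential avoids stiffness trouble at extreme rate ratios such
as 0.01 vs 10 1/s) and a matrix exponential of the augmented generator.
The two routes agree to better than $10^{-6}$ relative error, an
independently hand-derived 4-state chain is reproduced to the same
precision, and Gillespie summaries at $10^4$ runs match the oracle within
3 Monte-Carlo standard errors on lattices such as $L=12$, footprint 3.

## Synthetic data

Because the empirical decoding-rate table and transcript annotations are
not shipped, `synthetic_rate_table()` and `make_transcriptome()` generate
stand-ins: 61 sense-codon rates drawn lognormally (spanning roughly
0.5–40 1/s, the realistic spread of codon decoding speeds) and rescaled to
a mean of exactly 10 1/s, and random CDSs with a fixed ATG start, uniform
sense-codon bodies, no internal stops and a random stop codon.  A packaged
copy of the table ships in `inst/extdata/codon_rates_synthetic.tsv`
(synthetic, as the name says).  What these fixtures deliberately do not
emulate: real codon-usage bias and its covariation with expression level,
amino-acid composition, length–codon-adaptation correlations, UTRs, or
secondary-structure effects.  Tests passing on these fixtures therefore
validate the *machinery* (rules, counting, calibration, slopes), not any
claim about real transcriptomes.

## Scope and limitations

The model deliberately omits 5′/3′ UTR geometry, ribosome drop-off during
elongation, depletion of a shared free-ribosome pool, and coupling between
transcripts; each transcript is simulated independently.  Correlating
simulated read-outs against published ribosome-profiling or proteomics
datasets is out of scope for the package itself — the translatome driver
produces the per-transcript tables such comparisons would consume, and
`loglog_slope()` is the only regression utility provided.

Problem sizes in the shipped test suite are the package's own choices for
a quick default run: calibration checks use 200 runs (the full protocol
in `scripts/acceptance.R` uses 1000), sweeps use 150–500 runs per length,
and oracle comparisons use $10^4$ runs on small lattices.

## A worked example

```{r example, eval = FALSE}
rb <- rates_from_level(0.999, 10)
ref <- transcript_spec(L = 400, elong_rates = 10, alpha = 0,
                       reinit_rate = rb[["reinit_rate"]],
                       release_rate = rb[["release_rate"]],
                       lifetime = 1553, footprint = 10)
cal <- calibrate_alpha(ref, target_count = 6, n_runs = 1000, seed = 11)
cal
spec <- ref
spec$alpha <- cal$alpha
simulate_translation(spec, n_runs = 1000, seed = 99)
```
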