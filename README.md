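# riboloop

Stochastic simulation of mRNA translation on **circularized transcripts**:
a finite-lifetime TASEP (totally asymmetric simple exclusion process) with
extended ribosome particles and a **reinitiation** channel that lets
terminating ribosomes return directly to the start codon of the same
transcript.

## The problem

Across eukaryotes, ribosome density, initiation rate and protein abundance
all fall steeply with coding-sequence length, and codon usage matters for
protein output even when initiation should be limiting.  Linear models of
translation — where every terminating ribosome returns to the cytoplasmic
pool — struggle to explain either observation.  If mRNAs are effectively
circular, a terminating ribosome can reinitiate on the same transcript, and
the consequences are strongly length- and time-dependent: short transcripts
complete recirculation cycles faster, and the approach to any steady state
can take far longer than the transcript lives.  `riboloop` is for
quantitative/systems biologists who want to simulate and explore this
regime rigorously, without steady-state assumptions.

## The model

Each transcript is a lattice of `L` sites (one per codon; site `L` is the
stop codon).  Ribosome A-sites must stay ≥ 10 codons apart (the footprint).
Four reactions, simulated exactly with the Gillespie algorithm over the
transcript lifetime `T`:

| reaction | rate | rule |
|---|---|---|
| de novo initiation | α | entry region (sites 1–10) must be free |
| elongation `i → i+1` | kᵢ | next A-site must be > 10 codons downstream |
| release from site `L` | β | always available at the stop codon |
| reinitiation `L → 1` | r | entry region must be free |

The reinitiation level `p = r/(r+β)` is the probability a terminating
ribosome recirculates.  Read-outs per transcript: **ribosome density**
(lifetime-averaged ribosome count ÷ `L/10`), **effective initiation rate**
(de novo + reinitiation events per second), **protein yield** (arrivals at
the stop codon), averaged over ~1000 independent runs.

## Worked example

Calibrate the de novo initiation rate so a 400-codon transcript at 99.9%
reinitiation carries 6 ribosomes over a 1553 s lifetime, then simulate:

```r
library(riboloop)
rb  <- rates_from_level(0.999, 10)
ref <- transcript_spec(L = 400, elong_rates = 10, alpha = 0,
                       reinit_rate = rb[["reinit_rate"]],
                       release_rate = rb[["release_rate"]],
                       lifetime = 1553, footprint = 10, id = "demo")
cal <- calibrate_alpha(ref, target_count = 6, n_runs = 300, seed = 11)
cal
#> Calibrated alpha = 0.0091398 /s (mean count 5.961, target 6, 300 runs, 10 iterations)

spec <- ref; spec$alpha <- cal$alpha
simulate_translation(spec, n_runs = 300, seed = 99)
#> Translation summary for 'demo' (400 codons, 300 runs, lifetime 1553 s)
#>   ribosome density:     0.1531 (SE 0.0027)  [mean count 6.125]
#>   eff. initiation rate: 0.1528 /s (SE 0.0026)
#>   protein yield:        225.8 (SE 3.9)
```

So a calibrated α of ~0.009/s yields a density of 6/40 = 0.15, and almost
all of the 0.15/s effective initiation is recirculation (α is 60-fold
smaller): each mRNA produces ~226 proteins in its lifetime.  Under perfect
reinitiation with collision-free initiation, density falls with the inverse
of length:

```r
sw <- length_sweep(c(500, 1000, 2000, 4000), reinitiation_policy(1.0),
                   alpha = 0.001, elong_rate = 10, lifetime = 3000,
                   n_runs = 200, seed = 5)
sw$slopes
#>       measure  slope ci_lo  ci_hi n
#>       density -1.057 -1.25 -0.864 4
#> eff_init_rate -0.996 -1.14 -0.855 4
#>         yield -1.115 -1.37 -0.858 4
```

Other entry points: `perturb_transcript()` (2×/0.5× changes to the
reinitiation rate, α, or all elongation rates of one transcript species),
`slow_step_scan()` (a single 1/0.1/0.01 s⁻¹ codon at the start, middle or
final coding position), `steady_state_diagnostics()` (steady-state density
and first-passage time), `translatome_run()` (FASTA + codon rate table +
lifetimes → per-transcript summaries), and `exact_ctmc_summary()` (exact
master-equation oracle for small lattices).  A command-line front end with
the same operations is installed at
`system.file("exec", "riboloop", package = "riboloop")`.

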