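# osmcheck

Statistical model checking of probabilistic claims about stochastic systems
— reaction-network models of cellular pathways, or any simulator observed
only through Boolean outcomes of a property.

## The problem

Given a stochastic model *M* and a path property ψ (e.g. "the ASER marker
gcy-5 stays above the ASEL marker gcy-6 after time 300"), statistical model
checking decides the claim

&nbsp;&nbsp;&nbsp;&nbsp;*M* ⊨ Pr<sub>Δθ</sub>{ψ},&nbsp;&nbsp;Δ ∈ {≥, >, ≤, <}

by simulating independent trajectories, judging ψ on each (a Bernoulli
outcome x<sub>i</sub> with unknown success probability *p*), and applying a
sequential hypothesis test — no state-space enumeration.

The classical sequential tests need a user-chosen *indifference region*
half-width δ around θ:

* **Wald SPRT** (`younes_a`): H₀: p ≥ θ+δ vs H₁: p < θ−δ, likelihood-ratio
  boundaries A = (1−β)/α, B = β/(1−α). Always definite, but the error bounds
  ⟨α, β⟩ silently fail when p lies inside [θ−δ, θ+δ].
* **Two acceptance tests** (`younes_b`): H₀: p ≥ θ vs H₁: p < θ−δ with
  strength ⟨α, γ⟩, simultaneously H₀′: p ≥ θ+δ vs H₁′: p < θ with strength
  ⟨γ, β⟩. TRUE when both accept their null, FALSE when both reject,
  UNDECIDED otherwise (rate bounded by γ outside the region).

Choosing δ well requires knowing *p* — which is what you came to estimate.
The optimized algorithms remove the choice:

* **`osm_a(problem, alpha, beta, source)`** starts at the widest possible
  half-width δ = 1 with γ = min(α, β), runs the two-test procedure
  incrementally, and on every UNDECIDED halves δ and re-enters with the
  accumulated tally (n, d) — samples are never redrawn. Always returns an
  error-bounded TRUE/FALSE.
* **`osm_b(problem, alpha, beta, max_samples, source)`** is `osm_a` under a
  global sample cap. If the cap is reached, it falls back to the binomial
  p-value rule — accept whichever of H₀: p ≥ θ, H₁: p < θ has the smaller
  p-value (1 − F(d; n, θ) vs F(d; n, θ)) — and flags the answer as
  *not* guaranteed, reporting the p-value as the confidence measure.

The package also provides a mass-action Gillespie simulator
(`load_network`, `simulate_trace`), a finite-trace temporal-logic evaluator
for properties over species trajectories with G/F/U, forward differences
d([X]) and time windows (`parse_formula`, `evaluate_formula`), a seeded
replication harness (`run_benchmark`) and a CLI (`smc_cli`).

## Worked example

Does the surrogate pathway property hold with probability at least 0.28,
when the true satisfaction probability is 0.25?

```r
library(osmcheck)
pr  <- verification_problem("GE", 0.28,
         property_id = "(d([lsy2N]) > 0) U (G(d([lsy2N]) <= 0))")
src <- bernoulli_source(p = 0.25, seed = 42)
osm_a(pr, alpha = 0.01, beta = 0.01, src)
#> <verification result> [osm-a]
#> <verification problem> P >= 0.28 { (d([lsy2N]) > 0) U (G(d([lsy2N]) <= 0)) }
#>   decision:   FALSE (error-bounded)
#>   samples:    3383 (successes 865)
#>   final delta: 0.03125
```

The claim is rejected with the full ⟨0.01, 0.01⟩ guarantee; the algorithm
needed to shrink δ to 1/32 (p is only 0.03 below θ) and 3383 samples. Under
a 3000-sample budget the capped variant answers the same way but honestly
downgrades the guarantee:

```r
osm_b(pr, 0.01, 0.01, max_samples = 3000, bernoulli_source(0.25, 42))
#>   decision:   FALSE (p-value based)
#>   samples:    3000 (successes 775)
#>   p-value:    0.00413186 (other hypothesis: 0.995868)
```

A small replication study (200 repetitions; the published studies use
1000):

```r
prm <- test_parameters(delta = 0.05, gamma = 0.01)
tab <- summarize_to_table(list(
  run_benchmark(benchmark_config("younes-a", 0.5, 0.25, params = prm,
                                 replications = 200, base_seed = 1)),
  run_benchmark(benchmark_config("osm-a", 0.5, 0.25, params = prm,
                                 replications = 200, base_seed = 1))))
tab[, c("theta", "delta", "algorithm", "mean_n", "correct", "errors")]
#>   theta delta algorithm mean_n correct errors
#> 1   0.5  0.05  younes-a  45.53     200      0
#> 2   0.5    NA     osm-a  33.25     200      0
```

Both reject P ≥ 0.5 on every run; the δ-free algorithm needs ~27% fewer
samples. White-box verification runs the same algorithms against
trajectories of a JSON-defined mass-action network:

```r
net <- load_network(system.file("extdata", "race_network.json",
                                package = "osmcheck"))
src <- property_source(net, "G([B] > [C]) {[time] > 0}", seed = 1)
osm_a(verification_problem("GE", 0.2, "race"), 0.01, 0.01, src)$decision
#> [1] "TRUE"
```

The CLI wraps the same functionality:

```sh
Rscript inst/scripts/osmcheck verify --model bernoulli:p=0.25 \
    --prop "P>=0.5 psi" --algo osm-a --seed 1      # exit code 1 (FALSE)
```

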