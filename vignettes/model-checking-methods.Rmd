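---
title: "Sequential statistical model checking without an indifference region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential statistical model checking without an indifference region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmcheck)
```

## The verification problem

A stochastic model — here, a continuous-time Markov jump process defined by
a mass-action reaction network, but any seedable simulator works — is
queried through a path property $\psi$ over its trajectories. Each
simulated trajectory yields one Boolean outcome $x_i \in \{0,1\}$
("did this run satisfy $\psi$?"); the outcomes are i.i.d. Bernoulli with
unknown success probability $p$. The claim to decide is
$\Pr_{\Delta\theta}\{\psi\}$ with $\Delta \in \{\ge, >, \le, <\}$.

Strict and non-strict relations are statistically indistinguishable from
samples, so $>$ is treated as $\ge$. The $\le$/$<$ relations are mechanized
by the complement identity
$\Pr_{\le\theta}\{\psi\} \iff \Pr_{\ge 1-\theta}\{\neg\psi\}$: the
threshold becomes $1-\theta$ and each outcome is negated before tallying;
the TRUE/FALSE verdict then answers the original claim directly. (How the
published experiments mechanized their $\le$ row is not stated anywhere;
the complement transform is this package's choice, and its correctness is
property-tested over all outcome strings of length $\le 10$.)
$\theta \in \{0,1\}$ is rejected rather than special-cased: both hypothesis
tests are degenerate there.

## The two baselines

**Wald SPRT with indifference region** (`younes_a`). Tests
$H_0: p \ge \theta+\delta$ against $H_1: p < \theta-\delta$. After $n$
samples with $d$ successes the log likelihood ratio is

$$\log f_n \;=\; d \log\frac{\theta-\delta}{\theta+\delta}
  \;+\; (n-d) \log\frac{1-\theta+\delta}{1-\theta-\delta},$$

accepting $H_0$ (TRUE) when $\log f_n \le \log\frac{\beta}{1-\alpha}$ and
$H_1$ (FALSE) when $\log f_n \ge \log\frac{1-\beta}{\alpha}$. Computed in
log space; the product form underflows for long runs. The
$\langle\alpha,\beta\rangle$ guarantee holds **only** when
$|p-\theta| > \delta$, and the test cannot tell the user whether it does.

**Two simultaneous acceptance tests** (`younes_b`). Test 1:
$H_0: p \ge \theta$ vs $H_1: p < \theta-\delta$ with strength
$\langle\alpha,\gamma\rangle$; test 2: $H_0': p \ge \theta+\delta$ vs
$H_1': p < \theta$ with strength $\langle\gamma,\beta\rangle$; log-space
boundaries $A_1 = \log\frac{1-\gamma}{\alpha}$,
$B_1 = \log\frac{\gamma}{1-\alpha}$, $A_2 = \log\frac{1-\beta}{\gamma}$,
$B_2 = \log\frac{\beta}{1-\gamma}$. Sampling continues while either
statistic is strictly inside its interval; on stop, TRUE iff both accept
their null, FALSE iff both reject, UNDECIDED otherwise. Definite answers
are $\langle\alpha,\beta\rangle$-bounded for any $p$; $\gamma$ bounds the
undecided rate outside the indifference region.

## The optimized algorithms

`osm_a` removes the user-chosen $\delta$. It starts at $\delta = 1$ — the
widest region needs the fewest samples — with
$\gamma = \min(\alpha,\beta)$ fixed (not user-tunable, by design), and
runs the two-test procedure incrementally. On UNDECIDED it halves $\delta$
and re-enters carrying the tally $(n, d)$: the stop condition is
re-evaluated on the carried tally *before* drawing, so a re-entry may
immediately yield a definite answer, need more samples, or demand a
further halving. Samples are never redrawn; the total draw count equals
the $n$ at which the last level decided.

Clamping the hypothesis points into $[0,1]$
($p_0 = \max(\theta-\delta, 0)$, $p_1 = \min(\theta+\delta, 1)$) is what
makes $\delta = 1$ legal. At the clamped endpoints the log-ratios take
their limit values: with $p_0 = 0$ a single success drives the first
statistic to $-\infty$ (its null is accepted by any success); with
$p_1 = 1$ a single failure drives the second to $+\infty$. All $\pm\infty$
comparisons are well defined. $\delta$ halves without a lower limit;
floating-point underflow of $\theta \pm \delta/2^k$ toward $\theta$ is
benign, and termination in the capped variant never depends on it.

`osm_b` adds a **global** sample cap across all $\delta$ levels (not per
level — the published capped mean of 2784.7 below a 3000 cap implies whole
truncated runs). A boundary crossing at or before the capped sample wins
over the budget check. Once the cap is hit, the fixed-sample fallback
accepts whichever of $H_0: p \ge \theta$, $H_1: p < \theta$ has the lower
binomial p-value, where
$\text{pval}_{H_0} = 1 - F(d; n, \theta)$ and
$\text{pval}_{H_1} = F(d; n, \theta)$, $F$ the binomial CDF (the published
formula's exponent reads $n-1$ where the CDF requires $n-i$; this is
treated as a typo). The knife-edge tie $F = \tfrac12$ is resolved by the
fixed-sample rule TRUE iff $d/n \ge \theta$ and flagged in the run record.
The accepted hypothesis's p-value is reported together with the rejected
one, so small p-values can be used as a trust heuristic. One subtlety: an
UNDECIDED stop *exactly at* the cap also falls through to the fallback
rather than halving further — the carried tally cannot become definite at
the same $n$ by shrinking $\delta$ (see the next section for how far that
argument carries), and halting there guarantees termination even when
$p = \theta$ exactly.

$F$ is computed by `stats::pbinom` (regularized incomplete beta), stable
to $n \sim 10^6$; the test suite checks it against naive term-by-term
summation exhaustively for $n \le 50$.

## A known overstatement in the reuse argument

The sample-reuse argument claims that if the two-test procedure at
half-width $\delta$ stops UNDECIDED at $n_0$, the procedure at $\delta/2$
cannot have produced a definite answer at any $n \le n_0$, and hence that
the optimized run costs exactly what the fixed-$\delta$ procedure would
cost at the final half-width. For the printed, non-latching stop rule this
is **not strictly true**: the narrower statistics can cross their
boundaries at an $n$ where the wider ones are still inside (intuitively,
$d/n$ between the acceptance slopes of $\delta$ and $\delta/2$ favors a
definite answer at $\delta/2$ and an undecided one at $\delta$). Measured
on random streams, the fixed-$\delta$ run stops earlier on roughly 5–8% of
streams; in every observed case the *decision* agreed. The invariants
actually guaranteed — and tested — are: decisions agree; whenever the
standalone run does not stop before the reuse re-entry tally, it stops at
exactly the same $n$; and the error bounds of `osm_a` hold regardless,
because each level is a valid two-test run entered at a tally the narrower
test had not yet rejected. The strict form is kept, deliberately red, in
the acceptance suite.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\alpha$ | P(answer FALSE when the claim holds) | 0.01 | strictly in (0, 0.5) for the optimized runs |
| $\beta$ | P(answer TRUE when it does not) | 0.01 | as above |
| $\gamma$ | undecided-rate bound of the two-test run | `min(alpha, beta)` | fixed to that value inside `osm_a`/`osm_b`; 0.01 in the replications (the published studies never state theirs; 0.01 is inferred from their $\alpha=\beta=0.01$ settings) |
| $\delta$ | indifference half-width | — | baselines only; must satisfy $\delta < \min(\theta, 1-\theta)$ for the SPRT, $\delta \in (0,1]$ for the two-test run |
| `max_samples` | global cap | 3000 in the replications | `osm_b` only |

All randomness is explicit: every source takes a seed, sources keep a
private RNG stream (drawing never disturbs the session RNG), and the
benchmark harness derives replication $r$'s seed as `base_seed + r`, so
any summary is reproducible from its configuration alone.

## What the synthetic generator emulates

The replication studies drive the algorithms with a Bernoulli surrogate:
draw a uniform number, call the sample true iff it is below $p$ — exactly
how the published "simple model" works, and a faithful stand-in for any
model because the algorithms see nothing but i.i.d. Boolean outcomes. The
surrogate probabilities are the published estimates ($p = 0.25$ for the
"lsy-2 never rises again" property, $p = 0.46$ for the ASER-fate marker
property, both estimated there from $10^7$ runs). What the surrogate does
*not* emulate: simulation cost (a real SSA run is expensive; sample counts
translate to wall-clock time), trajectory-level structure (judging $\psi$
on a trace is exercised separately through the SSA + temporal-logic
modules), and any model misspecification — a green replication says the
*statistics* behave as published, nothing about any particular pathway
model. The 22-entity cell-fate network behind the published case study is
out of scope (its rate parameters were never published); the shipped JSON
examples are illustrative stand-ins, not reconstructions.

## Finite-trace semantics

Properties are judged on the finite event sequence of one SSA trace,
optionally restricted to times beyond $T$ by a trailing `{time > T}`
qualifier (the restriction is applied first; the verdict is satisfaction
at the first retained observation). `G`/`F`/`U` take their usual bounded
semantics; a `G` over the empty window is vacuously true, `F`/`U` are
false. The forward difference `d([X])` at position $i$ is
$X(s_{i+1}) - X(s_i)$; the final position has no forward difference, so
derivative atoms there are *undefined*: they can neither witness an
`F`/`U` nor refute a `G`, and an undefined verdict at the top level is
reported as FALSE. (Treating them as plain false would make
`G(d([X]) <= 0)` unsatisfiable and break the duality
$G\,\varphi \equiv \neg F\,\neg\varphi$, which the suite property-tests.)
These are conventions — linear temporal logic over infinite paths behaves
differently — and are stated here because verdicts near the horizon depend
on them. Conjunctions of probabilistic claims (`... AND ...` at the CLI)
run as independent problems; the conjunction holds iff every conjunct is
TRUE.

The simulator is Gillespie's direct method with combinatorial
(falling-factorial) mass-action propensities, the standard CTMC convention
for pathway models; every event is recorded (no thinning), times are
unitless and shared with the property layer's time bounds. Traces end at
the first event time at or beyond the horizon, or at total-propensity
zero.

## Design choices where the design was open

* **Ties in the p-value fallback** can only occur at $F = \tfrac12$
  exactly; the fixed-sample $d/n \ge \theta$ rule breaks them, and the run
  record flags the tie. Which rule the published runs used is unknowable
  from the text; the choice is measure-zero for continuous $\theta$.
* **Strict relations** are decided exactly like their non-strict
  counterparts and recorded as such in the result metadata.
* **The cap-vs-boundary race** in `osm_b` is resolved for the boundary
  (checked before the budget), maximizing guaranteed answers.
* **Benchmark ground truth** must be decidable: the harness refuses
  $p_{\text{true}} = \theta$, and white-box sources require an explicit
  truth label.
* **Configs and model files are JSON.** No YAML parser is available in the
  target R environment; the network schema is otherwise exactly the
  documented one.

## Known limitations

* `osm_a` need not terminate when $p = \theta$ exactly; that regime is the
  reason `osm_b` exists. Expected sample counts grow like
  $|p-\theta|^{-2}$ as $\theta$ approaches $p$.
* The p-value fallback carries no frequentist error guarantee; the
  reported p-value is a confidence heuristic (empirically, wrong fallback
  answers carry visibly larger p-values than correct ones — the
  replication suite checks the separation).
* The SSA is a plain R implementation adequate for the small demonstration
  networks; verifying properties of large networks at $10^4$+ samples per
  decision would want a compiled simulator behind the same
  `property_source` contract.
* Replication matches published *distributions*, not streams: the original
  per-run seeds are unknown, so comparisons are statistical (means within
  Monte Carlo tolerance, counts within $\pm 3\sqrt{k}$).
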