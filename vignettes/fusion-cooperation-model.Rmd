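---
title: "The identity-fusion / indirect-reciprocity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The identity-fusion / indirect-reciprocity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fusionsim)
```

## The model

`fusionsim` simulates how *identity fusion* — the degree to which an
agent's identity, here operationalised as its reputation, overlaps with
that of a group — can coevolve with cooperation sustained by indirect
reciprocity. A population of `N` agents repeatedly plays the one-shot
donation game: a donor may pay a cost `c` to grant a recipient a benefit
`b > c`, with no promise of reciprocation. Donations are conditioned on
reputation, so cooperation can be sustained by reputation dynamics alone.

Each agent `i` carries:

* a heritable fusion level `f_i` in `[0, 1]`;
* heritable action rules `(s_i, u_i, d_i)`: binary flags that say whether
  `i` donates when the recipient's reputation looks *similar* to,
  *above*, or *below* its own. The rule `(1, 1, 0)` — donate upward and
  on similarity, defect downward — is the strategy that dominates when
  identity is purely personal;
* a personal reputation `r_i`, an integer in `[-5, 5]`, reset at the
  start of every generation;
* payoff and three contribution counters (below), also reset each
  generation.

The population shares a single group reputation `r_G`, an integer in
`[-5, 5]`.

**Reputation views.** A fused observer (`f_i > 0`) sees agent `j`
through the integrated reputation

```
r^j = (1 - f_j) * r_j + f_j * r_G,
```

so the more fused the *target*, the more its public face is the group's.
An unfused observer (`f_i = 0`) is assumed to place no value on the
group's standing and sees only `r_j`. The donor applies the same rule to
itself to obtain its self-view `r^i`.

**Donation decision.** The donor classifies `r^j` against `r^i` with a
similarity band `delta = 0` and applies the matching rule bit. Views are
real numbers, and the comparison is exact arithmetic comparison;
similarity at `delta = 0` therefore means exact equality of the two
views (see *Numerical choices* for consequences).

**Assessment (standing).** A donation increments `r_i`, and `r_G` too
when the donor is fused. A defection against a recipient viewed as at
least as reputable (`r^j >= r^i`) decrements `r_i` (and `r_G` when
fused); a defection against a less reputable recipient is *legitimate*
and costs nothing. Increments saturate at the caps. A defection forced
by interaction-stage ostracism (below) can still cost the donor personal
reputation, but never the group reputation: from the group's
perspective, that defection is legitimate.

**Contribution and vicarious hypocrisy.** A fused donor's group-relevant
actions are tallied: `n_pos` donations (raise `r_G`), `n_neu` legitimate
or ostracism-forced defections (leave `r_G`), `n_neg` illegitimate
defections (lower `r_G`). Its contribution ratio is

```
ctr_i = (n_pos + n_neu) / (n_pos + n_neu + n_neg),
```

undefined until the agent has acted as a fused donor. A fused observer
`i` perceives a fused target `j` as a *hypocrite* when `f_j >= f_i` and
`ctr_j < ctr_i`: someone at least as dependent on the group identity who
visibly supports it less. A check occurs with probability `p = f_i`
(sensitivity to hypocrisy scales with the observer's own fusion), only
when `f_i` reaches the threshold `T`, and never against oneself.

**Ostracism.** Four regimes: type 0 (none), type 1 (a donor that detects
hypocrisy in its prospective recipient withholds the donation regardless
of its action rules), type 2 (at reproduction, an agent excludes
perceived hypocrites as candidates to copy), type 3 (both).

**Errors.** With probability `e_p` a perceived contribution ratio is
replaced by a Uniform(0,1) draw (mis-information; the replacement
fabricates a value even where the true ratio is still undefined). With
probability `e_x` an ostracism that should happen is not performed.

**Partner choice.** With probability `S_i` the donor draws its recipient
uniformly from its in-group — the other agents at least as fused as
itself — and otherwise uniformly from everyone else. `S_i` is either a
fixed exogenous probability (0 meaning fully global mixing) or the
donor's own fusion level (`s_policy = "fusion"`). An empty in-group
falls back to a global draw so that every game is played.

**Selection.** After `m` games a generation ends. Each slot of the next
generation independently copies the rules and fusion level of a parent
drawn roulette-wheel style with weights proportional to payoff shifted
by the worst payoff (uniform if all weights vanish); the candidate pool
includes the reproducing agent itself, minus its exclusions under
type-2/3 ostracism (if exclusions empty the pool, the full population is
used). Each offspring's rule bits then flip independently with
probability `mu`, and its fusion level is resampled Uniform(0,1) with
probability `mu`. All payoffs, reputations and counters reset to zero.

## Parameters and defaults

| Parameter | Meaning | Default |
|---|---|---|
| `n_agents` (`N`) | population size | 100 |
| `games_per_gen` (`m`) | donation games per generation | 5000 |
| `generations` (`M`) | generations per run | 50,000 (paper preset); 2,000 (desk) |
| `benefit` (`b`), `cost` (`c`) | donation game stakes | 1.0, 0.7 |
| `extra_cost` (`c_T`) | donation surcharge for agents with `f_i >= T` | 0 |
| `threshold` (`T`) | minimum fusion to ostracise (and surcharge gate) | 0 |
| `delta` | similarity band | 0 |
| `mutation_rate` (`mu`) | per-element mutation probability | 0.01 |
| `ostracism_type` | 0–3 | 0 |
| `s_policy` | in-group mixing | 0 (global) |
| `err_perception`, `err_execution` | error rates | 0 |

The defaults are the study conditions under which all reported regimes
were obtained; only the swept parameter changes between conditions.

## What a run generates, and what it does not

A run *is* its own synthetic data: the initial population draws rule
bits Bernoulli(1/2) and fusion levels Uniform(0,1), and everything
thereafter is endogenous. Reported metrics are cumulative: **average
cooperation** is all donations so far over all games so far; **average
fusion** is the mean fusion level over all generation–agent pairs, with
each generation's fusion recorded at the end of its games, before
replacement. Cumulative averaging damps single-generation shocks by
`1/generation`, which is why short runs still carry their initial
transient (an effect visible in the baseline numbers below).

The model idealises aggressively: dyadic public encounters, a single
group, global observability of fusion and contribution, no population
structure. Passing tests say nothing about human behaviour; they say the
mechanics of this idealisation are implemented exactly.

## Reproducibility and the documented draw order

Two engines implement the identical model: a compiled one (used by
default) and a pure-R one. Both consume R's RNG stream in the same
documented order, so runs are bit-identical across engines at any seed —
this is tested, and it pins the compiled engine to the readable
reference implementation. Per game: donor index; in-group gate (one
draw, consumed even when `S_i = 0`); partner index; then, for types 1
and 3, the hypocrisy-check draws (check gate; perception gate, plus the
replacement value only if it fires; execution gate only for a perceived
hypocrite). Per reproduction slot: the per-candidate check draws in
increasing candidate index (types 2 and 3, skipping the slot itself);
one selection draw; the mutation gates (`s`, `u`, `d`, fusion, then the
fusion replacement value only if its gate fires). A third, independent
implementation of the unfused special case (`base_model_reference()`)
follows the same order, and fusion-pinned-at-zero runs of the full
engine must reproduce it bit-exactly — the reduction property.

## Numerical choices and their consequences

*Exact real comparisons.* Reputation views are real-valued, and
`delta = 0` similarity is exact equality. This was a genuinely open
design choice: agents could plausibly perceive views on the integer
scale on which reputations themselves live. The choice matters more
than it may appear, because it controls how well a highly fused
defector can hide behind the group reputation. With exact comparisons,
any personal-reputation deficit leaves a trace of size
`(1 - f_j) * (r_G - r_j)` in the composite view, so discrimination is
nearly perfect and the no-ostracism baseline (type 0) settles into a
stable, highly fused cooperative state (cooperation ≈ 0.8, fusion ≈
0.98 at desk scale) rather than collapsing under shirker invasions. In
controlled side experiments, coarsening perception to the integer scale
collapses the type-0 baseline (≈ 0.37/0.41) and damps the damage of
perception error, but destroys the establishment of fused cooperation
under low exogenous in-group mixing (type 3 at `S = 0.1` becomes
bistable and stays mixed for at least 10,000 generations) — the
package's headline robustness property. Fine discrimination is needed
for fused cooperation to *establish* without assortment; coarse
perception is needed for fused shirkers to *hide*. No single granularity
delivers both. We keep exact comparisons, which preserves the type-3
robustness results, and report the baseline's behaviour as measured.

*Perception-error scope.* Noise replaces the perceived ratio even when
the true ratio is still undefined (early in a generation). A side
experiment restricting noise to defined ratios changed the
perception-error results by less than 0.001, so the simpler rule is
kept.

*Undefined ratios.* Before an agent has acted, no hypocrisy judgement is
possible: `is_hypocrite()` returns `FALSE` if either ratio is undefined,
avoiding a spurious first-move penalty.

*Saturation.* Reputation increments at a cap are lost, not banked.

*Ties and degenerate sets.* An empty in-group falls back to a global
draw; exclusions that empty the reproduction pool fall back to the full
population; all-zero selection weights fall back to a uniform draw.

*Self-checks.* An agent never tests itself for hypocrisy at
reproduction. Without perception error a self-check could never fire
(`ctr_i < ctr_i` is false); allowing noisy self-exclusion seemed
unfounded, and skipping the draws keeps the stream lean.

*Fusion mutation.* Mutated fusion is resampled Uniform(0,1) —
replacement, not perturbation — matching the uniform initial assignment.
A consequence worth knowing: exactly unfused agents (`f = 0`) occur with
probability zero after mutation, so the unfused special cases of the
view and assessment rules are exercised only by explicitly constructed
populations (`mutate_fusion = FALSE`).

## Problem sizes

The desk preset (`M = 2000` generations, 3 seeds per condition, with
`N = 100`, `m = 5000`) is the package's standard experimental scale: a
single condition is ~10^7 games and takes seconds with the compiled
engine, and all qualitative regimes reported here are stable at it. The
paper preset (`M = 50,000`, 5 seeds) is available via
`preset_params("paper")` for long-run work. Unit tests run the same
mechanics at toy sizes (N ≈ 10–20, m ≈ 50–300), where the pure-R engine
and brute-force traces are practical.

## What the desk-scale experiments show

Numbers below are seed-averaged cumulative metrics computed by the
acceptance suite (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`); they are reproduced, not asserted.

* **Type-3 robustness.** With hypocrisy ostracism at both interaction
  and reproduction (`T = 0`, no errors), cooperation and fusion both
  exceed 0.85 for every mixing setting `S ∈ {0.1, 0.5, 0.9, f_i}`
  (≈ 0.90–0.92 cooperation, 0.94–0.99 fusion).
* **Execution-error tolerance.** Type 3 at `S = f_i` holds ≈ 0.92/0.99
  at `e_x = 0.2` and ≈ 0.91/0.99 at `e_x = 0.4`.
* **Perception error.** At `e_p = 0.2`, fusion stays ≈ 0.99 but
  cooperation falls to ≈ 0.61: fabricated contribution readings make
  honest fused agents withhold donations from each other, and with
  exact-comparison discrimination the reputational side effects
  compound. This cell falls short of the 0.8 level that coarser
  perception variants reach (see *Numerical choices*).
* **Baseline contrast.** Without ostracism (type 0), cooperation is
  clearly below the type-3 level (≈ 0.82 vs ≈ 0.92), but the population
  stabilises fused (≈ 0.98) instead of abandoning fusion — again the
  exact-comparison regime; coarser perception collapses this baseline
  entirely.
* **Reduction.** With fusion pinned at zero the full engine is
  bit-identical to the independent base-model implementation, the group
  reputation is never touched, and the evolved modal rule is `(1,1,0)`.

## Known limitations

* The perception-granularity sensitivity above is the model's largest
  unresolved degree of freedom; results for the type-0 baseline and for
  perception error should be read conditional on the exact-comparison
  choice.
* Cumulative metrics at `M = 2000` still carry the initial transient;
  plateau (instantaneous) rates are typically a few points higher than
  the cumulative averages reported.
* The pure-R engine is a correctness oracle, not a workhorse: it is
  ~100× slower than the compiled engine.
* No population structure, private information, or multi-group dynamics;
  encounters are strictly dyadic.
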