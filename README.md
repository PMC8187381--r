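# fusionsim

Agent-based simulation of how **identity fusion** — a strongly held
personal identity that overlaps with a group's identity — can coevolve
with cooperation under **indirect reciprocity**, and of the role of
**ostracising perceived hypocrites** in protecting a shared group
reputation from exploitation.

The package is for researchers in social and cultural evolution who want
a fast, fully reproducible implementation of this model family:
reputation-conditioned donation games under the standing norm, a shared
group reputation blended into individual reputations by fusion, and
evolutionary (roulette-wheel) transmission of strategies and fusion
levels.

## The model in brief

`N` agents play `m` one-shot donation games per generation (donor pays
`c = 0.7`, recipient gains `b = 1`). A donor `i` compares its view of the
recipient's reputation with its view of its own and donates according to
its heritable rule bits `(s_i, u_i, d_i)` for similar / upward / downward
comparison. Views integrate a personal reputation `r_j` and the group
reputation `r_G` (both integers in `[-5, 5]`, standing assessment norm)
through the target's fusion level:

    r^j = (1 - f_j) r_j + f_j r_G        (fused observer, f_i > 0)
    r^j = r_j                            (unfused observer, f_i = 0)

Fused agents also track a per-generation **contribution ratio**
`ctr_i = (n_pos + n_neu) / (n_pos + n_neu + n_neg)`, the fraction of
their group-relevant actions that supported or legitimately spared
`r_G`. With probability equal to its own fusion level, a fused agent
checks a fused partner for **vicarious hypocrisy** — `f_j >= f_i` yet
`ctr_j < ctr_i` — and, if detected, ostracises: by withholding the
donation (type 1), by excluding the hypocrite as a parent at
reproduction (type 2), or both (type 3). A fusion threshold `T`,
perception error `e_p` and execution error `e_x` gate and perturb the
mechanism. Selection copies rules and fusion with probability
proportional to payoff; each heritable element mutates at 1%.

Reported metrics are cumulative: average cooperation (donations over
games played so far) and average fusion (mean fusion over all
generation–agent pairs so far).

## Worked example

A desk-scale run of the strongest regime — type-3 ostracism with
in-group mixing tied to fusion (`S_i = f_i`):

```r
library(fusionsim)
p <- sim_params(ostracism_type = 3, s_policy = "fusion",
                generations = 2000, seed = 1)
fit <- run_model(p)
fit
#> Identity-fusion / indirect-reciprocity simulation
#>   N = 100 agents, m = 5000 games/gen, M = 2000 generations, seed 1
#>   ostracism type 3, S = f_i, T = 0, e_p = 0, e_x = 0
#>   average cooperation: 0.9197
#>   average fusion:      0.9905
summary(fit)
#> Average cooperation 0.9197 over 10000000 games (9197036 donations)
#> Average fusion 0.9905; final-generation mean fusion 0.9930
#> Modal final action rule (s,u,d): 110
#> Final rule frequencies:
#> rules
#> 110 111 011 100
#>  66  31   2   1
```

Read: over 10 million games, 92% ended in a donation; the population is
almost fully fused (average fusion 0.99); and the dominant evolved
strategy is `(1,1,0)` — donate to those seen as similar or better,
legitimately defect on those seen as worse. `plot(fit)` draws both
cumulative curves against generation. Multi-seed replicates and
parameter sweeps:

```r
run_experiment(p, n_seeds = 3)             # seed-averaged metrics
sweep_s_policy(p, ostracism_types = 0:3,
               s_values = list(0, 0.1, 0.5, 0.9, "fusion"))
```

Sweep tables carry every parameter, the seeds and a config hash, so any
row is regenerable from the table alone. A thin command-line interface
(`inst/cli/fusionsim.R`) wraps runs, the six standard sweeps and
plotting. The methods vignette
(`vignettes/fusion-cooperation-model.Rmd`) documents the model, the
documented RNG draw order behind the engine cross-validation, and the
numerical design choices.

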