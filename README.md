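# adaptrex

Adaptive temperature replica exchange (parallel tempering) with self-guided
Langevin dynamics, in R.

## What problem this addresses

Replica-exchange (T-ReX) simulations run N copies of a system at a ladder of
temperatures spanning [T_min, T_max] and periodically swap temperatures
between neighboring clients with the Metropolis probability

    P(a <-> b) = min(1, exp[(beta_a - beta_b)(E_a - E_b)]),   beta = 1/(kB T),

so cold replicas escape kinetic traps by cycling through the hot end. A
static geometric ladder,

    T_i = T_min (T_max/T_min)^(i/(N-1)),   i = 0..N-1,

works well until a sharp energy barrier sits between conformational states:
exchange acceptance collapses near the transition temperature and the ladder
stops mixing. The adaptive remedy implemented here labels every replica
"cold" or "hot" by the last temperature extreme it visited, accumulates
per-window visit histograms, and periodically re-places the interior
temperatures so that the fraction-cold profile

    f(T) = n_cold(T) / (n_cold(T) + n_hot(T))

becomes linear in client index, under the constraint that no neighboring
pair drifts more than two geometric spacing units apart
(T_{i+1}/T_i <= r^2). Dynamics between swap attempts is self-guided Langevin
(SGLD): plain Langevin plus a guiding force λγ⟨p⟩ built from a recursive
moving average of the momentum, which accelerates slow collective motions
(λ = 0 recovers plain Langevin exactly).

The package is aimed at people studying tempering schedules and refinement
analytics at desk scale: it ships toy and Gō-type bead models, decoy
generation, the refinement metrics (fraction of native contacts f_N at a
6.5 Å side-chain-center cutoff, Kabsch RMSD), and the rank-order aggregation
used to summarize refinement benchmarks — not an all-atom force field.

## Worked example

```r
library(adaptrex)

# 16 independent double-well coordinates, barrier 5 kB*T_min: the
# heat-capacity peak sits at the cold edge of the [1, 5] ladder
dw  <- double_well_model(5, 1, dim = 16)
pr  <- dynamics_params(dt = 0.02, gamma = 1, lam = 1, t_l = 1)
cfg <- run_config(dw, "adaptive", t_min = 1, t_max = 5, n = 8, pr,
                  steps_per_swap = 20, n_rounds = 20000, seed = 7, init_x = 1)
res <- run_simulation(cfg)
res
#> <run_result> mode = adaptive, 20000 rounds, 8 replicas
#>   mean round trips/replica: 209.12
#>   mean exchange rate: 0.667

round(res$rep$ladder$temps, 3)          # converged ladder: clustered cold end
#> [1] 1.000 1.089 1.331 1.513 2.007 2.640 4.077 5.000
round(exchange_rate_profile(res$rep), 3)  # near-flat acceptance profile
#> [1] 0.782 0.624 0.637 0.636 0.613 0.585 0.789
```

The geometric ladder on the same system accepts ~0.45 at the cold pair and
~0.64 at the hot pair; adaptation moves four of the six interior windows
below T = 2.7 and flattens the profile. Refinement metrics on a synthetic
native (a helical bead chain) and noisy decoys:

```r
nat <- synthetic_fold(30)
ds  <- generate_decoys(nat, 16, sigma = 1.5, seed = 7)
head(metric_report(ds), 4)
#>   decoy_id       f_N   rmsd_A
#> 1        1 0.6727273 2.427132
#> 2        2 0.5909091 2.308696
#> 3        3 0.5545455 2.724552
#> 4        4 0.6000000 2.620827
```

f_N is the fraction of the native's side-chain-center pairs within 6.5 Å
that are preserved in the decoy; rmsd_A is the optimal-superposition RMSD in
angstroms. The packaged refinement benchmark grid (8 targets × 2 sampling
methods × 4 scoring functions) aggregates to the published margins:

```r
tab <- read_score_table()
aggregate_score_table(tab, method = "adaptive")
#> $mean     0.6225
#> $rounded  0.62
#> $n_cells  32
```

## Command line

`inst/cli/adaptrex.R` exposes subcommands `run` (JSON config → artifact
directory with ladder history, occupancy trace, exchange log, histogram and
summary), `adapt-ladder` (offline histogram CSV → new ladder CSV), `metrics`
(PDB decoys + native → f_N/RMSD CSV), `aggregate` (score-table CSV →
margin summaries) and `compare` (two run directories → comparison table).
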