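# neutralcr

Stochastic consumer-resource communities that look neutral even when they
are not — an exact simulator, the deterministic theory that predicts when
that happens, and the statistics that try to tell the difference.

## The problem

Neutral theory assumes every individual has the same birth and death
probabilities regardless of species. Its signature prediction — Fisher's
log-series species abundance distribution (SAD), `P_k ∝ p^k / k` — fits
many real high-diversity communities, yet real species differ in how they
use resources. `neutralcr` is for theoretical and microbial community
ecologists who want to ask, quantitatively: *how different can consumers'
resource preferences be before community-level patterns stop looking
neutral?*

The package models `S` consumers competing for `K` externally supplied,
substitutable resources through a `K × S` consumption matrix `C`, as an
exact continuous-time Markov chain (Gillespie simulation) with events

```
R_k → R_k + 1              rate ρ_k                 (resource inflow)
N_i → N_i − 1              rate η_i N_i             (consumer death)
R_k → R_k − 1              rate (1−ε) R_k C_ki N_i  (consumption)
R_k → R_k − 1, N_i → N_i+1 rate ε R_k C_ki N_i      (consumption + birth)
```

plus a speciation floor: a species drawn for death at abundance 1 stays at
1 and an extinction (turnover) is logged. Two scenarios break neutrality:
**generalists** (i.i.d. random entries of `C` with coefficient of variation
CV) and **specialists** (diagonal `Cd`, off-diagonal `Co`). Linearizing the
mean-field model splits the Jacobian spectrum into fast resource/collective
modes and `S − 1` slow niche modes whose leading rate `λ₊` measures
stabilization. Comparing `1/|λ₊|` with the drift-to-extinction timescale
`T_n/η̄` yields threshold scales

```
CV_thr   ~ sqrt( (S/4n) (1 − εr/2n) )            (generalists)
Cd/Co_thr ~ (1 + γ(S−1)) / (1 − γ),  γ = (1/n)(1 − εr/2n)   (specialists)
```

below which SADs, extinction times, and short-time abundance fluctuations
are statistically indistinguishable from pure drift.

## A worked example

```r
library(neutralcr)

# a specialist community: 20 consumers, each with one preferred resource
C <- specialist_matrix(20, Cd = 3, Co = 1)
non_neutrality_index(C)
#> [1] 0.1428571

params <- community_params(C, n = 50, r = 50)   # calibrated equilibrium
traj <- simulate_community(C, params, burn_in = 300, n_generations = 500,
                           cadence = 100, seed = 1)
sort(final_sad(traj), decreasing = TRUE)
#>  [1] 274 142 134 121  84  53  40  31  24  18  11   8   5   5   4   4   2   2   1   1

tidy(cvm_logseries_test(final_sad(traj), seed = 2))
#> # A tibble: 1 × 7
#>   statistic p_value success p_hat     n n_boot cutoff
#>       <dbl>   <dbl> <lgl>   <dbl> <int>  <dbl>  <dbl>
#> 1    0.0943   0.539 TRUE    0.996    20    999   0.05
```

At `Cd/Co = 3` this community has genuinely distinct preferences
(NNI ≈ 0.14), yet its SAD spans three orders of magnitude and is retained
as log-series (bootstrap p-value 0.54): the predicted specialist threshold
scale at these parameters, `predict_specialist_threshold(20, 50, 50)`
≈ 1.20 (defined up to a multiplicative constant; the measured 50% crossing
in the package's own scans is ≈ 3.5), has not been crossed decisively.
Raising `Cd/Co` to 6-7 makes the fit fail reliably.

Ensemble experiments follow the same pattern and return tidy tables, e.g.

```r
cfg <- experiment_config("specialist", index_grid = c(1.5, 2.3, 3.2, 4.5, 6.5),
                         S = 20, n = 50, r = 50, ensemble = 32, seed = 5)
ens <- run_sad_ensemble(cfg)     # per-community CvM fits + logistic threshold
autoplot(ens)
```

A thin command-line wrapper with subcommands (`simulate`, `sad-ensemble`,
`threshold-scan`, `nni-compare`, `extinction`, `fluctuations`,
`cosine-obs`) over JSON configs lives in `inst/scripts/crneutrality`.

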