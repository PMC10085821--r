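# tagrecover

Estimate how long a captured, tagged and released marine animal takes to
return to baseline behaviour, from archival depth and tri-axial
accelerometer records.

Tagging induces a transient stress response. Data recorded right after
release mix that response with the natural behaviour the tag was meant to
observe, so analysts either trim an arbitrary initial stretch or
contaminate their baseline. `tagrecover` estimates the recovery time
itself, separately for two behavioural channels that recover at different
speeds, and supports contrasts between groups of animals (e.g. short vs
long handling time).

## Methods in brief

**Quantile-regression recovery (activity metrics).** For VeDBA, ODBA or
jerk, the model at quantile level τ is

    log Y_τ = β_ind + α_g · z,   z = 1/(t+1),  t = hours since release

one offset per animal, one decay slope per group, fitted by pinball-loss
minimisation. The return time at threshold δ solves `exp(α z) = δ`:

    t_R = max(0, |α| / |log δ| − 1)        (δ = 0.25 by default)

with cluster-bootstrap (by animal) confidence intervals and Wald tests
for slope equality between groups or quantile levels.

**Relative-entropy recovery (dive profile).** Hourly distributions `P_t`
of dive duration over target-depth categories (Shallow/Medium/Deep) are
compared with a baseline `Q` — a weighted average over the "normal
region" t > tN whose weights `w_i = n_i / Σ n_j` account for staggered
tag drop-offs — via the base-2 Jensen–Shannon divergence `J(P_t‖Q) ∈
[0,1]`. A leave-one-out 95% band of typical divergences (the *region of
recovery*) labels each hour ±1, and the return time is the breakpoint of
the cumulative label sum, estimated by segmented regression over
block-bootstrap resamples.

A preprocessing chain (zero-offset depth correction by recursive moving
quantiles, dive segmentation, zero-phase low-pass static acceleration,
VeDBA/ODBA/jerk, resampling, block-mean aggregation) produces both inputs
from raw sensor streams, and seeded simulators (`simulate_accel()`,
`simulate_dives()`, `simulate_cohort()`) generate cohorts with known
ground truth.

## Worked example

```r
library(tagrecover)

# --- activity channel: known truth alpha = -2.5, t_R(0.25) = 0.803 h
sc  <- accel_scenario(n_animals = 5, duration_h = 60, obs_per_h = 20)
sim <- simulate_accel(sc, seed = 42)
design <- qr_design(sim$observations, tau = 0.5, response = "VeDBA")
fit <- fit_quantile_model(design)
fit
#> <qr_fit> VeDBA tau = 0.5 - 6000 obs
#>   alpha: all -2.4963
#>   pinball loss: 2278.433
bootstrap_ci(design, delta = 0.25, n_boot = 500, seed = 42)
#>     tau group delta t_R_h ci_lower_h ci_upper_h method
#> 1   0.5 all    0.25 0.801      0.745      0.830 percentile_bootstrap(...)

# --- dive channel: composition steps back to baseline at t* = 12 h
dv     <- simulate_dives(dive_scenario(t_star = 12), seed = 42)
hourly <- hourly_distributions(dv$dives)
sch    <- build_schedule(dv$record_ends_h, tN = 40)
ror    <- region_of_recovery(hourly, sch, T_h = 80)
ror
#> <ror> [ 0.0001358 , 0.01926 ] at level 0.95 from 40 leave-one-out
#>       divergences, hours ( 40 , 80 ]
es   <- entropy_series(hourly, reference_distribution(hourly, sch))
labs <- label_series(es[es$hour <= 80, ], ror)
block_bootstrap_breakpoint(labs, block_h = 5, n_boot = 1000, seed = 42)
#> <breakpoint_estimate> t_R = 10.84 h, 95% CI [ 7 , 16 ]
#>       (block 5 h, 1000 replicates, 188 dropped)
```

The fitted slope −2.496 recovers the generating value −2.5; the 0.801 h
return time sits on the closed-form truth 0.803 h, inside its bootstrap
interval; and the dive-profile breakpoint interval [7, 16] h brackets the
simulated 12 h changepoint (the point estimate sits slightly below the
step — see the methods vignette for why block resampling leans early).

A YAML-driven pipeline (`run_pipeline()`, or the CLI wrapper
`inst/cli/tagrecover.R` with stages `preprocess|qr|entropy|simulate|all`)
runs both channels over a cohort, writes per-group estimate tables
(metric × τ × group for the regression stage; one row per group for the
entropy stage), JSON results, diagnostic plots and a reproducibility
manifest. See `vignettes/tag-recovery-methods.Rmd` for the model details,
tunable parameters and design decisions.

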