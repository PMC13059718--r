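# ferrodyn

Feedback dynamics of cell proliferation, lipid reactive oxygen species
(ROS), and ferroptosis sensitivity.

Proliferating cells generate lipid ROS as a by-product of division; lipid
ROS above a threshold triggers ferroptotic death; death and crowding in turn
change how fast the population proliferates. `ferrodyn` implements this
feedback loop as a two-variable dynamical system and provides everything
needed to analyse it and confront it with live-cell-imaging data:

- **model core** — the ODE system, fixed-point enumeration, and stability
  classification;
- **phase analysis** — attractor assignment, basin-of-attraction maps over
  initial (ROS, confluence) states, and nullclines;
- **fitting** — bounded weighted least squares against tidy time courses,
  with multi-start optimisation and condition-specific parameters (e.g. a
  separate death threshold under GPX4 inhibition);
- **observables** — the signal transforms from raw imaging channels to
  model observables: oxidized/reduced reporter ratios, dead counts per
  confluence, population doublings, per-replicate MFI normalisation, and
  dead-cell mask exclusion on multi-channel image frames;
- **synthetic data** — a fully seeded generator emulating seeding-density,
  GPX4-inhibition, glucose/galactose, and growth-space experimental
  designs, including rendered microscopy-like frames with ground-truth
  labels;
- **pipeline I/O** — CSV/JSON/YAML/TIFF formats and a small command-line
  driver (`inst/cli/ferrodyn.R`).

## The model

Confluence fraction `n` and per-cell lipid ROS `r` evolve as

    dn/dt = alpha * n * (1 - n/K) - beta * n * sigma(r)
    dr/dt = a * alpha * (1 - n/K) - b*r + c*r

with the Hill death switch `sigma(r) = r^h / (r0^h + r^h)`. ROS production
is proportional to the per-capita division rate `alpha (1 - n/K)`, which is
what couples population density to ferroptosis sensitivity: crowded
populations divide slowly, make little lipid ROS, and resist death, while
sparse populations divide fast and can push themselves over the threshold.
`b > c` is required so that net ROS clearance (first-order clearance `b`
minus Fenton-type autocatalysis `c`) stays positive.

Under the canonical defaults the system is bistable: a
ferroptosis-**resistant** state at full confluence and zero lipid ROS, and a
ferroptosis-**sensitive** state at low confluence and high lipid ROS. Which
one a population reaches depends on where it starts — the seeding-density
phenotype.

## Quick start

```r
library(ferrodyn)

p <- model_params()   # canonical parameter set
p
#> Feedback-model parameters (hill death switch):
#> alpha     K  beta     a     b     c    r0     h
#> 0.050 1.000 0.045 0.500 0.030 0.020 1.200 4.000

find_fixed_points(p)[, c("n", "r", "classification")]
#>        n     r classification
#> 1 0.0000 2.500         saddle
#> 2 0.2061 1.985         stable    <- ferroptosis-sensitive state
#> 3 0.4821 1.295         saddle
#> 4 1.0000 0.000         stable    <- ferroptosis-resistant state
```

An untreated low-density population grows toward confluence:

```r
simulate_model(p, model_state(0.10, 0), seq(0, 72, by = 12))
#>   time_h      n      r   dead
#>        0 0.1000 0.0000 0.0000
#>       12 0.1683 0.2453 0.0000
#>       24 0.2683 0.4390 0.0010
#>       48 0.5247 0.6654 0.0246
#>       72 0.7266 0.7163 0.0970
```

Lowering the death threshold to 40% of control (the GPX4-inhibition
preset) flips the fate of the same seeding density — growth stalls and the
cumulative dead count climbs:

```r
simulate_model(update_params(p, r0 = 0.48), model_state(0.10, 0),
               seq(0, 72, by = 12))
#>   time_h      n      r   dead
#>        0 0.1000 0.0000 0.0000
#>       24 0.2383 0.4422 0.0274
#>       48 0.2741 0.7388 0.2260
#>       72 0.2492 0.9746 0.4834
```

The basin map quantifies the shift: the sensitive basin covers about 74% of
the default grid under control parameters and about 95% under the inhibitor
preset:

```r
bs <- compute_basins(p)
basin_area_fraction(bs, sensitive_index(bs$attractors))
#> [1] 0.7377778
bs_rsl3 <- compute_basins(update_params(p, r0 = 0.48))
basin_area_fraction(bs_rsl3, sensitive_index(bs_rsl3$attractors))
#> [1] 0.9483333
plot(bs)   # shaded basin map with the attractors marked
```

Generate a synthetic experiment and fit it back:

```r
syn <- generate_dataset(preset_scenarios()[c("LD_DMSO", "LD_RSL3")])
fit <- fit_timecourses(syn$dataset,
                       fit_spec(free = c("alpha", "K", "beta", "r0"),
                                condition_specific = "r0"))
fit$estimates[c("r0.LD_DMSO", "r0.LD_RSL3")]
# the recovered threshold is lower under RSL3 than under vehicle,
# with a median estimated ratio of ~0.40 across seeds (truth: 0.40)
```

Image analysis with dead-cell exclusion:

```r
f <- render_frame(n = 0.35, r = 1.5, dead_area = 0.05, seed = 99)
live_cell_measurement(f)
#> live confluence 0.342 | live ox/red 0.850 | cellular lipid ROS 2.487 | dead area 0.058
```

## Command-line pipeline

Every analysis step is available as a subcommand writing its artifacts plus
a `run_info.json` log:

```sh
Rscript inst/cli/ferrodyn.R simulate --out-dir out --seed 1
Rscript inst/cli/ferrodyn.R basins   --out-dir out
Rscript inst/cli/ferrodyn.R synth    --out-dir out --seed 1
Rscript inst/cli/ferrodyn.R fit      --out-dir out --data out/timecourses.csv
```

Exit codes: 0 success, 2 configuration/schema error, 3 numerical failure.
Subcommands also accept a YAML configuration via `--config`; unknown keys
are rejected.

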