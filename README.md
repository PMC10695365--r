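# grouptrax

Trajectory analysis of social behavior in group-housed rodents.

## The problem

Whether and how an animal's behavioral traits (boldness, exploration,
activity, tameness, sociability) shape the social relationships it forms is
a core question in animal-personality research. The measurement design the
question demands is heavy: a multi-test behavioral battery per subject,
then continuous multi-animal video tracking of small groups — here, groups
of four female laboratory rats in a 91 × 54 cm cage, tracked over nine-hour
nightly sessions across two multi-day terms — and a statistical layer that
connects the two. grouptrax implements that full pipeline for R users:

* **synthetic arena** — an agent-based simulator of group trajectories
  (bounded correlated random walk with per-partner social attraction and
  home-base pull) and of a 13-item behavioral-test battery with a planted
  low-rank trait structure, so every downstream stage has a
  parameter-recovery test surface, plus a corruption generator for tracking
  failure modes;
* **track repair** — speed gating, identity-swap resolution by per-frame
  optimal assignment with hysteresis, and bounded linear gap interpolation,
  scored by an estimation-accuracy measure against a reference trajectory;
* **behavioral tests** — the 13 battery indices from open field, novel
  object, three-chamber, elevated plus maze and glove-test material, with
  fixed zone and entry-counting conventions;
* **social metrics** — dyadic proximity (threshold + bout debouncing),
  isolation time, and approach/avoidance events with mover attribution,
  aggregated to per-term means and standardized by group;
* **stats suite** — correlation-matrix PCA with salient-loading assignment
  (|loading| ≥ 0.4) and the Kaiser criterion; ICC(3,k) consistency with the
  substantial (> 0.7) / moderate (0.4–0.7) / low bands; a random-intercept
  LMM likelihood-ratio test of familiarity; Pearson correlation panels with
  Fisher-z intervals; and trait-similarity versus dyad proximity.

The central statistic for consistency is the two-way mixed, consistency,
average-measures intraclass correlation computed from the two-way ANOVA
without interaction:

    ICC(3,k) = (BMS − EMS) / BMS

with BMS the between-subject and EMS the residual mean square over k
occasions (days).

Data containers follow Bioconductor idiom: a tracking session is a
`TrajectorySet`, a `SummarizedExperiment` with assays `x`, `y`, `valid`
(frames × animals), the time base in `rowData` and animal metadata in
`colData`. I/O covers a plain long CSV layout and the three-header-row CSV
dialect of pose-tracking tools.

## Worked example

Simulate one week for a group of four in which one dyad (r1, r2) is mutually
attracted, then recover that structure from the trajectories:

```r
library(grouptrax)

ids <- c("r1", "r2", "r3", "r4")
traits <- lapply(setNames(nm = ids), function(id)
  agentTraits(activity = 2, attraction = setNames(rep(0, 3), setdiff(ids, id)),
              homeAffinity = 0.1, noiseSd = 0.6))
traits$r1@attraction["r2"] <- 0.8
traits$r2@attraction["r1"] <- 0.8

cfg  <- arenaConfig(sessionDuration = 600, nDays = 7, seed = 42)
days <- simulateGroup(traits, cfg,
                      familiarity = setNames(ids[c(2, 1, 4, 3)], ids))
days[[1]]
#> TrajectorySet: 3000 frames x 4 animals (day 1)
#>   arena 91 x 54 cm, 5 Hz, 600 s
#>   animals: r1, r2, r3, r4
#>   valid animal-frames: 100.0%

ps <- proximitySeries(days[[1]], thresholdCm = 20, minBoutS = 2)
round(proximityTime(ps), 1)
#> r1-r2 r1-r3 r1-r4 r2-r3 r2-r4 r3-r4
#> 600.0  76.4   9.8  81.6   8.0  37.0
```

The attracted dyad spends the whole 600 s session in proximity; chance-level
dyads sit an order of magnitude lower. Onset/offset events carry mover
attribution:

```r
ev <- detectEvents(ps, days[[1]], windowS = 3)
head(ev[, c("dyad_a", "dyad_b", "kind", "time_s", "mover")], 3)
#>   dyad_a dyad_b      kind time_s mover
#> 1     r1     r3 avoidance    5.6    r1
#> 2     r1     r3  approach   53.2    r1
#> 3     r1     r3 avoidance   62.6    r3
```

Partner preference consistency across the seven days, for subject r1's three
partners:

```r
prox_by_day <- vapply(days, function(ts)
  proximityTime(proximitySeries(ts)), numeric(6))
icc3k(prox_by_day[c("r1-r2", "r1-r3", "r1-r4"), ])
#> ICC(3,k): 0.999  (n = 3 subjects, k = 7 occasions) -> substantial
```

The planted preference is near-perfectly consistent, as it should be. The
whole chain — battery simulation, PCA, daily metrics, term aggregation,
group standardization, ICCs, LMM, correlation panels and a rendered report
— runs from one configuration with `runPipeline(defaultRunConfig())`, or
from the shell via `scripts/pipeline.R` (subcommands `run`, `simulate`,
`repair`, `metrics`, `stats`, `report`).

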