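# fireclust

Swarm-optimized clustering for mental-health grading of student cohorts.

College mental-health screening programs score each student on a battery of
0–10 psychometric indicators and then sort students into four anxiety grades
(normal, mild, moderate, severe). When the grades are assigned by K-means
clustering of the indicator vectors, the result depends heavily on the random
initial centroids: Lloyd's algorithm only descends to a local optimum of the
within-cluster sum of squares. `fireclust` removes that sensitivity by seeding
K-means with the best solution found by the **Fireworks Algorithm (FWA)**, a
swarm optimizer, and wraps the whole pipeline — indicator scoring (including a
temporal-perception indicator), synthetic cohort simulation, clustering,
grade mapping, and benchmarking — into one tested package with a CLI.

## The method

**Objective.** For data `x₁..xₙ ∈ ℝᵈ` and centroids `c₁..c_K`, both stages
minimize the SSE loss

```
L = Σᵢ Σ_{x ∈ Cᵢ} ‖x − cᵢ‖²
```

**Fireworks Algorithm.** A population of n "fireworks" (each encoding all K
centroids as one flat vector of length K·d) explodes each generation:

* *Explosion radius* — `rᵢ = (fᵢ − f_min) / Σⱼ(fⱼ − f_min) · A`: the best
  firework searches in a tiny radius (exploitation), the worst in a radius up
  to the amplitude A (exploration).
* *Spark counts* — `sᵢ = (f_max − fᵢ) / Σⱼ(f_max − fⱼ) · k`, rounded and
  clamped to `[0.1k, 0.5k]` with a hard minimum of 1, so better fireworks get
  more sparks.
* *Explosion sparks* perturb a random subset of dimensions by
  `rᵢ · U(−1, 1)`; *Gaussian mutation sparks* multiply a random subset of
  coordinates by `N(1, 1)` draws for diversity.
* *Selection* keeps the best candidate (elitism) and fills the remaining
  slots by distance-proportional sampling, preferring isolated candidates.

**Hybrid.** After T generations the best firework is decoded into K initial
centroids and refined by Lloyd's K-means; elitism makes the FWA best-fitness
history non-increasing, and Lloyd descent guarantees the final loss never
exceeds the FWA seed's fitness.

**Index system.** Indicators are scored on 0–10 (≥ 8 normal, < 3 obstacle,
otherwise average). Temporal perception — a person's untimed sense of
duration — is scored from duration-estimation trials as
`10 · max(0, 1 − median relative error)`. With K = 4, clusters are mapped to
the four grades by descending mean indicator score, and clustering accuracy
against known grades is computed after optimal (Hungarian) one-to-one
cluster-to-grade matching.

## Worked example

```r
library(fireclust)

co  <- generate_cohort(cohort_config(seed = 0))   # 6 colleges x 200 students
res <- fwa_kmeans(co$scores, K = 4, fwa_config(seed = 0))
res
#> <clustering_result>
#>   K          : 4
#>   n          : 1200
#>   loss (SSE) : 7448.95
#>   iterations : 7 (converged)

map_clusters_to_grades(res, co$scores)
#>                1                 2                 3                 4
#> "severe_anxiety"          "normal"    "mild_anxiety" "moderate_anxiety"

match_accuracy(res$assignment, co$true_grades)
#> [1] 1
```

The cohort is a labeled simulation of the target study design: four latent
anxiety grades with mean indicator profiles 8.5 / 6.5 / 4.5 / 2.0 and
Gaussian noise (sd 0.8) clipped to [0, 10]. The hybrid recovers the planted
grades exactly here (accuracy 1.0); the SSE of 7448.95 is the residual noise
variance around the four centroids. Indicator-level helpers work the same
way:

```r
indicator_level(c(8.4, 5.0, 2.1))
#> [1] normal   average  obstacle
quantify_temporal_perception(c(11, 14, 32), c(10, 15, 30))
#> [1] 9.333333
```

## Command line

```sh
Rscript inst/cli/fireclust.R simulate  --seed 1 -o cohort.csv
Rscript inst/cli/fireclust.R cluster   --cohort cohort.csv --method fwa_kmeans --k 4 --seed 0 -o result.json
Rscript inst/cli/fireclust.R evaluate  --result result.json --cohort cohort.csv -o metrics.json
Rscript inst/cli/fireclust.R benchmark --cohort cohort.csv --n-seeds 20 -o report.json --csv report.csv
```

All subcommands are byte-reproducible under a fixed `--seed`.

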