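---
title: "Methods: fireworks-seeded K-means for mental-health grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fireworks-seeded K-means for mental-health grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireclust)
```

## The problem

Screening a student cohort for anxiety means scoring every student on a set
of 0--10 psychometric indicators and sorting the score vectors into four
grades: normal, mild, moderate and severe anxiety. When the sorting is done
by K-means, the answer depends on the initial centroids -- Lloyd's algorithm
is a coordinate descent that stops at the nearest local optimum of the
within-cluster sum of squares (SSE). `fireclust` treats centroid placement as
a global optimization problem: the Fireworks Algorithm (FWA) searches the
space of complete centroid sets, and its best solution seeds K-means.

## The Fireworks Algorithm

A firework is a candidate solution: a flat vector of length $K \cdot d$
encoding all $K$ centroids row-major (each firework carries a *complete*
centroid set -- this is what makes a per-firework SSE fitness well defined).
Each generation:

1. **Fitness** $f_i$ = SSE loss of the nearest-centroid assignment the
   decoded centroids induce.
2. **Explosion radius** $r_i = \frac{f_i - f_{\min}}{\sum_j (f_j - f_{\min})}
   \, A$. The best firework gets a radius near zero (we floor it at
   $10^{-8}A$ so it still moves), the worst up to the amplitude $A$. If all
   fitnesses tie, each gets $A/n$.
3. **Spark counts** $s_i = \frac{f_{\max} - f_i}{\sum_j (f_{\max} - f_j)}\,k$,
   rounded, clamped to $[\mathrm{round}(0.1k), \mathrm{round}(0.5k)]$, hard
   minimum 1. Ties split the budget as $k/n$ each.
4. **Explosion sparks**: each spark picks $z \sim U\{1..D\}$ dimensions and
   displaces each by $r_i \cdot U(-1, 1)$; out-of-box coordinates wrap
   modularly, $x \mapsto lo + (|x - lo| \bmod (hi - lo))$.
5. **Gaussian mutation sparks** (6 per generation by default): multiply $z$
   random coordinates by $N(1,1)$ draws. A published variant of this formula
   multiplies by $N(0,1)$, which recentres coordinates at zero in
   expectation and destroys position information; we keep it available as
   `mutation_mode = "as_printed"` but default to the $N(1,1)$ form.
6. **Selection**: the best candidate always survives (elitism; ties by
   lowest index); the other $n-1$ slots are sampled without replacement with
   probability proportional to each candidate's summed Euclidean distance to
   all others, which preserves diversity.

Elitism makes the best-fitness history non-increasing -- a property the test
suite asserts on every run.

### Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `n_fireworks` | 6 | population size n |
| `spark_budget` | 6 | total explosion sparks k per generation |
| `amplitude` | 25 | maximum explosion radius A (score units) |
| `n_mutation_sparks` | 6 | Gaussian sparks per generation |
| `max_iterations` | 100 | generations T |
| `clamp_low_frac`, `clamp_high_frac` | 0.1, 0.5 | spark-count clamps as fractions of k |

The defaults are the published study settings. Two of them needed a reading:
the printed definition of the mean radius is circular (it averages the radii
it is used to compute), so the amplitude is a user constant, which is also
the canonical FWA form; and "individual variation 6" is ambiguous between
6 mutation sparks per generation and per firework -- we implement the
per-generation total, which keeps the candidate pool size comparable to the
spark budget. The study also lists 10 cluster centers while the application
has four grades; `K` is therefore an explicit argument (the application layer
uses 4, where the cluster-to-grade mapping is defined), and any other K is
honored without a merging heuristic.

## K-means and the hybrid

`kmeans_fit()` is Lloyd's algorithm from explicit initial centroids:
alternate nearest-centroid assignment (squared-Euclidean, ties to the lowest
centroid index) and mean updates, stopping when the relative loss change
falls below `loss_tolerance` ($10^{-6}$ by default; the termination threshold
is configurable because no canonical value exists) or after
`max_iterations`. Empty clusters are repaired by re-seeding them with the
sample currently farthest from its own centroid, keeping K fixed. The search
box for the FWA stage is the per-dimension data min/max repeated K times:
a centroid outside the data hull can always be moved onto the hull without
increasing the SSE, so nothing is lost by the restriction.

`fwa_kmeans()` decodes the single best firework into K initial centers and
refines with `kmeans_fit()`. Because Lloyd descent is monotone from that
start, the final loss never exceeds the FWA best fitness.

Comparators: `kmeans_random` (K distinct random rows) and `kmeans_pp`
(K-means++ D²-weighted seeding). An exhaustive set-partition oracle
(`exhaustive_optimal_partition()`, restricted-growth-string enumeration,
refused above $10^5$ partitions) provides ground truth on tiny instances.

## The index system

Indicators are real-valued on $[0, 10]$. The three-band reading is exact at
its cut-offs: $\ge 8$ normal, $< 3$ obstacle, $[3, 8)$ average -- the
half-open middle band means real-valued scores leave no gap between the
integer anchors 3 and 7. The final outcome has exactly four grades.

**Temporal perception** is scored from duration-estimation trials. No
published formula exists for turning such trials into a 0--10 indicator; we
operationalize the identify/aggregate/validate narrative as: per-trial
relative error $e_t = |est_t - true_t| / true_t$, aggregated by the median
(robust to a single wild trial), mapped linearly to the score scale,
$\mathrm{score} = 10 \max(0, 1 - \tilde e / e_{\max})$ with
$e_{\max} = 1$ (a 100% misjudgment saturates to 0). The linear ramp keeps
the score directly interpretable against the 3/8 band cut-offs. The indicator
list itself is configuration data (default: 9 conventional indicators + 1
temporal-perception indicator), not a hard-coded taxonomy.

**Grade mapping.** With K = 4, clusters are ordered by descending mean
indicator score (higher = healthier) and assigned normal, mild, moderate,
severe in that order, ties broken by cluster index. Grades arise purely from
clustering; no scalar composite score is computed first, since the pipeline
never needs one.

## The synthetic cohort

No public data accompany the study design (6 colleges × 200 students,
grades pre-labeled by a university psychological association), so the
generator emulates it: per college, grade labels are drawn from configurable
prevalences (default 0.55 / 0.25 / 0.15 / 0.05, skewed toward normal as in a
plausible student population), and each student's scores are the grade's
mean profile (default 8.5 / 6.5 / 4.5 / 2.0 on every indicator) plus
isotropic $N(0, 0.8^2)$ noise, clipped to $[0, 10]$.

Grade-conditional isotropic Gaussians are deliberately the *weakest*
structure under which "clustering recovers grades" is a testable claim;
harder regimes (smaller separation, unequal covariances, correlated
indicators) are one configuration away. What the default regime implies:
adjacent grades are separated by 2.0 points ≈ 2.5σ per indicator, i.e.
about 7.9σ in 10-dimensional Euclidean distance, so nearest-profile
classification is near-perfect (the suite checks ≥ 99%). Passing the
accuracy benchmark therefore demonstrates that the optimizer finds the
planted partition, *not* that real survey data would be this separable —
real psychometric data have correlated indicators, heavier tails and
boundary effects the generator does not model. Clipping (rather than
truncated-normal resampling) leaves a mild point mass at 0 for the severe
grade; it is visible only at profile means within ~2σ of the boundary.

## Numerical choices

* All randomness flows from explicit integer seeds; entry points seed the
  RNG locally and restore the caller's state, so identical seeds give
  bit-identical results (asserted down to CLI output bytes).
* Assignment ties and selection ties break deterministically to the lowest
  index.
* The cluster-to-grade matching maximizes total agreement over one-to-one
  matchings (optimal assignment on the negated contingency table, padded
  square). Majority-vote mapping was rejected because it can hand one grade
  to two clusters and inflate accuracy. The solver is an exact
  subset-DP ($O(n 2^n)$), ample for the table sizes here, and is
  cross-checked against brute-force permutation search in the tests.
* Degenerate inputs: equal fitnesses fall back to uniform radius/spark
  splits; constant data columns get an $10^{-8}$-wide search interval; empty
  clusters are repaired as above; an objective returning a non-finite value
  aborts with the offending position.

## Problem sizes in the test suite

The suite runs the full 6 × 200 default cohort through 20 paired seeds of
the hybrid and of random-init K-means (the headline accuracy and ordering
checks), 100 seeded 5-D sphere runs for optimizer sanity, 100 random
datasets for loss monotonicity, and 30 tiny instances (n ≤ 8) against the
exhaustive oracle — about two minutes in total. These sizes were chosen as
the smallest that exercise every claim at its stated threshold.

## Known limitations

* The FWA stage treats the centroid encoding as a plain box-bounded vector;
  it does not exploit the label-permutation symmetry of the objective, so
  some search effort is spent revisiting equivalent solutions.
* The grade mapping is defined only for K = 4; other K require a
  user-supplied mapping.
* The benchmark reports per-run wall-clock-free metrics only (accuracy,
  error, loss, iterations); timing comparisons are hardware-dependent and
  deliberately not asserted anywhere.
* Accuracy claims are relative to the synthetic generator's assumptions; see
  the cohort section above.
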