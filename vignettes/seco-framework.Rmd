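---
title: "Selecting reproducible k-means partitions with separation-concordance maps"
author: "SeCoClust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting reproducible k-means partitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeCoClust)
```

## The problem

k-means converges only to a local minimum of its objective, the
within-cluster sum of squares (WSS)

$$\mathrm{WSS} = \sum_{i=1}^{k}\sum_{x_j \in S_i} \lVert x_j - u_i \rVert^2,$$

with $u_i$ the mean of cluster $S_i$. Practice therefore repeats the
algorithm from many random initialisations and keeps the best-separated
solution. The difficulty this package addresses is that for cluster numbers
of practical interest many local minima have *nearly identical* WSS yet
*markedly different* partitions: the best-SSQ rule then returns a different
partition from one batch of initialisations to the next. For applications
such as disease sub-typing, where individuals must be assigned to a cohort
consistently, this instability matters as much as separation does.

The dual-measure remedy implemented here scores every run on two axes:

* **separation** — $\Delta\mathrm{SSQ}$, the total sum of squares about the
  global mean minus the run's WSS (larger is better separated);
* **concordance** — med(CV), the median Cramér's V of the run's labels
  against every other *retained* run, a stability score in $[0, 1]$.

The procedure, per cluster number $k$:

1. run an ensemble of $N_\mathrm{total}$ k-means fits, each seeded with $k$
   randomly chosen data points;
2. rank by $\Delta\mathrm{SSQ}$ and retain the top fraction $f$;
3. compute all pairwise Cramér's V values among the retained runs and each
   run's median against the others;
4. plot the retained runs at coordinates $(\Delta\mathrm{SSQ},
   \mathrm{med(CV)})$ — the SeCo map;
5. select the run with the highest med(CV), breaking ties by larger
   $\Delta\mathrm{SSQ}$, then by lower run index.

The map itself is a diagnostic: a tight cloud at med(CV) $\approx 1$ means
the best-SSQ rule is safe at that $k$; leftward spread means equally
separated ensembles disagree and the stability axis is needed. Choosing
$k$ itself is out of scope — the map only guides that choice visually.

## The clustering engine

The engine is the standard two-stage scheme: batch (Lloyd) iterations —
assign every point to its nearest prototype by squared Euclidean distance,
recompute prototypes as cluster means — until the labels stop changing,
followed by on-line refinement in which points are presented one at a time
and moved to their nearest prototype, with both affected means updated
incrementally, until a full pass moves nothing. A nearest-move with the
incremental mean update always lowers WSS, so both phases are monotone;
the engine records per-iteration WSS traces and the tests assert the
monotonicity on every run they touch.

Numerical/degenerate-case policy, chosen once and fixed:

* distance ties go to the lowest prototype index (determinism);
* a cluster emptied by a batch update is re-seeded at the point farthest
  from its stale prototype, so a requested $k$ is always delivered with
  $k$ nonempty clusters; the on-line phase never moves the last member
  out of a cluster;
* caps of 300 batch iterations and 50 on-line passes (ordinarily unhit —
  convergence is by unchanged labels);
* the on-line schedule presents points in row order. Incremental-update
  ("MacQueen-style") refinement is one reading of on-line optimisation;
  pass order can, in principle, affect which local optimum is reached,
  which is precisely the degeneracy the ensemble machinery exists to
  measure;
* features are used as supplied — no internal standardisation. Real
  datasets with incommensurate units should be min-max scaled first
  (`minMaxScale()`), which is how the labelled case study runs.

Seeding contract: ensemble run $r$ uses seed $\mathrm{master} + r$, and
benchmark repetition $r$ offsets the master seed by $r \cdot
N_\mathrm{total}$, so repetitions consume disjoint seed streams. Every
solution records its seed; any map point can be re-materialised from the
data plus its seed, which is why only retained solutions keep their label
vectors in memory.

## Concordance statistics

For two partitions cross-tabulated as a $P \times Q$ contingency table
with observed counts $O_{pq}$ and independence expectations $E_{pq} =
r_p c_q / N$,

$$\chi^2 = \sum_{p}\sum_{q} \frac{(O_{pq} - E_{pq})^2}{E_{pq}}, \qquad
C_V = \sqrt{\frac{\chi^2}{N \min(P - 1, Q - 1)}}.$$

Cramér's V was chosen because it is normalised, symmetric, indifferent to
label numbering, and defined for partitions with different cluster counts,
so no reference labelling is needed. The square root in $C_V$ is part of
the standard definition of the index and is implemented as such. The
Hubert–Arabie adjusted Rand index is provided alongside; over random
partition pairs the two indices correlate above 0.9 (asserted in the
tests), so conclusions do not hinge on the choice.

A solution's med(CV) is the median over its $m - 1$ pairings with the
other retained solutions, excluding the self-pair, which carries no
information; with an even count the mean of the two central values is
used. An overall-median summary is available (`overall = TRUE`) but never
drives selection. When the retained fraction is tightened the pairwise
matrix is recomputed on the retained subset, not filtered from a fixed
matrix, since med(CV) is defined relative to the working sample.

## The synthetic benchmark

`benchmarkMixture()` is the package's canonical test bed: ten anisotropic
trivariate normal cohorts combining well-separated and strongly
overlapping components, with mixing weights proportional to the cohort
sizes of the original 1076-point realisation. Samples are drawn i.i.d. —
component index from the weights, then a deviate through the Cholesky
factor of that component's covariance — rather than with fixed per-cohort
counts, matching a mixture's sampling model; the usual study sizes are
10000, 5000, 2500, 1000 and 500 points. Component overlap is quantified by
Dasgupta's c-separation,

$$c_{ij} = \frac{\lVert \mu_i - \mu_j \rVert}
{\sqrt{d \cdot \max(\lambda_{\max}(\Sigma_i),
\lambda_{\max}(\Sigma_j))}},$$

which the acceptance checks verify across all 45 cohort pairs. One cohort
(C8) is far from everything (all $c_{8j} \gtrsim 2$); several others mix
heavily ($c_{ij} < 1.3$).

Because of that mixing, and because the isotropic Euclidean metric ignores
the covariance structure, exact recovery of the generating cohorts is not
the yardstick. Instead a **reference partition** is derived: 500 runs at
$k = 10$ on the largest sample, lowest WSS kept; its prototypes are
propagated to each smaller dataset by iterating to convergence from them
(no random seeding, hence deterministic). Accuracy and concordance are
measured against these reference labels. On our draws the reference
agrees with the true mixture labels at about 0.6 by optimal matching —
the overlapping cohorts genuinely exceed what any Euclidean k-means can
separate, which is the intended difficulty of the benchmark.

What the generator does *not* emulate: non-Gaussian cluster shapes, heavy
tails, outliers, missing values, or feature scaling artefacts. Passing
benchmarks here therefore demonstrates correct behaviour of the selection
machinery on anisotropic overlapping Gaussian structure, not robustness
to arbitrary real data.

## Evaluation metrics

* **Accuracy** — the proportion of points whose cluster matches the
  reference under the best one-to-one relabelling. The matching maximises
  the total matched count of the contingency table by an exact
  subset-dynamic-programming assignment ($O(2^k k)$, trivial for the
  $k \le 15$ used here); greedy matching was rejected because it is not
  permutation-safe. A square table is required — accuracy is undefined
  when cluster counts differ, which is why cross-$k$ comparisons use
  Cramér's V instead.
* **Affinity** — every selected partition is aligned to the reference
  frame by that same matching; per data point the frequency of its modal
  cohort across the selections is taken, and the mean over points
  reported. It reads as "how often does a point stay in its cohort":
  1 means no point ever swaps. Alignment against the reference (rather
  than mutual alignment among selections) is used because the metric
  needs one common labelling frame; when no reference exists the first
  selection serves as the frame.

The benchmarking protocol compares the single-measure rule (best SSQ of
the whole ensemble) with the dual-measure rule on identical seed streams:
each repetition generates one ensemble and both rules select from it, so
their dispersions are directly comparable. Ordered per-repetition CV
curves (with optional per-rank percentile-bootstrap bands, 1000 resamples;
the band method is this package's choice) and a summary table of accuracy
mean/SD and affinity per method are exportable.

## Partition trees

`buildPartitionTree()` cross-tabulates the selected solutions at
consecutive $k$ and records every nonzero membership flow with its
fraction of the originating cohort. Flows under 10% of their source
(configurable) are flagged invisible rather than dropped, so rendering
stays legible while conservation — outgoing flows summing to the source
cohort size, incoming to the target's — remains exactly checkable.
Cohorts are displayed in decreasing size order, stable across renders.
The tree is built from SeCo-selected solutions; building from best-SSQ
solutions is possible by passing those solutions instead, for
comparison. On the benchmark mixture the far cohort C8 splits off by
$k = 3$ and passes essentially all its members straight down the tree,
while the mixed cohorts interleave above $k = 8$.

## Problem sizes and defaults

The package defaults are the study's operating point: $N_\mathrm{total} =
500$ initialisations, top decile $f = 0.10$ (so a working sample of 50),
$k$ mapped over 2–15, benchmark protocol of 100 repetitions. The bundled
analyses and tests run the same pipeline at reduced sizes chosen to keep
a full check of every claim comfortably interactive on one core:
stability claims use 100-run ensembles (retaining 10), the sparse-data
benchmark keeps the full 500-run ensembles with 25 repetitions, the
dense-data benchmark uses 10 repetitions of 100-run ensembles, and trend
checks use 40–60-run ensembles on 2000–3000-point samples. These sizes
are stated here once; the acceptance script prints the size it used next
to every number it reports. At the reduced ensemble size the dense-data
dual-measure accuracy sits a few parts per thousand below its full-scale
value (stability selection has only 10 retained runs to vote among), a
scale effect worth remembering when comparing against full-scale figures.

## Known limitations

* The framework stabilises *selection among* k-means optima; it cannot
  rescue structure the Euclidean objective cannot express (elongated or
  nested clusters, varying densities).
* med(CV) is relative to the retained working sample: with a very small
  retained set the median is noisy, which is why configurations keeping
  fewer than two solutions are rejected outright.
* Medoid, mode-based and kernelised variants of the engine are out of
  scope, as are consensus/ensemble-merging methods and automatic
  selection of $k$.
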