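---
title: "Methods: consensus map construction and ICIM QTL scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus map construction and ICIM QTL scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamap)
```

## The problem

Biparental mapping populations (recombinant inbred lines, doubled
haploids) are each genotyped with partially overlapping marker panels.  A
*consensus* linkage map places the union of markers on a single
coordinate system, which increases marker density for any one population
and allows QTL discovered in different populations to be compared on one
scale.  clamap builds such maps from the raw genotype data by combined
linkage analysis, scans for additive QTL by inclusive composite interval
mapping (ICIM), and quantifies — by simulation — what the denser
consensus map buys in QTL-mapping precision.

## Combined linkage analysis

For two markers observed in a homozygous population of size $n$, the
observed discordance $\hat R = k/n$ (where $k$ lines differ) estimates
the population-specific recombination metric: $R = r$ in a DH
population, and $R = 2r/(1+2r)$ in a RIL population derived by repeated
selfing, where $r$ is the meiotic recombination frequency.  The ML
estimate and its sampling variance are

$$\hat r_{\mathrm{DH}} = \hat R,\quad
\operatorname{Var} = \frac{\hat R(1-\hat R)}{n};\qquad
\hat r_{\mathrm{RIL}} = \frac{\hat R}{2(1-\hat R)},\quad
\operatorname{Var} = \frac{\hat R(1-\hat R)}{n}
\left[\frac{1}{2(1-\hat R)^2}\right]^2$$

(the RIL variance by the delta method).  Estimates from populations are
combined on the $r$ scale by inverse-variance weighting,
$\hat r_c = \sum_i w_i \hat r_i / \sum_i w_i$ with $w_i = 1/\mathrm{Var}_i$
and $w_i = 0$ where the pair is not estimable (fewer than `n_min = 20`
informative lines, or $\hat R \ge 0.5$).  The $r$ scale is used because
the $R \to r$ transform differs between population types; $r$ is the
common currency.  Two numerical choices matter here:

* A pair with no observed recombinants has $\mathrm{Var} = 0$; its
  weight is floored at $1/(1/(n+2))^2$ so perfect data dominate without
  producing infinite weights.  Several conflicting zero-variance
  estimates are averaged and a condition is signalled.
* `n_min = 20` reflects that the delta-method variance is unreliable in
  smaller samples.

Markers are grouped by the chromosome labels of the individual maps;
markers carried by all populations on one chromosome are *anchors*.  A
marker with conflicting labels is assigned to the candidate chromosome
with the strongest combined linkage to anchors (sum of $1/\mathrm{Var}$
over anchors with estimable $\hat r_c \le 0.3$); markers linked to no
anchor are dropped and logged.

## Marker ordering

Within a group, ordering minimises the sum of adjacent distances (SARF)
as an open travelling-salesman path.  The heuristic is deterministic:

1. a nearest-neighbour tour grown from the marker whose nearest
   neighbour is farthest (a likely chromosome end);
2. 2-opt segment reversals, first-improvement, left-to-right sweeps;
3. or-opt relocations of segments of one to three markers (either
   orientation), alternated with 2-opt to a joint fixed point.

The or-opt pass exists because a single marker displaced between two
well-ordered runs cannot be repaired by any segment reversal — the
repairing move is a relocation — and without it the heuristic visibly
stalls above the exhaustive optimum on small instances.  On random
map-like instances (noisy one-dimensional distances, five to eight
markers) the combined heuristic matches the exhaustive SARF optimum in
over 99% of cases and never exceeds it by more than about 3%.

The TSP operates on cM distances from the combined $\hat r_c$ (an open
choice; $r$ itself or $-\ln(1-2r)$ would order almost identically).
Pairs with no estimable combined frequency are completed by the shortest
path over estimable edges — map distances are additive along a
chromosome, so the geodesic is the natural imputation; a flat penalty
here would leave whole blocks free to order arbitrarily whenever a
junction pair happens to be genotyped in no shared population.  Truly
disconnected pairs receive twice the largest estimable distance, and a
group with no estimable chain splits into subgroups with a warning.
Each group is oriented so its lexicographically smallest anchor falls in
the front half, making the output invariant to input permutation.

Positions accumulate from 0 by converting adjacent combined frequencies
through the mapping function — Kosambi by default (conventional for
wheat), Haldane in all simulations because simulated crossovers carry no
interference.  Markers at $\hat r = 0$ from their predecessor share a
position (a bin).  A non-estimable adjacent pair is bridged by the
nearest downstream marker with an estimable frequency to the last placed
marker, interpolating the intervening markers evenly (logged).

Finally, automated pruning emulates the manual curation step of
consensus-map construction: markers whose removal shortens the group by
more than `max_contrib = 10` cM are removed iteratively (positions
re-assigned after each removal), and, when a physical map is supplied,
markers whose removal raises the group's Spearman collinearity with it
by more than 0.02.  The thresholds are configurable; 10 cM is large
enough that no marker in a clean simulated map ever triggers it, while a
single badly misplaced marker (two long spurious adjacent intervals)
always does.

## ICIM

The scan phenotype model at a position with QTL genotype code
$x \in \{+1, -1\}$ (parent-1 homozygote $= +1$) is a two-component
Gaussian mixture with means $\mu + a$ and $\mu - a$, common variance,
and per-line mixing probabilities equal to the conditional probability
of each QTL class given the flanking marker genotypes, assuming
independent recombination in the two sub-intervals on the observable $R$
metric.  Background genetic variation is controlled by cofactors chosen
once per trait by forward–backward stepwise regression on the $\pm 1$
marker codes (missing imputed to 0, the expectation under 1:1
segregation), with entry and removal p-value thresholds
`p_in = 0.001` and `p_out = 0.002`; ties break to the lower marker index
and candidates collinear with the current model are skipped.  For each
scanned interval, the phenotype is adjusted by all cofactors *except*
the interval's own flanking markers, so the local signal is not
absorbed:

$$\Delta y_i \;=\; y_i \;-\; \sum_{j \in S
\setminus \{\mathrm{left}, \mathrm{right}\}} \hat\beta_j\, x_{ij}.$$

The mixture is fitted by EM — only $(\mu, a, \sigma^2)$ are estimated;
mixing probabilities stay fixed — from a least-squares start on the
expected QTL code, to a relative log-likelihood change below $10^{-8}$
(at most 200 iterations).  The LOD compares the fitted mixture with the
single-Gaussian fit to the same $\Delta y$; since the mixture nests the
null at $a = 0$, the LOD is non-negative by construction.  PVE is
$100\, \hat a^2 s^2_x / s^2_y$ with $s^2_x$ the sample variance of the
per-line expected QTL code and $s^2_y$ the variance of the unadjusted
phenotype.  With no cofactors selected the whole construction reduces
exactly to simple interval mapping, which the test suite verifies
against an independent R implementation to $10^{-6}$ LOD.

A marker missing for a line — including markers missing for *every*
line, as happens when a population is scanned on a consensus map denser
than its own panel — contributes no information; the conditional
probabilities fall back to the nearest informative marker on each side,
and with no informative flank the prior $(0.5, 0.5)$ applies.

Peaks are local LOD maxima at or above the threshold (2.5); two maxima
are distinct QTL only if at least 5 cM apart or separated by a valley
dropping 1 LOD below the lower one.  The support interval is the
one-LOD-drop region around the peak, linearly interpolated between grid
points and clipped at chromosome ends.

## The simulator and the study conditions

The generator draws each line as a Markov chain along the ordered loci
(markers and QTLs jointly — QTL genotypes are simulated, never imputed):
the first locus is Bernoulli(1/2) and the switch probability per
interval is the observable discordance of the population type, with
$r$ from the Haldane inverse of the interval length (no interference).
For non-adjacent loci the chain composes adjacent discordances,
$R_{ij} = \tfrac12\big(1 - \prod_k (1 - 2R_k)\big)$ — the single-spore
Markov approximation to RIL descent, chosen to keep the simulation and
the estimation theory internally consistent.

The catalogued study conditions are a 100 cM chromosome with 101
markers at 1 cM spacing and RIL populations of $n = 200$: model I has
one QTL at 34.5 cM with additive effect 1 ($H^2 \in \{0.05, 0.1,
0.2\}$); models II and III have two QTLs at 26.5 and 34.5 cM in coupling
$(+1,+1)$ and repulsion $(-1,+1)$ respectively ($H^2 \in \{0.1, 0.2,
0.4\}$).  The two-QTL positions are an inference — only the single-QTL
position is fixed by convention — and remain configurable.  Phenotypes
add Gaussian noise scaled so the broad-sense heritability matches the
target against the *realized* genetic variance of the drawn population,
which keeps $H^2$ exact in expectation under linkage, including the
negative genetic variance contribution of repulsion linkage.

Two map scenarios are carved from each simulated population: the
*individual* scenario keeps the 51 even-cM markers (2 cM density); the
*consensus* scenario keeps all 101 map positions but marks the 50 odd-cM
markers missing for every line.  The observed data are identical — only
the map differs — so any difference in mapping outcomes is attributable
to the denser coordinate system, exactly the comparison of interest.
The mechanism favouring the consensus map is the interval structure:
with 1 cM intervals, a cofactor sitting two intervals from the scanned
position is no longer a flanking marker and keeps absorbing background
signal, so the LOD profile drops off faster away from the true QTL and
one-LOD support intervals shrink (by roughly 40% in the study
conditions) at essentially unchanged power.

What the generator does *not* emulate: crossover interference,
segregation distortion, residual heterozygosity, genotyping error, and
multi-trait or multi-environment structure.  Passing tests therefore
demonstrate correctness of the algorithms under the stated genetic
model, not robustness to those artefacts of real data.

## Evaluation rules

A true QTL is detected in a replicate when a called peak lies within a
5 cM support window centred on its true position; among several such
calls only the highest-LOD one is counted, and calls inside no window
are false positives.  Power is the percentage of detecting replicates
per QTL; FDR is pooled over replicates,
$100 \cdot \mathrm{FP}/(\mathrm{FP}+\mathrm{TP})$ — pooling was chosen
over per-replicate averaging for stability when detection counts are
small.  Position, effect, CI-length and LOD summaries condition on
detection, as is standard when power is low.  Downstream of the
simulation harness, the same module provides the bookkeeping rules used
on real multi-population QTL records: records within 20 cM (same
population) merge into one QTL, cross-population merges additionally
require flanking-interval physical distance under 25 Mb, a QTL is stable
when found in at least half the tested environments, stable QTLs across
traits cluster at CI gaps under 15 cM (all thresholds strict), and
genotypic values are predicted per line as the intercept plus the sum of
signed additive effects at stable QTLs.

## Problem sizes and determinism

The packaged test suite runs each simulation cell at 500 replicates,
which puts about two percentage points of Monte-Carlo standard error on
a power estimate near 90% and keeps a full run of six cells within a few
minutes on one core; `scripts/acceptance.R` uses 1,000 replicates per
cell.  All randomness flows through R's RNG: a seeded call to
`run_experiment()` or `simulate_population()` is bit-reproducible, and
the ordering heuristic, stepwise selection and EM are deterministic in
their inputs (fixed sweep orders, index tie-breaks, and a fixed
convergence rule).

## Known limitations

* Two-point estimation only; multi-point likelihoods (and F2/F3 EM
  estimation, for which the interface reserves the population-type hook)
  are out of scope.
* The consensus builder assumes shared marker names identify shared loci
  across populations.
* The stepwise-selection minutiae of other ICIM implementations (exact
  F-test degrees of freedom, entry order, collinearity handling) are not
  published; near the `p_in` boundary — for example tightly
  repulsion-linked QTLs whose marginal marker effects sit right at the
  threshold — detection power is sensitive to those details, and
  replication of third-party power figures in that regime is
  approximate even when position, effect and interval-length
  distributions match closely.
* Map pruning is an automated surrogate for what is, in practice, a
  manual curation step; its thresholds are configurable and its log
  should be reviewed.
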