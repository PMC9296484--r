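---
title: "Methods: quantifying functional trait space from fuzzy-coded traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying functional trait space from fuzzy-coded traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`traitspacer` treats each taxon as a point in a low-dimensional trait space
and asks three questions: which trait combinations explain most of the
variation among taxa (centred PCA of an incomplete fuzzy-coded trait matrix,
with broken-stick axis selection and trait–axis correlation screening); how
much of the available trait space the assemblage actually fills (convex-hull
volume compared against three Monte-Carlo null models); and whether taxonomic
membership — a proxy for phylogenetic relatedness when no phylogeny is
available — constrains where taxa sit and how much they spread (PERMANOVA and
PERMDISP on the component scores). A synthetic-data generator with planted
group-level trait syndromes makes the whole pipeline runnable and testable
without any external database.

# Fuzzy-coded traits and group-wise standardization

Expert-curated macroinvertebrate trait databases score the *affinity* of a
taxon for each state of a trait group (e.g. the eight states of "Feeding
habit") on an integer scale: 0 (no affinity) up to 3 for groups with few
states, or up to 5 for groups with many. A taxon can therefore belong
partially to several states at once. Two properties of this coding drive the
package's data model:

* **States within a group are related.** A score only means something
  relative to the other scores of the same group, so per-trait
  standardization (as one would do for independent traits) would destroy the
  within-group structure. The package standardizes *each trait group as a
  whole* onto [0, 1].
* **The coding range differs between groups** (0–3 vs 0–5), which would give
  wider-coded groups unintended extra weight in any variance-based analysis.

The default recipe divides every score by its group's *maximum possible*
code. The source descriptions of this kind of data state only that scores
were standardized to [0, 1]; dividing by the maximum possible code (rather
than the observed maximum) is this package's choice, because it equalizes
the coding ranges exactly while leaving the within-group score ratios — and
the meaning of an absent affinity as exactly 0 — untouched. An
`observed_minmax` mode (divide by the group's observed maximum) is provided
for sensitivity analysis.

The bundled dictionary assigns the 0–3 range to trait groups with five or
fewer states (respiration, resistance form, dispersal, aquatic stage, life
cycle duration, voltinism) and 0–5 to the larger groups (feeding habit,
locomotion, food type, maximal size, reproduction). Published tables of this
trait system list the ranges only as "low" vs "high" numbers of states; the
five-state cut is this package's reading, and the dictionary is a plain JSON
file the user can replace wholesale.

Missing cells (affinities never scored) are first-class: they are carried as
a mask, never imputed as zeros. An explicit zero is an *observed* absence of
affinity — which is also why the merge operation's `zero_fill` marks filled
traits as observed rather than missing: when a regional dataset simply lacks
a trait column (e.g. a respiration state no regional taxon has), the
biological assumption is zero affinity, not ignorance.

# Centred PCA of incomplete data

The ordination is a *centred* (covariance-based) PCA. Variance
standardization is deliberately not used: after group-wise [0, 1] scaling,
inflating every trait to unit variance would again distort the relatedness
of states within a group.

Missing cells are handled by pairwise deletion:

* each trait is centred on its available-case mean;
* the covariance entry for traits $j,k$ is
  $s_{jk} = \sum_{i \in J_{jk}} (x_{ij}-\bar x_j)(x_{ik}-\bar x_k) / (n_{jk}-1)$,
  where $J_{jk}$ are the taxa observed for both traits;
* the score of taxon $i$ on axis $a$ is
  $\sum_{j \; \mathrm{observed}} (x_{ij}-\bar x_j)\, u_{ja}$ — missing terms
  contribute zero. A sensitivity switch (`rescale_scores`) multiplies each
  taxon's scores by $p/p_{\mathrm{observed}}$ to compensate for the dropped
  terms; it is off by default because at the ~1% missingness this package
  targets the correction is negligible and the unrescaled score is the more
  transparent statistic.

A pairwise-deletion covariance matrix need not be positive semi-definite;
eigenvalues below $10^{-12}$ of the largest (including any negative ones)
are clipped to zero and excluded from the variance-proportion denominator.
On complete data the whole construction collapses to classical centred PCA,
which is the module's master oracle in the test suite. Axis signs are fixed
by convention — the largest-magnitude loading of each axis is positive — so
fitted objects are exactly reproducible.

Axis retention uses the broken-stick rule: axis $k$ is significant when its
variance proportion exceeds $b_k = \frac1p \sum_{i=k}^{p} 1/i$, and the
retained set is the *leading run* of significant axes (stop at the first
failure). Stopping at the first failure is standard practice and matches the
"leading block of significant axes" way such results are reported; flagging
isolated later axes that happen to beat their stick would retain axes that
cannot be interpreted in sequence. Traits are attached to axes by Pearson
correlation (available cases) with |r| > 0.5 as the default screening
threshold.

# Convex-hull occupancy and the null models

The occupied trait space is the d-dimensional convex-hull volume of the
component scores. By default the geometric analyses use the **first 4
axes**: in this trait system only the leading few axes are correlated with
multiple traits (later significant axes typically carry one trait each), and
hull cost grows steeply with dimension. The tests run on the
broken-stick-retained axes instead, where no geometry is involved.

The hull engine (compiled, incremental beneath-beyond insertion) applies a
deterministic joggle of relative amplitude $10^{-8}$ to resolve coplanar
degeneracies; the induced volume error is orders of magnitude below every
tolerance used. Inputs whose affine rank is below the space dimension
(groups of $\le d$ taxa, or flat configurations) return volume 0 with a
degeneracy flag rather than an error. To damp outlier influence, hulls can
be trimmed to the 95% of points nearest the centroid (per-axis mean; ties
broken by input order; `floor(0.95 n)` points kept).

Three null models ask whether the observed volume is smaller than expected
if axes varied independently:

1. **uniform** — each axis i.i.d. Uniform over the observed per-axis range;
2. **normal** — each axis i.i.d. Normal with the observed mean and SD;
3. **permutation** — each axis's observed values independently shuffled,
   preserving all marginals exactly.

Ranges and moments come from the *untrimmed* observed scores; trimming is
applied identically to the observed and every simulated cloud. Occupancy is
100 × observed / mean null volume (median available), and the one-sided
p-value is $(1 + \#\{V_{\mathrm{null}} \le V_{\mathrm{obs}}\})/(B+1)$ with
$B = 999$ replicates by default, so the minimum attainable p is
$1/(B+1)$ and p never prints as 0.

Whole-assemblage and per-group volume tables are computed on *untrimmed*
points by default (trimmed variants are exposed alongside), and per-group
volumes come with the per-taxon standardization $100 \cdot V_g / n_g$ and
the expected proportional volume $V_{\mathrm{whole}} / (\#\text{groups})$
for comparison.

**A calibration caveat that the test suite makes explicit.** Because Models
1–2 estimate their bounds/moments from the very cloud being tested, the
observed cloud always touches its own bounding box while null draws do not:
the observed hull is stochastically *larger* than the null hulls, and the
test is conservative (it under-rejects, and occupancy centres slightly above
100%, even when the independence null is true). The acceptance suite runs
this experiment at study scale and documents the miscalibration as a failing
expectation rather than hiding it. Model 3 is free of the problem: under
axis independence the observed cloud is exchangeable with its per-axis
permutations, and a property test verifies that its p-values are calibrated.
In practice the conservatism only strengthens a positive concentration
finding (occupancy well below 100% with a tiny p), which is the scientific
use case.

# Permutation tests of taxonomic constraint

**PERMANOVA** (one-way, Euclidean distances on the component scores)
partitions pairwise squared distances into between- and within-group sums of
squares and refers the pseudo-F to random relabellings of the taxa
(raw-label permutation — simple and exact under exchangeability). **PERMDISP**
measures each taxon's distance to its group's *spatial median* (geometric
median by Weiszfeld iteration, tolerance $10^{-9}$) and compares group mean
distances with a one-way ANOVA F; its permutation scheme relabels taxa and
*recomputes the medians* every time, so the reference distribution reflects
the full estimation procedure (this deliberately differs from implementations
that permute residual distances around fixed centres). Singleton groups have
dispersion 0 by construction. Both tests report
$p = (1+\#\{F^* \ge F\})/(B+1)$.

The relatedness suite reruns both tests three ways — small taxonomic groups
pooled into an "Others" category, the pool broken into its real groups, and
the pooled taxa omitted — because pooling heterogeneous small groups into
one label can mask or manufacture signal, and the comparison of the three
runs shows which conclusions are robust to that choice. The tests default to
the broken-stick-retained axes (the trait space that carries signal), with
the axis count exposed as a parameter since published analyses are often
ambiguous on this point.

# The synthetic-data generator

The generator emulates the *structure* of a continental fuzzy-coded trait
database, not its numbers: 596 taxa in 12 taxonomic groups (11 named + an
"Others" pool of 10 small groups, each of which keeps its fine-grained label
so the relatedness suite can unpool them), 11 trait groups / 63 traits with
the bundled 0–3 / 0–5 coding, and missing cells at a default rate of 1.03%,
injected completely at random. The default group sizes (42, 41, 10, 28, 37,
31, 39, 29, 173, 96, 38, 32, summing to 596) were derived once from the
arithmetic relation between published group volumes and their per-taxon
standardized values ($n_g = 100 \cdot V_g / \text{std}_g$) so that the
synthetic richness profile — one dominant group, several mid-sized ones, a
small pool — is realistic for European macroinvertebrates.

Each group has an *archetype*: a continuous [0, 1] profile per trait drawn
from a U-shaped Beta(0.4, 0.4) mixture of a shared baseline and a
group-specific draw, weighted by `syndrome_strength` (default 0.7, a strong
but not deterministic syndrome; 0 removes all group structure). A taxon is
its archetype plus Gaussian noise (`noise_sd`, default 0.15 on the [0, 1]
scale), clipped to [0, 1], scaled by the group's maximum code and rounded
half-away-from-zero (platform-stable, unlike IEEE half-even). The U-shaped
draw mimics how fuzzy profiles look in practice — most affinities are 0 or
maximal, with few intermediate scores.

What passing tests on this generator do **not** show: real trait databases
have correlated trait groups (e.g. size with life-cycle duration),
non-random missingness concentrated in poorly studied taxa, and
phylogenetic autocorrelation *within* groups. The generator plants none of
these, so downstream results on synthetic data validate the machinery (the
estimators, their calibration, their determinism), not ecological
conclusions about real assemblages.

# Numerical choices, in one place

* Pairwise covariance requires ≥ 2 jointly observed rows per trait pair;
  a violating pair is a named error, so the caller can drop a trait rather
  than receive a silent NaN.
* Eigenvalue clipping threshold: $10^{-12} \times$ the largest eigenvalue.
* Hull joggle amplitude: $10^{-8}$ of the coordinate scale, from a fixed
  internal generator, so hull volumes are reproducible and independent of
  R's RNG state; the affine-rank screen uses a $10^{-10}$ relative singular
  value threshold.
* Trimming keeps `floor(f n)` points; ties in centroid distance are broken
  by input order.
* Weiszfeld iteration: tolerance $10^{-9}$ on the iterate displacement,
  distance weights clamped at $10^{-12}$ to pass through data points.
* All permutation/Monte-Carlo p-values use the $(1+\text{count})/(B+1)$
  estimator.
* One master seed per run; each stage derives its own substream
  deterministically, so adding a stage never perturbs another stage's
  randomness.

Problem sizes in the test suite (596 × 63 tables, 200-replicate calibration
experiments with 99 inner replicates, $10^6$-sample Monte-Carlo hull
oracles) were chosen as the smallest sizes at which the binomial/Monte-Carlo
standard errors are tight enough for the stated tolerances to be meaningful.

# Known limitations

* The incomplete-data PCA recipe (available-case means, pairwise-deletion
  covariance, observed-terms scores) is a documented stand-in for the
  published incomplete-PCA approach it emulates, validated against classical
  PCA on complete data; with more than a few percent missingness the
  pairwise covariance can lose positive semi-definiteness noticeably and
  scores become biased toward 0 for poorly observed taxa.
* Uniform/normal null models are conservative (see above); interpret
  occupancy percentages, not their p-values, when the test does not reject.
* Convex hulls measure the occupied *envelope*: they are sensitive to
  extreme taxa (hence the 95% trimming option) and say nothing about density
  inside the hull. Kernel or trait-probability-density hypervolumes are out
  of scope.
* Hull volumes above ~6 dimensions are combinatorially expensive; the
  default of 4 geometric axes is also a practical ceiling at hundreds of
  taxa.
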