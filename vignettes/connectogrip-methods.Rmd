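---
title: "Methods: grip performance, sensorimotor connectomes, and two-level network factorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grip performance, sensorimotor connectomes, and two-level network factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectogrip)
```

# The problem

After a stroke, upper-extremity impairment is heterogeneous: some
survivors mainly lose grip strength, others the ability to initiate or
terminate a grip quickly, or to control the magnitude and direction of
fingertip forces. `connectogrip` implements a pipeline for asking
whether *different* aspects of hand grip performance relate to the
structural connectivity of *different* sensorimotor brain networks:

1. extract five grip performance measures from three-axis digit-force
   recordings;
2. build corrected structural-connectivity matrices from tractography
   streamline counts over a 20-region sensorimotor set;
3. identify latent networks with a two-level exploratory factor
   analysis of the connectome edges;
4. regress each performance measure on each network score while
   controlling for the lesion load of that network.

Because clinical MRI + force datasets of this kind are small and rarely
shared, the package also contains a first-class synthetic-cohort
generator with planted ground truth; every stage is verified against
quantities that are known by construction.

# Grip performance measures

A trial records thumb and index forces on two parallel grip surfaces at
500 Hz: a normal component $F_n$ (into the surface) and two tangential
(shear) components $F_{t1}, F_{t2}$, all in newtons. The scalar *grip
force* of a trial is the arithmetic mean of the two digits' normal
components. The mean rather than the sum is used because opposing
normal forces on parallel surfaces are ideally equal, so the mean keeps
the units and scale of one digit's force; `combine = "sum"` is
available.

The five measures, and the parameters that govern them
(see `grip_config()`):

* **Strength** — peak grip force during a maximum-grip trial.
* **Reaction time** — from the grip cue to grip initiation, defined as
  the first sample at which grip force exceeds the pre-cue baseline
  mean by 3 baseline SDs. The baseline window is the 0.5 s ending at
  the cue (250 samples at 500 Hz — long enough for stable statistics,
  short enough to avoid drift). The threshold condition must persist
  for 20 ms (10 samples): a single-crossing rule is fragile against
  isolated noise spikes, and the sustain requirement changes clean
  detections by at most one sample. The baseline SD is floored at
  $10^{-3}$ N so noiseless (synthetic) traces still have a
  finite-width detection band.
* **Relaxation time** — mirror image: from the rest cue until grip
  force returns to within 3 SDs of baseline, with the same sustain
  rule.
* **Force magnitude control** — absolute difference between the 4 N
  target and the mean grip force over the *hold window*. "During grip"
  is ambiguous; the hold window is taken as onset + 0.5 s through the
  rest cue, excluding the rise transient, which stabilizes both the
  mean-force and direction metrics. `transient_s = 0` reproduces the
  literal onset-to-rest-cue reading.
* **Force direction control** — per sample and digit, the angular
  deviation of the force vector from the surface normal,
  $\theta = \operatorname{atan2}\!\big(\sqrt{F_{t1}^2 + F_{t2}^2},\, F_n\big)$
  in degrees, averaged over hold-window samples with force magnitude
  above 0.1 N (below that no direction is defined), then averaged
  unweighted over the two digits. This is invariant to rotation of the
  shear plane about the normal and to uniform scaling of the force
  vector.

Crossings not found within `max_latency_s = 5` s mark the metric
invalid for that repetition; invalid repetitions are excluded from the
per-hand averages, mirroring manual quality screening. Repetitions are
averaged per hand and each measure is normalized as the paretic value
over the sum for both hands, $p/(p+q) \in [0,1]$, with 0.5 meaning
hand symmetry.

# Connectome construction

Inputs are directed streamline counts $n(i \to j)$ between 20
sensorimotor regions: precentral, Rolandic operculum, postcentral and
supplementary motor area, putamen, caudate, pallidum and thalamus —
all bilateral, labelled ipsi-/contralesional — plus the corticospinal
tract at the medulla (pyramid) and midbrain (cerebral peduncle) and the
corticoreticular pathway at the medulla and midbrain. Probabilistic
tracking is directional, so counts are symmetrized by averaging the
two directions. Counts fall off with inter-region distance and scale
with region size; the corrected weight is

$$w_{ij} = s_{ij}\, d_{ij}^{\alpha} \,/\, (v_i + v_j)^{\beta},
\qquad \alpha = \beta = 1,$$

with $d_{ij}$ the centroid distance (mm) and $v_i$ the region volume
(mm^3^). The published correction this follows is cited rather than
printed in the source literature, so the exponents are explicit
configuration: $\alpha=\beta=0$ disables the correction, and the
formula lives in one function (`correct_connectivity()`) so
alternatives (e.g. dividing by a volume product) are one-line swaps.
The summed volume was preferred to the product because it keeps the
correction on the scale of a single region's size and is the milder of
the two penalties.

A cohort is assembled as a participants-by-edges table over the
$\binom{20}{2} = 190$ undirected edges, in a fixed lexicographic edge
order so loadings are comparable across runs.

# Two-level network factorization

**First level.** Separately for each region $i$, a factor analysis is
fitted to the 19 edges incident to $i$ across participants, yielding
region-level factors ("how region $i$'s connections covary").

**Second level.** The pooled first-level factor scores (all regions)
enter one further factor analysis; its factors are the latent
*networks*, ordered by explained variance.

Both levels share one engine (`fit_factor_model()`) with four
configurable choices, defaulting to the classic defaults of the
statistics packages this style of analysis is usually run in:
principal-component extraction (eigendecomposition of the sample
correlation matrix), Kaiser retention (eigenvalue > 1), varimax
rotation, and regression-method scores. Principal-axis extraction and
fixed-$k$ retention are available. Numerical conventions fixed for
reproducibility: factors are ordered by descending explained variance;
within each factor the largest-magnitude loading is made positive;
scoring uses the Moore–Penrose pseudoinverse, $S = Z R^{+} \Lambda$,
because with $n$ participants $< 19$ edges the first-level correlation
matrices are singular by construction — the clinical regime must not
crash the pipeline. Score columns are re-standardized to unit SD.
Zero-variance edge columns are dropped with a warning before
correlation.

**Composite edge weights.** A network is reported in terms of original
edges. Every edge appears in the incident views of its two endpoint
regions and possibly in several factors; each (region, factor) pair
contributes a candidate
$\text{loading}(e \to p) \times \text{loading}(p \to g)$. The
composite weight keeps the candidate of largest magnitude (sign
preserved) — the dominant path — because summing paths lets many small
contributions swamp the interpretable one; `combine = "sum"` is
available. Edges with $|w| \ge 0.4$ are reported, at most the top 6
per network, ties broken by edge label order.

**A caution on Kaiser retention.** The eigenvalue-greater-than-one rule
ignores sampling fluctuation. For $p$ uncorrelated variables and $n$
observations, sample correlation eigenvalues spread up to roughly
$(1+\sqrt{p/n})^2$, so with edge counts and pooled factor counts that
are not tiny relative to $n$ the rule retains many noise factors at
both levels — at $n$ near 20 (a realistic clinical cohort) *most*
retained factors are of this kind, and even at $n = 300$ the second
level retains dozens of bulk factors alongside the planted ones. The
package therefore treats the retained factor *count* as descriptive,
not inferential: planted networks separate cleanly from the bulk by
eigenvalue and are recovered with high Tucker congruence (the
`match_factors()` / `tucker_congruence()` utilities align recovered
and reference networks), but the count itself should not be read as
the number of real networks. `retention = "fixed_k"` and inspection of
the scree (`autoplot()` on a fitted model) are the recommended
controls.

# Lesion-adjusted associations

Per-region lesion fractions are aggregated to one covariate per
network: region memberships are the largest absolute composite weight
over the region's incident edges (continuous, unthresholded, so every
network has a nonzero denominator — the 0.4-thresholded reported
edges would zero out some networks), and the network lesion percent is
the membership- and volume-weighted mean lesioned fraction times 100.

Each (network, measure) cell is an OLS fit of the measure on the
network score plus that network's lesion percent, all three variables
standardized, so the reported slope `beta` is on the correlation scale.
`partial_r` is the partial correlation of measure and score given
lesion load (computed by residualizing both on lesion; an independent
closed form over the three pairwise correlations is used as the test
oracle). Variance inflation factors are reported for both predictors
with a warning above 10; perfect collinearity yields `Inf`, not an
error. No multiple-testing correction is applied — p-values are
reported descriptively and never used for selection. Per measure, the
network with the largest $|$`partial_r`$|$ is flagged (ties to the
lowest network index, with a warning), the uncontrolled grid is
computed alongside, and the table records whether the best-network
calls agree with and without lesion adjustment.

# The synthetic cohort generator

`cohort_spec()` defaults describe the situation the pipeline targets:
22 participants; 500 Hz trials with a grip cue at 2 s, rest cue at
4 s, 4 N target, three repetitions per condition and hand; the
20-region set; 3 planted networks over disjoint region groups with
in-network composite weights drawn from $[0.4, 0.9]$; log-normal
streamline counts (baseline log-count 5, i.e. about 150 streamlines;
log-noise SD 0.3) rounded and split into two directions by a small
jitter; performance ratios centred and scaled like observed cohorts
(means 0.39–0.54, SDs 0.11–0.35), coupled to the latent scores with
standardized effects 0.35 by default; and logistic-normal lesion
fractions around 5% whose logits fall with the region's network score
(coupling 0.5) and which in turn depress performance (direct effect
0.2) — so lesions confound the network-performance relation in the
direction stroke anatomy suggests, and the lesion covariate can be
shown to correct estimates toward the planted effect.

Grip traces are built backwards from planted metric values: baseline
contact force 0.2 N, a quarter-sine rise timed so the 3-SD band
crossing falls exactly at the planted reaction time, a constant hold
at 4 N plus the planted magnitude offset, a quarter-sine fall timed
the same way for the planted relaxation time, and shear components set
so each digit's force angle equals the planted direction error. At
zero trace noise, re-extracting metrics recovers the planted values to
one sample period (times), 0.05 N (forces) and 0.1 degrees (angles) —
the round-trip that ties the generator to the extractor. Per-hand true
values come from inverting the generated ratios against normative
nonparetic values, clamped to physically synthesizable ranges.

One top-level seed expands into fixed per-component child seeds, so
latents, counts, lesions, measures and trials can be regenerated
independently and the whole bundle is byte-stable under a fixed spec.

What the generator does *not* emulate: brain geometry or tractography
artifacts (counts are conditionally log-normal given the latents, with
no spatial autocorrelation beyond the planted structure), fatigue or
learning across repetitions, non-Gaussian sensor noise, and
per-participant differences in normative nonparetic performance beyond
the ratio inversion. Passing tests therefore demonstrate that the
*statistical machinery* recovers planted structure under realistic
dimensions and noise — not that real tractography counts satisfy the
model.

# Verification scales

The test suite and `scripts/acceptance.R` verify, among others: the
metric round trip on 200 noiseless trials; factor loadings, varimax
communalities and regression scores against independent linear-algebra
oracles (tolerances 1e-8 to 1e-10); two-level recovery at $n = 300$
(planted-network congruence of matched composite weights); partial-
correlation calibration at $n = 100$ and type-I error at $n = 50$;
confounding correction at $n = 200$; and end-to-end best-network
identification with five planted drivers at $n = 150$. These sizes
were chosen to make sampling noise small relative to the planted
effects while keeping the full verification run in minutes on one CPU.

# Known limitations

* The retained-factor count under Kaiser retention is inflated by
  sampling noise (see above); treat it as descriptive.
* The correction exponents $(\alpha, \beta)$ are a modelling choice,
  not an estimate; sensitivity analyses over them are one config edit.
* With 22 participants nothing in the association stage is powered for
  significance; the pipeline reports effect sizes and best-network
  structure, not hypothesis tests.
* The composite-weight "dominant path" rule discards secondary paths
  by design; use `combine = "sum"` to see their aggregate.
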