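---
title: "Cross-recurrence metabolic networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-recurrence metabolic networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Teeth record elemental exposure longitudinally: laser-ablation ICP-MS scans
of dentine yield, for each child, a time series of metal:calcium intensity
ratios spanning from mid-gestation into the second year of life (the
package's default window is −143 to +389 days relative to birth). Elemental
metabolism is coupled — uptake and deposition of one element track shared
physiological rhythms and interact with other elements — so the scientific
object of interest is not any single profile but the *architecture of
coupling* between elements, and how a toxic exposure (lead) perturbs it.

`recurnet` quantifies that architecture in four stages:

1. **Attractor reconstruction.** Each element's series is standardized and
   delay-embedded (Takens embedding), with delay `tau` chosen at the first
   local minimum of the average mutual information (AMI) and dimension `m`
   chosen by minimizing the Kennel false-nearest-neighbour (FNN) fraction.
2. **Cross-recurrence quantification (CRQA).** For each pair of elements
   within a subject, a cross-recurrence matrix marks which embedded states
   of one series fall within a radius ε of states of the other. Two
   summaries are extracted: the recurrence rate (RR, a non-linear coupling
   proxy) and the Shannon entropy of diagonal line lengths (periodicity
   complexity shared by the pair).
3. **Per-subject networks.** The seven network elements (Ba, Cu, Li, Mg,
   Mn, Sr, Zn) become nodes; RR or entropy values become edge weights.
   Edges below the cohort-global median (per edge definition) are excluded,
   retaining only non-trivial connections; six node metrics are computed
   (strength, closeness, betweenness, eigenvector centrality, local
   clustering, eccentricity).
4. **Exposure inference.** Subjects are dichotomized into high/low lead
   groups by a median split of their mean Pb profile, and each metric is
   modelled as `value ~ Element + Pb + Element:Pb + (1 | subject)` by REML,
   with Wald tests of the lead main effect (averaged over elements) and of
   per-element high-vs-low contrasts.

Lead is an exposure marker only: it is never a network node.

## Threshold (ε) rules

Two ε rules are carried side by side, matching the two edge definitions:

* **Diameter rule** (RR edges): ε = 10% of the joint phase-space diameter —
  the exact maximal pairwise distance over the union of both trajectories'
  points. RR then varies freely between pairs and *is* the signal.
* **Fixed-RR rule** (entropy edges): ε is calibrated so the recurrence rate
  hits 0.1, making recurrence density comparable across pairs so that the
  diagonal-line structure, not the density, drives the edge weight. Because
  RR is a step function of ε jumping exactly at the pairwise distances, the
  calibration sorts/selects order statistics rather than root-finding: the
  returned ε is the smallest pairwise distance whose achievable rate
  `k/(N1·N2)` is closest to the target. With ~2 × 10⁴ distances per pair the
  achievable grid is fine enough that the default tolerance 10⁻³ is met
  except in highly degenerate (massively tied) cases, which raise a warning.

Numerical conventions: distances are Euclidean by default (a maximum-norm
option is provided, since recurrence toolboxes differ); the threshold is
inclusive (distance = ε counts as recurrent); both series in a pair share
one `(m, tau)` by pairwise maximum, so neither is under-embedded; series
are z-scored first so ε values are comparable across pairs.

## Diagonal-line entropy

A line is a maximal run of recurrent cells along any diagonal of the (in
general rectangular) matrix; runs of length ≥ 2 are counted by length and
the entropy is `−Σ p(ℓ) ln p(ℓ)` in nats (a log2 option exists). No Theiler
window is applied: a cross-recurrence matrix between distinct elements has
no trivial identity line. An empty histogram has entropy 0.

A direction worth stating explicitly, because intuition can go either way:
under the fixed-RR rule a strongly periodic, strongly coupled pair shows
*higher* diagonal entropy than a noise pair. Its recurrent diagonals are
long but truncated at the matrix edges to many different lengths, while
white noise concentrates its few runs at lengths 2–3. This is what makes
reduced coupling (more noise-like dynamics) show up as *lower* entropy-edge
weight, and hence lower entropy-edge degree, in the group comparisons.

## Embedding-parameter selection: validity regimes

Two properties of the selectors matter for interpreting results and for
what the tests can show:

* The histogram AMI of a *noise-free* sinusoid saturates: past a modest lag
  the binned joint distribution stops changing, the curve plateaus well
  before the quarter period, and the "first local minimum" lands at the
  plateau edge. With additive noise the AMI behaves like the Gaussian form
  `−½ ln(1−ρ²)` and has a sharp quarter-period minimum. Delay recovery is
  therefore exercised on noisy sinusoids (n = 4000, noise SD 0.5, 16 bins),
  where the selected delay is 10 ± 1 across seeds.
* The Kennel FNN criterion assumes low observational noise: noise occupies
  all dimensions, so as the sampling density grows the neighbour distance
  shrinks while the extra-coordinate separation stays at the noise scale,
  and the false fraction rises at every `m`. Dimension recovery is
  therefore exercised on a clean sinusoid, with a period incommensurate
  with the sampling grid (40.49 samples) so no embedded point is revisited
  exactly — exact revisits make the distance-ratio test a 0/0 coin flip.
  When the m-dimensional neighbour distance is exactly zero the ratio
  criterion is skipped and only the absolute criterion applies.

Defaults: AMI uses equal-width bins, `min(32, floor(sqrt(N)))` per axis,
maximum lag 30; FNN uses `r_tol = 10`, `a_tol = 2`, candidate dimensions
1–10 (reduced so at least 10 embedded points remain). On real cohort-like
data (strong autocorrelated noise) selected delays are often small (1–5)
and dimensions 3–7; the pairwise-maximum rule then governs the shared
embedding.

## The synthetic cohort generator

The study cohort is not public, so the generator is a first-class module
that emulates the statistical structure the pipeline assumes — it defines
the package's study conditions, and its defaults are fixed, not tuned:

* **Grid**: 150 evenly spaced points spanning exactly −143 to +389 days.
  The density is a design choice (the source data's per-profile sampling
  density is not stated): dense enough that ≥ 100 points survive embedding,
  sparse enough for fast CRQA.
* **Latent cycles**: periods 7, 91 and 365 days (circaseptan, quarterly,
  seasonal), with per-subject random phases *shared across elements*. Two
  elements loading on the same cycle inherit correlated dynamics — this is
  the coupling CRQA measures. Note the 7-day cycle sits at the grid's
  Nyquist edge (spacing ≈ 3.6 days) and contributes aliased fast structure,
  which is realistic for biomarker sampling.
* **Signal model**: log-scale signal = Σ loadings × sin(2πt/P + φ) + AR(1)
  noise (marginal SD 0.3, lag-1 correlation 0.4), exponentiated and scaled
  by element-typical magnitudes, keeping values positive and right-skewed
  like concentration data.
* **Exposure**: a balanced random high/low split. High-exposure subjects'
  loadings are multiplied element-wise by `group_effect` (all 1 under the
  null), and their Pb series is shifted by +0.6 on the log scale — a level
  shift, not a coupling change, so exposure recovery by the Pb median split
  and coupling effects are independently controllable.

What the generator does **not** emulate: instrument physics, ablation
geometry, dentine histology, irregular or subject-specific sampling grids,
non-stationary growth trends, or heavy-tailed measurement artifacts.
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
internal correctness and statistical calibration under the assumed
structure, not fidelity to any particular instrument's noise.

## Statistical model and conventions

One mixed model per (metric, edge definition) — 12 fits by default. Element
is dummy-coded with Ba (alphabetically first) as reference; contrasts are
parameterization-invariant, so the choice is cosmetic. The lead main effect
is the Wald test of the marginal high-vs-low difference,
`β_Pb + mean(interactions) = 0`; per-element contrasts test
`β_Pb + β_{e:Pb} = 0`. P-values use standard-normal Wald statistics by
default (the degrees-of-freedom method is otherwise a free choice;
Satterthwaite via lmerTest is available as `df_method`). Per-element
p-values are reported raw, mirroring how such tables are usually presented;
Benjamini–Hochberg is a flag. A singular random-intercept fit is flagged,
not fatal. The median split of subject-mean Pb is the minimal-assumption
dichotomization (ties go to the low group); a pre-specified grouping can be
supplied instead.

Disconnection conventions are chosen so every subject yields finite
metrics: closeness uses the Wasserman–Faust correction
`(r/(n−1))·(r/Σd)` over the `r` reachable nodes, eccentricity is the
maximal *finite* distance, and isolated nodes score 0. Path metrics use
length = 1/weight; clustering uses the Onnela geometric-mean form; the
eigenvector centrality is the leading eigenvector of the weighted adjacency
(non-negative, unit Euclidean norm; all-zero for an empty graph). Retained
edges keep their weights (a binarize flag exists), and ties at the median
threshold are retained — exclusion applies to values strictly below it.

## Calibration and power properties

Simulation experiments shipped in the test suite (sizes chosen to keep the
default run in minutes):

* **Type-I error**: 200 null cohorts (40 subjects, `group_effect = 1`)
  through the full pipeline; the main-effect test on network degree rejects
  at the 5% level at close to the nominal rate. These cohorts use an
  80-point grid — null validity is a property of group exchangeability, not
  of the grid length, and the shorter grid keeps 200 full-pipeline
  replicates in a few minutes.
* **Directional recovery**: with loadings suppressed for Zn and Mg (×0.4)
  and enhanced for Li (×1.8) in the high group — a strong exposure
  contrast — the per-element entropy-edge degree contrasts come out
  negative for Zn and Mg and positive for Li in the large majority of 50
  replicates (80 subjects, default grid). The cohort size matters here as a
  power question: suppressing two elements' coupling damps *every*
  element's entropy-edge degree (edges are pairwise and the median
  threshold is pooled), so the lithium contrast is only modestly positive
  in the population and smaller cohorts recover its sign less reliably.
* **Estimator consistency**: per-element contrast estimates concentrate
  around the configured shift as the subject count grows.

## Known limitations

* Embedding-parameter selection on short (~150-point), noisy series is
  rough; the AMI/FNN defaults are standard but not optimal for every
  signal class, which is why both are exposed as configuration (including
  per-element pooling).
* The fixed-RR calibration reports, not hides, coarse achievable-rate grids
  (a warning when |achieved − target| > 10⁻³).
* Wald z p-values are mildly anti-conservative at small cohort sizes;
  Satterthwaite is available when lmerTest is installed.
* CRQA metrics beyond RR and diagonal entropy (determinism, laminarity,
  trapping time) are out of scope, as are community detection and global
  network summaries.
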