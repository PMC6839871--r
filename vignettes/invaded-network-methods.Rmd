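---
title: "Methods: plant–floral-visitor networks in invaded communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant–floral-visitor networks in invaded communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invanet)
```

## The question and the data model

When alien plants invade a community, do they disrupt the native
plant–pollinator interaction network, or do they slot into it and carry the
same structural load as natives? `invanet` implements the comparative
workflow for answering this at the community level: per-site bipartite
interaction matrices (rows = plants, columns = floral visitors, cells =
observed visit counts), species metadata including each plant's origin
(native vs alien) and flower abundance, mixed-type floral trait tables, and
long-format plot × day visit records.

Two conventions matter everywhere downstream. First, matrix orientation is
fixed (plants × visitors). Second, plants recorded flowering but never
visited — and visitors never observed — stay in the community metadata but
are excluded from network metrics; `drop_empty()` removes all-zero rows and
columns (with a warning) before any structural computation, since a species
without interactions carries no network information but is still part of the
pollination environment.

## Network-level metrics

**NODF nestedness** operates on the binarized matrix. For every pair of rows
(and of columns) whose marginal totals strictly differ, the paired overlap
is 100 × (shared presences)/(presences of the poorer species); ties and
empty species contribute 0; NODF is the mean over all pairs, 0–100. Weights
are deliberately not used — NODF is a presence–absence concept, and the
binarize-for-nestedness / weight-for-specialization split matches how these
metrics are conventionally computed, even though field studies rarely state
it.

**H2′ specialization** uses the weights. With interaction proportions
*p<sub>ij</sub>*, the two-dimensional Shannon entropy H2 = −Σ *p* ln *p* is
standardized between the extreme entropies achievable by non-negative
*integer* matrices with the observed marginal totals:
H2′ = (H2max − H2)/(H2max − H2min), clamped to [0, 1]. The extremes are
found heuristically:

- *H2min* (maximal specialization): greedy packing — repeatedly allocate
  min(largest remaining row total, largest remaining column total) to that
  cell.
- *H2max* (maximal generalization): the proportional table
  *r<sub>i</sub>c<sub>j</sub>*/m, floored, with remaining units placed by
  largest remainder wherever row and column capacity remains.
- Both tables are then polished by hill-climbing over margin-preserving 2×2
  rebalances (move one unit around a 2×2 cycle when it improves the
  objective). Every accepted move keeps a feasible integer matrix, so the
  heuristic extremes are contained in the exact enumeration bounds by
  construction; the test suite verifies this, and equality with the
  exhaustive oracle, on all its small-margin enumeration sets (≤ 12 cells,
  marginal totals ≤ 8). The polish is skipped above 500 total visits, where
  the integer grid is fine enough that packing/repair already sit at the
  extremes for practical purposes.

One consequence worth knowing: because the extremes are integer-constrained,
H2′ is *not* exactly invariant to uniformly scaling all counts. The exact
(exhaustively enumerated) H2′ shifts with scale at very small totals too —
this is a property of the integer-constrained definition, not of the
heuristic. The suite asserts exact scale invariance for the two components
where it genuinely holds (the observed entropy and the packed minimum) and
stability of H2′ between moderate and large totals.

**Barber bipartite modularity** for a module partition *g* is
Q = (1/m) Σ<sub>ij</sub> (A<sub>ij</sub> − k<sub>i</sub>d<sub>j</sub>/m)
[*g<sub>i</sub>* = *g<sub>j</sub>*], summed over plant–visitor pairs only.
`optimize_modularity()` maximizes Q by simulated annealing over partitions
with three move types (reassign one species, including to a fresh module;
merge two modules; random split), geometric cooling (factor 0.95), 50·(r+c)
moves per temperature, stop after 20 improvement-free temperatures, and an
initial temperature set from a pilot sample of downhill move sizes so that
roughly 80% of them would be accepted. The single-module partition (Q = 0
identically) is the fallback, so reported Q is never negative. On every ≤
8-species instance in the test suite the annealer reaches the exhaustive
optimum over all set partitions.

**Robustness** R is the area under the attack-tolerance curve: plants are
removed in random order (plant removal is the default, matching the
extinction-scenario framing; visitor removal is available by flag) and a
visitor goes secondarily extinct when all of its partners are gone. The
curve plots the surviving fraction of the opposite guild against the
fraction removed, includes the endpoints (0, 1) and (1, 0), and is averaged
over `n_orders` random orders before trapezoidal integration. These
conventions are stated because the numeric value depends on them. Note that
the secondary-extinction rule involves *no* rewiring: interaction weights
are never reallocated to surviving plants. Field descriptions of the
commonly cited routine sometimes claim rewiring; the documented behaviour of
that routine is the plain secondary-extinction rule, which is what is
implemented here — no alternative mechanism is guessed.

## Null models

The CE (degree-proportional) null assigns each cell an occupancy probability
that is the mean of its row's and column's degree fractions,
*p<sub>ij</sub>* = (*k<sub>i</sub>*/c + *d<sub>j</sub>*/r)/2, and draws
independent Bernoulli matrices. Draws with an empty row or column are
redrawn up to 100 times, then kept with a flag — a redraw cap rather than
marginal-preserving swaps, to stay faithful to the Bernoulli formulation.
The same null serves the nestedness test (default 1000 replicates) and the
modularity test (default 100 replicates, since each replicate requires an
annealing run); the tool chain this mirrors labels the model both "CE" and
"Model III", and both labels refer to the formula above. p-values are
one-sided (fraction of null values ≥ observed) because for both metrics
"structured" means larger; z = (obs − mean)/sd, reported as 0 when the null
is degenerate at exactly the observed value and as missing otherwise when
sd = 0.

The per-species **nestedness contribution** randomizes only the focal
species' presence vector under its CE probabilities, holding everyone else
fixed, and reports (NODF<sub>obs</sub> − mean NODF*)/sd NODF* over 100
draws by default. The reference this follows names no null; using the CE
probabilities keeps the species-level and network-level tests on one model.

## Floral traits

Gower distance averages, over usable traits, |x−y|/range for quantitative
traits and 0/1 mismatch for categorical ones; traits with missing values or
zero range are excluded from the mean (a zero-range trait distance is
undefined, and exclusion under a mean — unlike a sum — leaves comparable
scales). Ranges are community-level and supplied explicitly so per-pair
distances are comparable within a site. The per-species similarity index is
*s<sub>i</sub>* = 1 − mean distance to all co-occurring species; the field
phrase "1 − average similarity of pairwise distances" conflates similarity
and distance, and 1 − mean distance is the only reading consistent with a
"degree of similarity". Chromatic coordinates enter the Gower computation
as two ordinary quantitative traits; hexagon-specific colour distances are
not used.

`hexagon_coordinates()` computes those coordinates from spectra: per
receptor (UV, blue, green), the quantum catch is the trapezoidal integral of
reflectance × sensitivity × illuminant; catches are normalized by the
background catch (von Kries adaptation) and passed through E = I/(I+1), so
the background sits at E = 0.5 in every channel; then
X = (√3/2)(E<sub>G</sub> − E<sub>UV</sub>) and
Y = E<sub>B</sub> − (E<sub>UV</sub> + E<sub>G</sub>)/2. Receptor
sensitivities, illuminant and background are user inputs, not bundled
constants.

## Extinction scenarios and effect sizes

Three removal scenarios are compared with the intact network:
`aliens_removed` (deterministic: drop every alien plant),
`natives_removed` and `random_removal` (uniform random subsets of the same
size as the site's alien count; whether the original analysis removed
natives with abundance-weighted probability is unstated, so uniform sampling
is used). Visitors orphaned by a removal are dropped before metrics are
recomputed, consistent with the secondary-extinction rule. Stochastic
scenarios default to 100 replicates with per-replicate values retained.

Scenario contrasts are summarized by bias-corrected Hedges' g:
SD<sub>pooled</sub> = √(((n₁−1)s₁² + (n₂−1)s₂²)/(n₁+n₂−2)),
J = 1 − 3/(4(n₁+n₂)−9), g = J(M₁−M₂)/SD<sub>pooled</sub>, with a normal
approximate 95% CI. Arithmetic percent change 100·(M₂−M₁)/M₁ is always
reported next to g: published "Δ% according to effect size" tables cannot
generally be reproduced as either quantity alone, so both are given and
neither is guessed into the other.

## Sampling completeness

Interaction accumulation permutes survey samples (site-days by default, nine
per site in the emulated design) without replacement, 500 randomizations,
and reports the mean ± sd cumulative count of distinct plant–visitor pairs.
Chao1 uses the classic form S + F1²/(2F2) when doubletons exist and the
bias-corrected form S + F1(F1−1)/(2(F2+1)) when F2 = 0 (the switching rule
of the standard estimator software; both variants are always retrievable),
and completeness is 100·S/Chao1.

## The synthetic-community generator

The generator exists so that every stage is testable end to end without
field data. Its defaults encode the study conditions: 8–17 plants and 22–38
visitors per site, alien species proportion 0.22–0.50, alien flower share
targets spanning 0.11–0.99 across a nine-site study, per-site visit totals
504–3335 in a single multinomial draw, and a designated super-generalist
visitor whose propensity column is scaled to an expected 57.5% visit share.

Mechanism, per site (all randomness in a per-site substream of the master
seed):

1. **Abundances**: log-normal flower counts (sdlog 1.2); alien counts are
   rescaled so the alien flower share hits the site's target (the suite
   checks recovery within ±0.02 averaged over 200 sites).
2. **Traits**: five quantitative floral traits (height, corolla diameter,
   corolla opening — 0 in the ~85% of species modelled as non-tubular, as
   befits a dune flora of mostly open flowers — and two chromatic
   coordinates). Species share a per-species deviation scale across traits
   (morphological integration) drawn from a heavy-tailed lognormal: most
   species sit near the community centroid while occasional divergent
   phenotypes stretch the community ranges. This is what keeps
   range-normalized Gower similarity high (community means ≈ 0.72–0.78,
   bracketing the ≈ 0.79 reported for the emulated system) — independent
   per-trait draws cannot reach that level.
3. **Preferences**: each visitor anchors on the phenotype of one plant
   (plus noise) and receives a diet breadth multiplier ~ lognormal(0,
   0.75). Interaction propensity is
   w<sub>ij</sub> = flowers<sub>i</sub><sup>α</sup> ·
   activity<sub>j</sub><sup>β</sup> ·
   exp(−γ<sub>i</sub> b<sub>j</sub> · Gower mismatch<sub>ij</sub>).
   α = 0.6 < 1 makes per-flower visitation rate decline with abundance
   (the sign the suite checks by regression); γ = 0 gives the
   abundance-driven, strongly nested and generalized regime, while the
   default γ = 300 (large because typical Gower mismatches are only
   0.02–0.1) combined with the breadth gradient yields networks with
   specialization, connectance and robustness in the emulated system's
   range and a majority of sites significantly nested under the CE null.
   The breadth gradient is essential: uniform strong specialization
   produces disconnected trait modules (anti-nested against the null),
   whereas a generalist-to-specialist gradient produces *nested*
   specialization, the structure actually observed in mutualistic webs.
   `gamma_alien` overrides γ for alien plants only (0 plants
   super-generalist aliens — the planted effect the suite recovers as a
   sign test on nestedness loss); δ shifts alien trait means, with δ = 0
   the origin-blind null case under which aliens-removed and
   natives-removed scenarios are statistically equivalent (mean |g| < 0.3
   across 100 sites in the suite).
4. **Surveys**: each visit is attributed uniformly to one of 9 days × 10
   plots and aggregated to long-format records (15 observed minutes per
   plot-day), feeding the accumulation/Chao1 machinery.

What the generator does *not* emulate: day-to-day and plot-level
heterogeneity in visitor activity (visits are spread uniformly, so
accumulation curves saturate somewhat faster than patchy real surveys);
phylogenetic trait structure; within-season phenology; and visitor-side
origins (all visitors are treated as a native pool with one introduced
super-generalist). Passing tests therefore demonstrate that the *methods*
recover planted structure under realistic sizes and noise — not that any
particular field system behaves like the generator.

## Numerical choices and degenerate inputs

- Round-half-up for flower-count estimates (`floor(x + 0.5)`), so 7.5 → 8.
- Visitation rate defaults to one 15-minute plot-day as the observation
  period; zero flower counts give missing rates, never infinities.
- Metrics require ≥ 2 rows and columns after dropping empties; scenario
  replicates that reduce a site below that report missing values rather
  than failing the run.
- Seeds: every stochastic routine takes an explicit seed, restores the
  caller's RNG state, and derives per-replicate substreams below 2³¹.
- Tie-breaks: greedy packing and repair use first-maximum selection
  (`which.max`), making the heuristics deterministic.

## Problem sizes in the test suite

The suite runs the exhaustive oracles at the scales where exhaustion is
exact and cheap: all integer matrices for margin sets up to 12 cells with
totals ≤ 8; all set partitions for networks of ≤ 8 species (4140
partitions); all removal orders for ≤ 5 plants, against 2000 Monte-Carlo
orders at tolerance 0.01. Generator calibration checks use 50–200 sites per
property; study-level determinism and schema tests use 3–9 sites with
reduced replicate counts. These sizes were chosen so the full suite
exercises every claim in minutes on a single core while keeping every
oracle exact rather than sampled.

## Known limitations

- The H2′ extremes are heuristic above the exhaustively verified range;
  containment in the true bounds is guaranteed by feasibility, but exact
  optimality is only verified for small margins.
- Simulated annealing offers no optimality certificate on large networks;
  the defaults were chosen to be reliable at field-study sizes (≤ ~60
  species), where repeated runs agree.
- The CE redraw-cap policy slightly conditions the null ensemble on
  non-degeneracy for sparse matrices; the unconditional ensemble is
  available by setting the cap to 1.
- Robustness assumes static secondary extinction (no rewiring, no partial
  dependence); treat R as a comparative index, not a forecast.
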