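# invanet

Structure and robustness of plant–floral-visitor networks in invaded plant
communities.

`invanet` is an R package for community ecologists studying how alien
(invasive or exotic) plant species integrate into native plant–pollinator
interaction networks. It was built around the analysis of nine invaded
coastal sand-dune co-flowering communities in Yucatán, México — sites whose
alien flower share spans 11–99% and whose visits are dominated by the
super-generalist honey bee — and packages that whole analysis as tested,
reusable functions:

- **Network-level structure** — NODF nestedness, H2′ network specialization,
  Barber bipartite modularity *Q* maximized by simulated annealing, and
  robustness *R* to sequential plant loss (area under the secondary-extinction
  attack-tolerance curve), plus connectance, links per species and pairwise
  interaction counts.
- **Null-model inference** — the degree-proportional CE null model
  (*p<sub>ij</sub>* = (*k<sub>i</sub>*/c + *d<sub>j</sub>*/r)/2) with
  Monte-Carlo z-scores and one-sided p-values for nestedness and modularity.
- **Species-level roles** — normalized degree, species strength (sum of
  partner dependencies; plant strengths sum exactly to the number of
  visitors), and per-species nestedness contribution (z-score under focal-row
  CE randomization).
- **Floral traits** — mixed-type Gower distances over flower height, corolla
  diameter, corolla opening and chromatic coordinates; per-species similarity
  index *s<sub>i</sub>* = 1 − mean Gower distance; native-vs-alien summaries;
  hexagon chromatic coordinates for trichromatic hymenopteran vision.
- **Extinction scenarios** — aliens-removed, natives-removed and random
  removal (each dropping as many plants as the site holds aliens), recomputed
  metrics, and bias-corrected Hedges' *g* = *J*·(*M₁* − *M₂*)/*SD*pooled with
  percent change reported side by side.
- **Sampling completeness** — interaction accumulation curves, Chao1
  asymptotic interaction richness, and percent completeness.
- **Synthetic communities** — a generator that emulates the statistical
  structure of the study system (species counts, alien flower-share gradient,
  visit totals, a ~57.5% super-generalist, trait similarity ≈ 0.78, negative
  abundance–visitation-rate relation), so the entire pipeline is testable
  without any field data.

## Worked example

Generate one synthetic invaded community and analyse it end to end:

```r
library(invanet)

cfg  <- generator_config(seed = 42)
site <- generate_site(cfg, site_index = 6)
site$community
#> site_community 'site06': 15 plants (6 alien) x 33 visitors, 1168 visits

m <- drop_empty(site$community$counts, warn = FALSE)
network_metrics(m, n_orders = 200, seed = 1)
#> network metrics: NODF 52.60 | H2' 0.406 | Q 0.301 | R 0.700 |
#>   connectance 0.267 | links/sp 1.86 | links 52

significance_test(m, "nodf", n_replicates = 1000, seed = 1)
#> CE null test of nodf: observed 52.596, null 37.898 +/- 5.888 (n = 1000),
#>   z = 2.50, p = 0.0090

group_similarity_summary(site$traits, site$traits$origin)
#> floral similarity: 0.782 +/- 0.106 (native 0.784, n=9; alien 0.779, n=6)

sampling_completeness(site$community, seed = 1)$completeness
#> [1] 83.00512
```

Reading the numbers: the site is significantly *nested* against the CE null
(z = 2.5, p = 0.009) — specialists interact with subsets of the partners of
generalists — with intermediate specialization (H2′ = 0.41 on the 0–1 scale)
and a robustness of 0.70 to random plant loss. Native and alien floral
phenotypes are nearly indistinguishable (similarity 0.78 vs 0.78), the
mechanism thought to let aliens slot into the native network. Sampling
recovered an estimated 83% of the asymptotic interaction richness.

The full study-level pipeline (all metrics, null tests, species roles,
extinction scenarios with effect sizes, completeness, CSV/JSON artifacts):

```r
res <- run_pipeline(pipeline_config(generator_config(seed = 42),
                                    n_sites = 9, out_dir = "out"))
res$effects          # Hedges' g and % change per metric x removal scenario
```

With origin-blind defaults the aliens-removed and natives-removed scenarios
give effect sizes near zero — removing aliens is statistically equivalent to
removing as many natives — while `generator_config(gamma_alien = 0)` plants
deliberately super-generalist aliens whose removal degrades nestedness more
than native removal does.

The bundled published site summaries from the Yucatán survey are available
via `yucatan_sites()`, `yucatan_network_metrics()` and
`yucatan_survey_totals()`.

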