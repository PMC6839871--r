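#' Published site summaries from the Yucatán coastal dune survey
#'
#' Site-level summary table from a field survey of nine invaded coastal
#' sand-dune co-flowering communities along the north coast of the Yucatán
#' Peninsula, México: native and alien plant species counts, the printed
#' alien-species percentage, the proportion of alien flowers, and the mean
#' (+/- SD) native-alien floral-trait similarity per site. Sites are ordered
#' by increasing alien flower share (11-99%). These printed summaries are the
#' calibration targets the synthetic generator emulates.
#'
#' Note: a couple of the printed alien-species percentages are internally
#' inconsistent with the species counts in the same row (e.g. Sisal: 6 alien
#' of 15 species printed as 27%); the table is reproduced as printed and no
#' reconciliation is attempted.
#'
#' @return data frame with columns `site, n_native, n_alien,
#'   alien_species_pct, alien_flower_pct, trait_similarity_mean,
#'   trait_similarity_sd`.
#' @export
yucatan_sites <- function() {
  utils::read.csv(system.file("extdata", "yucatan_sites.csv",
                              package = "invanet"),
                  stringsAsFactors = FALSE)
}

#' Published per-site network metrics from the Yucatán survey
#'
#' Network size and structural metrics (H2' specialization, NODF nestedness,
#' modularity, robustness) reported for the nine surveyed sites, with the
#' nestedness-significance flag (all sites but Charcas significantly nested
#' under the degree-proportional null).
#'
#' @return data frame with columns `site, n_plants, n_visitors, h2prime,
#'   nodf, modularity, robustness, nestedness_significant`.
#' @export
yucatan_network_metrics <- function() {
  utils::read.csv(system.file("extdata", "yucatan_network_metrics.csv",
                              package = "invanet"),
                  stringsAsFactors = FALSE)
}

#' Survey-wide totals from the Yucatán coastal dune survey
#'
#' Headline counts from the same survey: insect floral-visitor species per
#' order, total plant species, total distinct pairwise interactions, total
#' visits and flowers recorded, and the visit share of the super-generalist
#' honey bee.
#'
#' @return a list with elements `visitor_species_by_order` (named integer
#'   vector: Diptera, Hymenoptera, Lepidoptera), `n_plant_species`,
#'   `n_sites`, `total_pairwise_interactions`, `total_visits`,
#'   `total_flowers`, `honeybee_visit_share`.
#' @export
yucatan_survey_totals <- function() {
  list(visitor_species_by_order = c(Diptera = 26L, Hymenoptera = 27L,
                                    Lepidoptera = 20L),
       n_plant_species = 30L,
       n_sites = 9L,
       total_pairwise_interactions = 685L,
       total_visits = 14255L,
       total_flowers = 516609L,
       honeybee_visit_share = 0.575)
}
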