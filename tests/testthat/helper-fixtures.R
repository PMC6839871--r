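# small in-code fixtures shared across tests

make_species_df <- function(plant_ids, visitor_ids,
                            origins = rep("native", length(plant_ids)),
                            flower_counts = rep(100, length(plant_ids))) {
  rbind(
    data.frame(species_id = plant_ids, guild = "plant", origin = origins,
               family = NA_character_, flower_count = flower_counts,
               stringsAsFactors = FALSE),
    data.frame(species_id = visitor_ids, guild = "visitor",
               origin = "not_applicable", family = NA_character_,
               flower_count = NA_real_, stringsAsFactors = FALSE))
}

make_community <- function(counts, origins = NULL, flower_counts = NULL,
                           site_id = "test_site") {
  counts <- as.matrix(counts)
  p <- sprintf("pl%02d", seq_len(nrow(counts)))
  v <- sprintf("vi%02d", seq_len(ncol(counts)))
  origins <- origins %||% rep("native", nrow(counts))
  flower_counts <- flower_counts %||% rep(100, nrow(counts))
  sp <- make_species_df(p, v, origins, flower_counts)
  site_community(site_id,
                 sp[sp$guild == "plant", ],
                 sp[sp$guild == "visitor", ],
                 counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixture with 9 native + 3 alien plants, mirroring a low-invasion site
make_invaded_community <- function(seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(12 * 6, 1.5), 12, 6)
  counts[1, ] <- counts[1, ] + 3   # keep things non-degenerate
  counts[, 1] <- counts[, 1] + 2
  make_community(counts,
                 origins = c(rep("native", 9), rep("alien", 3)),
                 flower_counts = sample(50:500, 12))
}
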