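#' Normalized degree of every species
#'
#' Realized interaction partners divided by possible partners: for a plant,
#' the number of visitor species observed on it divided by the number of
#' visitor species in the network; symmetrically for visitors.
#'
#' @param matrix non-empty plants x visitors matrix.
#' @return list with numeric vectors `plants` and `visitors`, named by
#'   dimnames where present.
#' @export
normalized_degree <- function(matrix) {
  m <- as.matrix(matrix)
  if (length(m) == 0) stop_invanet("empty_matrix", "empty matrix")
  list(plants = rowSums(m > 0) / ncol(m),
       visitors = colSums(m > 0) / nrow(m))
}

#' Species strength
#'
#' Strength of a plant is the sum over visitors of that visitor's dependency
#' on it, a_ij / A_j with A_j the visitor's column total: how much of its
#' partners' activity the plant supports. Plant strengths sum exactly to the
#' number of visitor species with at least one visit. `side = "visitors"`
#' gives the mirrored quantity from row-wise dependencies.
#'
#' @param matrix non-empty count matrix.
#' @param side "plants" (default) or "visitors".
#' @return numeric vector of strengths. Zero-total partner columns (rows) are
#'   excluded with a warning.
#' @export
species_strength <- function(matrix, side = c("plants", "visitors")) {
  side <- match.arg(side)
  m <- as.matrix(matrix)
  if (side == "visitors") m <- t(m)
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d partner column(s) with zero total from strength",
                    sum(tot == 0)), call. = FALSE)
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (length(tot) == 0) stop_invanet("empty_matrix", "no interactions")
  dep <- sweep(m, 2, tot, "/")
  rowSums(dep)
}

#' Nestedness contribution of one species
#'
#' z-score of the observed network NODF against a null where only the focal
#' species' presence/absence vector is randomized: the focal row (or column)
#' is replaced by independent Bernoulli draws under its CE probabilities
#' (see [ce_probability_matrix()]) while every other species keeps its
#' observed interactions. Positive values mean the species' observed
#' interactions make the network more nested than its degree alone explains.
#'
#' @param matrix count or binary matrix (binarized internally).
#' @param focal_species row/column name, or index when `guild` is given.
#' @param guild "plants" or "visitors"; inferred from dimnames when
#'   `focal_species` is a name.
#' @param n_randomizations null draws (default 100).
#' @param seed integer seed.
#' @return the z-score, or NA when the null sd is 0.
#' @export
nestedness_contribution <- function(matrix, focal_species,
                                    guild = c("plants", "visitors"),
                                    n_randomizations = 100, seed = 1) {
  if (n_randomizations < 2) stop_invanet("bad_replicates", "need >= 2 randomizations")
  b <- as.matrix(matrix) > 0
  storage.mode(b) <- "double"
  if (is.character(focal_species)) {
    if (focal_species %in% rownames(b)) {
      guild <- "plants"; idx <- match(focal_species, rownames(b))
    } else if (focal_species %in% colnames(b)) {
      guild <- "visitors"; idx <- match(focal_species, colnames(b))
    } else {
      stop_invanet("unknown_species", sprintf("no species named '%s'", focal_species))
    }
  } else {
    guild <- match.arg(guild)
    idx <- as.integer(focal_species)
  }
  work <- if (guild == "plants") b else t(b)
  if (idx < 1 || idx > nrow(work)) {
    stop_invanet("unknown_species", "focal index out of range")
  }
  p <- ce_probability_matrix(work)[idx, ]
  obs <- nodf(work)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vals <- numeric(n_randomizations)
  for (i in seq_len(n_randomizations)) {
    w <- work
    w[idx, ] <- stats::rbinom(ncol(w), 1, p)
    vals[i] <- nodf(w)
  }
  sdv <- stats::sd(vals)
  if (sdv == 0) return(NA_real_)
  (obs - mean(vals)) / sdv
}

#' Species-level metrics table for a community
#'
#' Normalized degree, species strength, and nestedness contribution for every
#' plant (and optionally every visitor) in a community, on the matrix with
#' empty rows/columns dropped.
#'
#' @param community a `site_community` or count matrix.
#' @param include_visitors also compute visitor-side rows (default FALSE,
#'   matching the plant-focused species-level analysis).
#' @param n_randomizations null draws per species for the nestedness
#'   contribution.
#' @param seed integer seed.
#' @return data frame: `species_id, guild, origin, normalized_degree,
#'   strength, nestedness_contribution`.
#' @export
species_metrics <- function(community, include_visitors = FALSE,
                            n_randomizations = 100, seed = 1) {
  is_comm <- inherits(community, "site_community")
  m <- if (is_comm) community$counts else as.matrix(community)
  m <- drop_empty(m, warn = FALSE)
  nd <- normalized_degree(m)
  st_p <- species_strength(m, "plants")
  origin_of <- function(ids) {
    if (!is_comm) return(rep(NA_character_, length(ids)))
    community$plants$origin[match(ids, community$plants$species_id)]
  }
  pid <- rownames(m) %||% paste0("plant_", seq_len(nrow(m)))
  res <- data.frame(
    species_id = pid, guild = "plant", origin = origin_of(pid),
    normalized_degree = as.numeric(nd$plants),
    strength = as.numeric(st_p),
    nestedness_contribution = vapply(seq_len(nrow(m)), function(i) {
      nestedness_contribution(m, i, "plants", n_randomizations,
                              seed = (seed + 7919L * i) %% 2147483647L)
    }, numeric(1)),
    stringsAsFactors = FALSE)
  if (include_visitors) {
    vid <- colnames(m) %||% paste0("visitor_", seq_len(ncol(m)))
    res <- rbind(res, data.frame(
      species_id = vid, guild = "visitor", origin = NA_character_,
      normalized_degree = as.numeric(nd$visitors),
      strength = as.numeric(species_strength(m, "visitors")),
      nestedness_contribution = vapply(seq_len(ncol(m)), function(j) {
        nestedness_contribution(m, j, "visitors", n_randomizations,
                                seed = (seed + 7919L * (nrow(m) + j)) %% 2147483647L)
      }, numeric(1)),
      stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}
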