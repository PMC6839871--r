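#' Gower distance between two trait vectors
#'
#' Mixed-type Gower distance: for quantitative traits |x - y| / range, for
#' categorical traits 0/1 mismatch, averaged over the usable traits. Traits
#' with a missing value in either species, or a zero (or missing) range, are
#' excluded from the mean. Ranges are community-level, supplied by the caller
#' so that per-pair distances are comparable across a community.
#'
#' @param traits_a,traits_b named lists or one-row data frames with the same
#'   trait schema; numeric entries are treated as quantitative, everything
#'   else as categorical.
#' @param ranges named numeric vector of community ranges (max - min) for the
#'   quantitative traits.
#' @return distance in `[0, 1]`.
#' @export
gower_distance <- function(traits_a, traits_b, ranges) {
  a <- as.list(traits_a); b <- as.list(traits_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0) stop_invanet("no_usable_trait", "no shared traits")
  d <- c(); used <- 0L
  for (tr in shared) {
    x <- a[[tr]]; y <- b[[tr]]
    if (is.na(x) || is.na(y)) next
    if (is.numeric(x) && is.numeric(y)) {
      rg <- ranges[[tr]]
      if (is.null(rg) || is.na(rg) || rg <= 0) next
      d <- c(d, min(1, abs(x - y) / rg))
    } else {
      d <- c(d, as.numeric(as.character(x) != as.character(y)))
    }
    used <- used + 1L
  }
  if (used == 0L) stop_invanet("no_usable_trait", "no usable trait for this pair")
  mean(d)
}

#' Community ranges for quantitative traits
#' @param traits data frame of traits (excluding the id column).
#' @return named vector of max - min per numeric column.
#' @keywords internal
trait_ranges <- function(traits) {
  num <- vapply(traits, is.numeric, logical(1))
  vapply(traits[num], function(x) diff(range(x, na.rm = TRUE)), numeric(1))
}

#' Pairwise Gower distance matrix for a trait table
#'
#' @param table data frame with a `species_id` column and trait columns
#'   (quantitative and/or categorical). Ranges default to the community's own
#'   observed ranges.
#' @param ranges optional named numeric vector overriding the ranges.
#' @return symmetric species x species distance matrix.
#' @export
gower_matrix <- function(table, ranges = NULL) {
  ids <- table$species_id
  tr <- table[setdiff(names(table), c("species_id", "origin", "guild"))]
  if (is.null(ranges)) ranges <- trait_ranges(tr)
  n <- nrow(tr)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- gower_distance(tr[i, , drop = FALSE],
                                           tr[j, , drop = FALSE], ranges)
    }
  }
  D
}

#' Per-species floral similarity index
#'
#' s_i = 1 minus the mean Gower distance from species i to every other
#' species present: the degree of similarity of each species' floral
#' phenotype with respect to the rest of the community.
#'
#' @param table trait table as in [gower_matrix()], at least two species.
#' @param ranges optional range override.
#' @return named numeric vector of similarities in `[0, 1]`.
#' @export
similarity_index <- function(table, ranges = NULL) {
  if (nrow(table) < 2) {
    stop_invanet("too_small", "similarity index needs at least two species")
  }
  D <- gower_matrix(table, ranges)
  1 - (rowSums(D) / (nrow(D) - 1))
}

#' Native vs alien floral-similarity summary
#'
#' Community mean and SD of the per-species similarity index, with subgroup
#' means for native and for alien species. A group with no members gets NA
#' summaries.
#'
#' @param table trait table (`species_id` + traits).
#' @param origins character vector of "native"/"alien", aligned with the
#'   table rows, or a data frame with `species_id` and `origin` to be matched
#'   by id.
#' @param ranges optional range override.
#' @return list of class `similarity_result`: `similarity` (per-species
#'   vector), `mean`, `sd`, `native_mean`, `alien_mean`, `native_n`,
#'   `alien_n`.
#' @export
group_similarity_summary <- function(table, origins, ranges = NULL) {
  if (is.data.frame(origins)) {
    origins <- origins$origin[match(table$species_id, origins$species_id)]
  }
  if (length(origins) != nrow(table) || anyNA(origins)) {
    stop_invanet("bad_origin", "an origin label is required for every species")
  }
  s <- similarity_index(table, ranges)
  grp_mean <- function(g) if (any(origins == g)) mean(s[origins == g]) else NA_real_
  structure(list(similarity = s, mean = mean(s), sd = stats::sd(s),
                 native_mean = grp_mean("native"), alien_mean = grp_mean("alien"),
                 native_n = sum(origins == "native"),
                 alien_n = sum(origins == "alien")),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("floral similarity: %.3f +/- %.3f (native %.3f, n=%d; alien %s, n=%d)\n",
              x$mean, x$sd, x$native_mean, x$native_n,
              ifelse(is.na(x$alien_mean), "NA", sprintf("%.3f", x$alien_mean)),
              x$alien_n))
  invisible(x)
}

#' Hexagon chromatic coordinates for hymenopteran vision
#'
#' Colour-hexagon coordinates of a floral reflectance spectrum as seen by a
#' trichromatic (UV, blue, green) hymenopteran eye. Per receptor, the quantum
#' catch is the integral of reflectance x receptor sensitivity x illuminant;
#' adaptation to the background divides each catch by the catch of the
#' background spectrum, and the non-linear phototransduction stage maps the
#' relative catch I to an excitation E = I / (I + 1) (so the background
#' itself sits at E = 0.5 in every channel, the achromatic centre). The
#' chromatic coordinates are X = (sqrt(3)/2) (E_G - E_UV) and
#' Y = E_B - (E_UV + E_G) / 2.
#'
#' @param reflectance numeric vector of stimulus reflectance on `wavelengths`.
#' @param sensitivities 3-column matrix (`uv`, `blue`, `green`) of receptor
#'   sensitivities on the same grid; these are user-supplied curves.
#' @param illuminant numeric vector, irradiance spectrum on the same grid.
#' @param background numeric vector, background reflectance on the same grid.
#' @param wavelengths the common grid in nm (default attr or 300-700
#'   evenly spaced to match `reflectance`).
#' @return named numeric vector `c(x = ..., y = ...)`.
#' @export
hexagon_coordinates <- function(reflectance, sensitivities, illuminant,
                                background,
                                wavelengths = seq(300, 700,
                                                  length.out = length(reflectance))) {
  n <- length(wavelengths)
  sens <- as.matrix(sensitivities)
  if (length(reflectance) != n || nrow(sens) != n ||
      length(illuminant) != n || length(background) != n) {
    stop_invanet("grid_mismatch", "all spectra must share the wavelength grid")
  }
  if (ncol(sens) != 3) {
    stop_invanet("grid_mismatch", "need exactly three receptor channels (uv, blue, green)")
  }
  catch <- function(refl) {
    # trapezoidal integration over the grid
    f <- sens * refl * illuminant
    colSums((f[-1, , drop = FALSE] + f[-n, , drop = FALSE]) / 2 *
              diff(wavelengths))
  }
  qb <- catch(background)
  if (any(qb <= 0)) stop_invanet("bad_background", "non-positive background quantum catch")
  I <- unname(catch(reflectance) / qb)
  E <- I / (I + 1)
  c(x = sqrt(3) / 2 * (E[3] - E[1]), y = E[2] - (E[1] + E[3]) / 2)
}
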