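#' Site community objects
#'
#' A `site_community` bundles one site's flowering plants (with origin and
#' flower abundance), its floral visitors, and the plants x visitors
#' interaction count matrix. Rows of the matrix are plants, columns are
#' visitors; this orientation is assumed by every downstream function.
#'
#' @param site_id single character token identifying the site.
#' @param plants data frame with columns `species_id`, `guild` ("plant"),
#'   `origin` ("native" or "alien"), optionally `name`, `family`, and
#'   `flower_count` (non-negative integer).
#' @param visitors data frame with columns `species_id`, `guild` ("visitor"),
#'   `origin` ("not_applicable"), optionally `name`, `family`.
#' @param counts integer matrix of observed visits, `nrow(plants)` x
#'   `nrow(visitors)`; dimnames are set from the species ids.
#' @param surveys optional long-format data frame of visit events with columns
#'   `site_id, plot_id, date_id, plant_id, visitor_id, n_visits,
#'   observation_minutes`.
#' @return an object of class `site_community`.
#' @seealso [load_community()], [validate_community()]
#' @export
site_community <- function(site_id, plants, visitors, counts, surveys = NULL) {
  plants <- as.data.frame(plants)
  visitors <- as.data.frame(visitors)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != nrow(plants) || ncol(counts) != nrow(visitors)) {
    stop_invanet("dimension_mismatch", sprintf(
      "counts is %d x %d but there are %d plants and %d visitors",
      nrow(counts), ncol(counts), nrow(plants), nrow(visitors)))
  }
  rownames(counts) <- plants$species_id
  colnames(counts) <- visitors$species_id
  obj <- structure(
    list(site_id = site_id, plants = plants, visitors = visitors,
         counts = counts, surveys = surveys),
    class = "site_community")
  viol <- validate_community(obj)
  if (length(viol)) {
    bad <- viol[[1]]
    stop_invanet(attr(bad, "code") %||% "invalid_community",
                 paste(unlist(viol), collapse = "; "))
  }
  obj
}

#' @export
print.site_community <- function(x, ...) {
  cat(sprintf("site_community '%s': %d plants (%d alien) x %d visitors, %d visits\n",
              x$site_id, nrow(x$plants), sum(x$plants$origin == "alien"),
              nrow(x$visitors), sum(x$counts)))
  invisible(x)
}

# condition helper: every validation failure carries a distinct class
# "invanet_<code>" so callers can test for the specific error
stop_invanet <- function(code, msg) {
  stop(structure(class = c(paste0("invanet_", code), "invanet_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a site community from the CSV contract
#'
#' Reads an interaction matrix (`interactions.csv`: first column `plant_id`,
#' remaining columns one per visitor id, integer cells) and a species metadata
#' table (`species.csv`: `species_id,guild,origin,family,flower_count`), checks
#' them against each other, and returns a validated [site_community()]. Row
#' order follows the matrix file; plant/visitor metadata are reordered to
#' match.
#'
#' @param matrix_path path to the interactions CSV.
#' @param species_path path to the species metadata CSV.
#' @param site_id site identifier (default: the matrix file's directory name).
#' @param surveys_path optional path to a long-format `visits.csv`.
#' @return a `site_community`.
#' @export
load_community <- function(matrix_path, species_path,
                           site_id = basename(dirname(normalizePath(matrix_path, mustWork = FALSE))),
                           surveys_path = NULL) {
  mat_df <- utils::read.csv(matrix_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(mat_df) == 0L || ncol(mat_df) < 2L) {
    stop_invanet("dimension_mismatch",
                 "interaction matrix file must have at least one plant row and one visitor column")
  }
  sp <- utils::read.csv(species_path, stringsAsFactors = FALSE)
  if (anyDuplicated(sp$species_id)) {
    stop_invanet("duplicate_species", sprintf(
      "duplicated species ids in %s: %s", species_path,
      paste(unique(sp$species_id[duplicated(sp$species_id)]), collapse = ", ")))
  }
  plant_ids <- as.character(mat_df[[1]])
  visitor_ids <- colnames(mat_df)[-1]
  unknown <- setdiff(c(plant_ids, visitor_ids), sp$species_id)
  if (length(unknown)) {
    stop_invanet("unknown_species", sprintf(
      "ids present in matrix but absent from species file: %s",
      paste(unknown, collapse = ", ")))
  }
  counts <- as.matrix(mat_df[, -1, drop = FALSE])
  if (any(is.na(counts)) || any(counts != round(counts))) {
    stop_invanet("non_integer_count", "interaction counts must be integers")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop_invanet("negative_count", sprintf(
      "negative count at plant '%s', visitor '%s'",
      plant_ids[bad[1]], visitor_ids[bad[2]]))
  }
  plants <- sp[match(plant_ids, sp$species_id), , drop = FALSE]
  visitors <- sp[match(visitor_ids, sp$species_id), , drop = FALSE]
  rownames(plants) <- rownames(visitors) <- NULL
  surveys <- if (!is.null(surveys_path)) {
    utils::read.csv(surveys_path, stringsAsFactors = FALSE)
  }
  site_community(site_id, plants, visitors, counts, surveys)
}

#' Write a site community to the CSV contract
#'
#' Inverse of [load_community()]: writes `interactions.csv` and `species.csv`
#' (and `visits.csv` when surveys are present) into `dir`.
#'
#' @param community a `site_community`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_df <- data.frame(plant_id = community$plants$species_id,
                       community$counts, check.names = FALSE)
  utils::write.csv(mat_df, file.path(dir, "interactions.csv"), row.names = FALSE)
  sp <- rbind_fill(community$plants, community$visitors)
  utils::write.csv(sp, file.path(dir, "species.csv"), row.names = FALSE)
  if (!is.null(community$surveys)) {
    utils::write.csv(community$surveys, file.path(dir, "visits.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cc in setdiff(cols, names(a))) a[[cc]] <- NA
  for (cc in setdiff(cols, names(b))) b[[cc]] <- NA
  rbind(a[cols], b[cols])
}

#' Check a site community's invariants
#'
#' Reports (never raises) violations of the community invariants: unique
#' species ids, plant origins in {native, alien}, visitor origin
#' "not_applicable", non-negative integer counts, non-negative flower counts.
#'
#' @param community a `site_community` (or a bare list shaped like one).
#' @return a list of character violations, empty when the object is valid.
#'   Each element names the offending species or matrix cell.
#' @export
validate_community <- function(community) {
  v <- list()
  add <- function(code, msg) {
    m <- structure(msg, code = code)
    v[[length(v) + 1L]] <<- m
  }
  ids <- c(community$plants$species_id, community$visitors$species_id)
  if (anyDuplicated(ids)) {
    add("duplicate_species", sprintf("duplicated species id(s): %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  bad_origin <- !(community$plants$origin %in% c("native", "alien"))
  if (any(bad_origin)) {
    add("bad_origin", sprintf("plant(s) with origin outside {native, alien}: %s",
        paste(community$plants$species_id[bad_origin], collapse = ", ")))
  }
  if (!is.null(community$visitors$origin)) {
    bad_v <- community$visitors$origin != "not_applicable"
    if (any(bad_v)) {
      add("bad_origin", sprintf("visitor(s) with a plant origin label: %s",
          paste(community$visitors$species_id[bad_v], collapse = ", ")))
    }
  }
  neg <- which(community$counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    add("negative_count", sprintf("negative count at (%s, %s)",
        rownames(community$counts)[neg[1, 1]] %||% neg[1, 1],
        colnames(community$counts)[neg[1, 2]] %||% neg[1, 2]))
  }
  if (any(community$counts != round(community$counts))) {
    add("non_integer_count", "non-integer interaction count(s)")
  }
  fc <- community$plants$flower_count
  if (!is.null(fc) && any(!is.na(fc) & fc < 0)) {
    add("negative_flower_count", sprintf("negative flower count for %s",
        paste(community$plants$species_id[!is.na(fc) & fc < 0], collapse = ", ")))
  }
  v
}

#' Estimate total flowers from inflorescence counts
#'
#' For species with many small flowers the per-plant flower number is
#' estimated as the average number of flowers counted on three inflorescences
#' multiplied by the total number of inflorescences, rounded half-up to an
#' integer.
#'
#' @param mean_flowers_per_inflorescence non-negative number.
#' @param n_inflorescences non-negative integer.
#' @return estimated flower count (integer-valued numeric).
#' @examples
#' estimate_inflorescence_flowers(12, 10)   # 120
#' estimate_inflorescence_flowers(2.5, 3)   # 8 (7.5 rounds half-up)
#' @export
estimate_inflorescence_flowers <- function(mean_flowers_per_inflorescence,
                                           n_inflorescences) {
  if (any(mean_flowers_per_inflorescence < 0) || any(n_inflorescences < 0)) {
    stop_invanet("negative_input", "inflorescence counts must be non-negative")
  }
  # round half-up, not banker's rounding
  floor(mean_flowers_per_inflorescence * n_inflorescences + 0.5)
}

#' Summarise the pollination environment of a site
#'
#' Per-plant floral visitor richness (number of visitor species observed at
#' least once) and per-flower visitation rate, plus the per-sample visitor
#' abundance vectors used for composition analysis when survey records are
#' present.
#'
#' The rate is visits per flower per observation period. The default period is
#' one 15-minute plot-day (three 5-minute rounds), the unit of the underlying
#' survey design; set `period_minutes` to rescale (e.g. `1` for visits per
#' flower per minute).
#'
#' @param community a `site_community` whose plants carry `flower_count`.
#' @param period_minutes length of the reporting period in minutes of
#'   observation (default 15).
#' @return a list of class `pollination_summary` with elements `per_plant`
#'   (data frame: `species_id, origin, richness, visits, flower_count, rate`)
#'   and `sample_abundance` (samples x visitor-species matrix, or NULL).
#'   Plants with zero or missing flower counts get `NA` rates.
#' @export
pollination_environment <- function(community, period_minutes = 15) {
  counts <- community$counts
  fc <- community$plants$flower_count
  total_minutes <- if (!is.null(community$surveys)) {
    # observed minutes per plant across all survey records
    tapply(community$surveys$observation_minutes,
           community$surveys$plant_id, sum)
  } else NULL
  richness <- rowSums(counts > 0)
  visits <- rowSums(counts)
  rate <- rep(NA_real_, nrow(counts))
  ok <- !is.null(fc) & !is.na(fc) & fc > 0
  if (is.null(fc)) ok <- rep(FALSE, nrow(counts))
  # periods observed per plant: total observed minutes / period, defaulting to
  # one period when no survey records exist
  n_periods <- rep(1, nrow(counts))
  if (!is.null(total_minutes)) {
    m <- total_minutes[community$plants$species_id]
    n_periods <- ifelse(is.na(m), 1, as.numeric(m) / period_minutes)
  }
  rate[ok] <- visits[ok] / fc[ok] / n_periods[ok]
  per_plant <- data.frame(
    species_id = community$plants$species_id,
    origin = community$plants$origin,
    richness = as.integer(richness),
    visits = as.numeric(visits),
    flower_count = if (is.null(fc)) NA_real_ else fc,
    rate = rate,
    stringsAsFactors = FALSE)
  sample_abundance <- NULL
  if (!is.null(community$surveys)) {
    s <- community$surveys
    key <- interaction(s$date_id, drop = TRUE)
    sample_abundance <- t(vapply(split(s, key), function(d) {
      out <- tapply(d$n_visits, factor(d$visitor_id,
                    levels = community$visitors$species_id), sum)
      out[is.na(out)] <- 0
      as.numeric(out)
    }, numeric(nrow(community$visitors))))
    colnames(sample_abundance) <- community$visitors$species_id
  }
  structure(list(per_plant = per_plant, sample_abundance = sample_abundance),
            class = "pollination_summary")
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between abundance vectors,
#' d = 1 - 2 sum(min(x, y)) / sum(x + y), as used for visitor-composition
#' comparisons. Computation is delegated to [vegan::vegdist()].
#'
#' @param abundance a samples x species matrix (or data frame) of non-negative
#'   abundances; every row must have at least one positive entry.
#' @return symmetric matrix of dissimilarities in `[0, 1]` with zero diagonal.
#' @export
bray_curtis_matrix <- function(abundance) {
  m <- as.matrix(abundance)
  if (any(m < 0)) stop_invanet("negative_count", "abundances must be non-negative")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop_invanet("all_zero_vector", sprintf(
      "sample(s) with no observations: %s",
      paste(rownames(m)[zero] %||% which(zero), collapse = ", ")))
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}
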