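#' Specify a plant-extinction scenario
#'
#' Four scenarios are compared: the intact (observed) network;
#' `aliens_removed`, dropping every alien plant; `natives_removed`, dropping
#' a uniform random subset of native plants; and `random_removal`, dropping a
#' uniform random subset of all plants regardless of origin. For the two
#' stochastic scenarios the number removed defaults to the number of alien
#' plants at the site, so all reduced networks lose equally many plants.
#'
#' @param scenario one of "intact", "aliens_removed", "natives_removed",
#'   "random_removal".
#' @param n_remove how many plants to remove in the stochastic scenarios;
#'   default (NULL) = the site's alien plant count.
#' @param n_replicates replicates for the stochastic scenarios (default 100;
#'   intact and aliens_removed are deterministic and always use 1).
#' @param seed integer seed.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("intact", "aliens_removed",
                                       "natives_removed", "random_removal"),
                          n_remove = NULL, n_replicates = 100, seed = 1) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("intact", "aliens_removed")) n_replicates <- 1L
  structure(list(scenario = scenario, n_remove = n_remove,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Apply an extinction scenario to a community
#'
#' Removes the scenario's plant set from the interaction matrix. Visitor
#' species left with no remaining partners (zero column total) are dropped as
#' secondary losses; visitor metadata rows are removed with them. The intact
#' scenario returns the community unchanged.
#'
#' @param community a `site_community`.
#' @param spec a [scenario_spec()].
#' @param replicate_seed seed for the random removal set (defaults to
#'   `spec$seed`).
#' @return the reduced `site_community` with an attribute
#'   `removed_plants` (character vector of removed plant ids).
#' @export
apply_scenario <- function(community, spec, replicate_seed = spec$seed) {
  origin <- community$plants$origin
  ids <- community$plants$species_id
  n_remove <- spec$n_remove %||% sum(origin == "alien")
  removed <- character(0)
  if (spec$scenario == "aliens_removed") {
    removed <- ids[origin == "alien"]
  } else if (spec$scenario != "intact") {
    pool <- if (spec$scenario == "natives_removed") ids[origin == "native"] else ids
    if (n_remove > length(pool)) {
      stop_invanet("too_many_removed", sprintf(
        "cannot remove %d of %d eligible plants", n_remove, length(pool)))
    }
    if (n_remove > 0) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(replicate_seed)
      removed <- sample(pool, n_remove)
    }
  }
  keep <- !(ids %in% removed)
  counts <- community$counts[keep, , drop = FALSE]
  orphan <- colSums(counts) == 0   # secondary loss of partnerless visitors
  out <- structure(
    list(site_id = community$site_id,
         plants = community$plants[keep, , drop = FALSE],
         visitors = community$visitors[!orphan, , drop = FALSE],
         counts = counts[, !orphan, drop = FALSE],
         surveys = community$surveys),
    class = "site_community")
  attr(out, "removed_plants") <- removed
  out
}

#' Run extinction scenarios over a study
#'
#' Recomputes the requested network-level metrics on the reduced network of
#' every site x scenario (x replicate for the stochastic scenarios) and
#' returns the per-replicate values in long format together with
#' scenario-level summaries.
#'
#' @param study list of sites: `site_community` objects or
#'   `list(community, traits)` pairs from [generate_study()].
#' @param scenarios character vector of scenario names (default all four).
#' @param metrics character subset of `c("nodf", "h2prime", "modularity_q",
#'   "robustness")`.
#' @param n_replicates replicates per stochastic scenario.
#' @param seed master seed.
#' @param n_orders removal orders for the robustness metric.
#' @param sa annealing settings for the modularity metric.
#' @return list of class `scenario_result`: `values` (data frame `site,
#'   scenario, replicate, metric, value`) and `summary` (data frame
#'   `scenario, metric, mean, sd, n`, means taken over the per-site replicate
#'   means).
#' @export
run_scenarios <- function(study,
                          scenarios = c("intact", "aliens_removed",
                                        "natives_removed", "random_removal"),
                          metrics = c("nodf", "h2prime", "robustness"),
                          n_replicates = 100, seed = 1, n_orders = 100,
                          sa = sa_config()) {
  comms <- lapply(study, function(s) {
    if (inherits(s, "site_community")) s else s$community
  })
  metric_funs <- list(
    nodf = function(m, s) nodf(m),
    h2prime = function(m, s) h2prime(m),
    modularity_q = function(m, s) optimize_modularity(m, sa, seed = s)$Q,
    robustness = function(m, s) robustness(m, n_orders = n_orders, seed = s)$R)
  metrics <- match.arg(metrics, names(metric_funs), several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(comms)) {
    comm <- comms[[ci]]
    for (sc in scenarios) {
      sp <- scenario_spec(sc, n_replicates = n_replicates, seed = seed)
      for (rep_i in seq_len(sp$n_replicates)) {
        rs <- (seed + 48611L * ci + 1009L * rep_i +
                 7L * match(sc, scenarios)) %% 2147483647L
        red <- apply_scenario(comm, sp, replicate_seed = rs)
        m <- drop_empty(red$counts, warn = FALSE)
        for (mt in metrics) {
          val <- if (nrow(m) < 2 || ncol(m) < 2) NA_real_
                 else metric_funs[[mt]](m, rs)
          rows[[length(rows) + 1L]] <- data.frame(
            site = comm$site_id, scenario = sc, replicate = rep_i,
            metric = mt, value = val, stringsAsFactors = FALSE)
        }
      }
    }
  }
  values <- do.call(rbind, rows)
  per_site <- stats::aggregate(value ~ site + scenario + metric, values,
                               mean, na.rm = TRUE)
  summary <- do.call(rbind, lapply(split(per_site,
                                         per_site[c("scenario", "metric")]),
    function(d) data.frame(scenario = d$scenario[1], metric = d$metric[1],
                           mean = mean(d$value), sd = stats::sd(d$value),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(values = values, per_site = per_site, summary = summary),
            class = "scenario_result")
}

#' Hedges' g standardized mean difference
#'
#' Bias-corrected standardized difference between two group means:
#' `g = J * (M1 - M2) / SD_pooled`, with
#' `SD_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))` and the
#' small-sample correction `J = 1 - 3 / (4 (n1+n2) - 9)`. The approximate
#' 95% CI uses `SE = sqrt((n1+n2)/(n1 n2) + g^2 / (2 (n1+n2-2)))`.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list of class `effect_size`: `g`, `ci` (length-2), `sd_pooled`,
#'   `J`, `percent_change` (of group 2 relative to group 1, NA when `m1` is
#'   0), and the inputs.
#' @examples
#' hedges_g(0.44, 0.15, 9, 0.52, 0.18, 9)$g   # -0.460
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop_invanet("too_small", "each group needs n >= 2")
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0)) {
    stop_invanet("zero_pooled_sd", "group SDs must be >= 0 and not both zero")
  }
  sd_pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- J * (m1 - m2) / sd_pooled
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2)))
  structure(list(g = g, ci = g + c(-1, 1) * 1.96 * se, sd_pooled = sd_pooled,
                 J = J,
                 percent_change = if (m1 != 0) 100 * (m2 - m1) / m1 else NA_real_,
                 m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Hedges' g = %.3f [%.3f, %.3f] (J = %.4f, SD_pooled = %.4f); change %+.1f%%\n",
              x$g, x$ci[1], x$ci[2], x$J, x$sd_pooled, x$percent_change))
  invisible(x)
}

#' Percent change of a scenario mean relative to the intact mean
#'
#' @param intact_mean non-zero reference mean.
#' @param scenario_mean scenario mean.
#' @return signed percent change `100 (scenario - intact) / intact`.
#' @export
percent_change <- function(intact_mean, scenario_mean) {
  if (intact_mean == 0) stop_invanet("zero_reference", "intact mean is zero")
  100 * (scenario_mean - intact_mean) / intact_mean
}

#' Effect sizes of every scenario against the intact network
#'
#' For each metric, compares the across-site distribution of per-site means
#' under each removal scenario with the intact distribution via [hedges_g()],
#' reporting g, its CI and the arithmetic percent change side by side.
#'
#' @param result a `scenario_result` from [run_scenarios()].
#' @return data frame: `metric, scenario, intact_mean, scenario_mean, g,
#'   ci_lo, ci_hi, percent_change`.
#' @export
scenario_effects <- function(result) {
  ps <- result$per_site
  out <- list()
  for (mt in unique(ps$metric)) {
    intact <- ps$value[ps$metric == mt & ps$scenario == "intact"]
    if (!length(intact)) next
    for (sc in setdiff(unique(ps$scenario), "intact")) {
      v <- ps$value[ps$metric == mt & ps$scenario == sc]
      if (length(v) < 2 || length(intact) < 2) next
      es <- hedges_g(mean(intact), stats::sd(intact), length(intact),
                     mean(v), stats::sd(v), length(v))
      out[[length(out) + 1L]] <- data.frame(
        metric = mt, scenario = sc,
        intact_mean = mean(intact), scenario_mean = mean(v),
        g = es$g, ci_lo = es$ci[1], ci_hi = es$ci[2],
        percent_change = percent_change(mean(intact), mean(v)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
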