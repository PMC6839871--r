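#' Configuration for the full analysis pipeline
#'
#' @param input either a directory of site subdirectories (each with
#'   `interactions.csv`, `species.csv`, optional `traits.csv`, `visits.csv`)
#'   or a [generator_config()] to simulate the study instead.
#' @param n_sites number of synthetic sites when `input` is a generator
#'   config.
#' @param out_dir output directory for artifacts.
#' @param nodf_replicates,modularity_replicates null-model replicate counts.
#' @param scenario_replicates replicates for stochastic extinction scenarios.
#' @param robustness_orders removal orders for robustness.
#' @param rarefaction_randomizations permutations for accumulation curves.
#' @param sa annealing settings, see [sa_config()].
#' @param seed master seed, recorded in every artifact.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, n_sites = 9L, out_dir = tempfile("invanet_"),
                            nodf_replicates = 1000L,
                            modularity_replicates = 100L,
                            scenario_replicates = 100L,
                            robustness_orders = 100L,
                            rarefaction_randomizations = 500L,
                            sa = sa_config(), seed = 1L) {
  stopifnot(nodf_replicates >= 1, modularity_replicates >= 1,
            scenario_replicates >= 1, robustness_orders >= 1,
            rarefaction_randomizations >= 1)
  structure(list(input = input, n_sites = n_sites, out_dir = out_dir,
                 nodf_replicates = nodf_replicates,
                 modularity_replicates = modularity_replicates,
                 scenario_replicates = scenario_replicates,
                 robustness_orders = robustness_orders,
                 rarefaction_randomizations = rarefaction_randomizations,
                 sa = sa, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_study_dir <- function(dir) {
  site_dirs <- list.dirs(dir, recursive = FALSE)
  # a malformed site yields its condition object; run_pipeline isolates it
  lapply(site_dirs, function(d) {
    tryCatch({
      comm <- load_community(file.path(d, "interactions.csv"),
                             file.path(d, "species.csv"),
                             site_id = basename(d),
                             surveys_path = if (file.exists(file.path(d, "visits.csv")))
                               file.path(d, "visits.csv") else NULL)
      traits <- if (file.exists(file.path(d, "traits.csv"))) {
        utils::read.csv(file.path(d, "traits.csv"), stringsAsFactors = FALSE)
      }
      list(community = comm, traits = traits)
    }, error = function(e) e)
  })
}

#' Run the full invaded-community network analysis pipeline
#'
#' End-to-end analysis of a multi-site study: per site, the network-level
#' metrics with CE-null significance tests for nestedness and modularity,
#' species-level metrics, and sampling completeness; study-level, a site
#' summary (species counts, alien flower share, trait similarity), a metric
#' table, the extinction-scenario simulation, and scenario effect sizes.
#' Every artifact embeds the seed and replicate settings for exact re-runs.
#'
#' Failures are isolated per site: a malformed site is reported in the
#' returned `failures` element (and the run carries on with the rest).
#'
#' @param config a [pipeline_config()].
#' @param write write JSON/CSV artifacts into `config$out_dir` (default TRUE).
#' @return list of class `pipeline_result`: `site_summary`, `metric_table`,
#'   `species_metrics`, `null_tests`, `completeness`, `scenarios`, `effects`,
#'   `failures`, `config`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  study <- if (inherits(config$input, "generator_config")) {
    cfg <- config$input
    cfg$seed <- config$seed
    generate_study(cfg, config$n_sites)
  } else {
    load_study_dir(config$input)
  }

  failures <- list()
  ok_sites <- list()
  site_rows <- metric_rows <- sp_rows <- null_rows <- comp_rows <- list()

  for (i in seq_along(study)) {
    s <- study[[i]]
    if (inherits(s, "error")) {
      failures[[length(failures) + 1L]] <- list(site = i,
                                                message = conditionMessage(s))
      next
    }
    res <- tryCatch({
      comm <- s$community
      m <- drop_empty(comm$counts, warn = FALSE)
      nm <- network_metrics(comm, n_orders = config$robustness_orders,
                            sa = config$sa, seed = config$seed + i)
      nt_nodf <- significance_test(m, "nodf",
                                   n_replicates = config$nodf_replicates,
                                   seed = config$seed + i)
      nt_mod <- significance_test(m, "modularity_q",
                                  n_replicates = config$modularity_replicates,
                                  seed = config$seed + i, sa = config$sa)
      spm <- species_metrics(comm, seed = config$seed + i)
      comp <- if (!is.null(comm$surveys)) {
        sampling_completeness(comm, config$rarefaction_randomizations,
                              seed = config$seed + i)
      }
      sim <- if (!is.null(s$traits)) {
        group_similarity_summary(s$traits, s$traits$origin)
      }
      fc <- comm$plants$flower_count
      alien_share <- if (!is.null(fc) && !anyNA(fc)) {
        sum(fc[comm$plants$origin == "alien"]) / sum(fc)
      } else NA_real_
      list(comm = comm, nm = nm, nt_nodf = nt_nodf, nt_mod = nt_mod,
           spm = spm, comp = comp, sim = sim, alien_share = alien_share)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(site = i, message = conditionMessage(res))
      next
    }
    ok_sites[[length(ok_sites) + 1L]] <- s
    comm <- res$comm
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      site = comm$site_id,
      n_native = sum(comm$plants$origin == "native"),
      n_alien = sum(comm$plants$origin == "alien"),
      n_visitors = nrow(comm$visitors),
      total_visits = sum(comm$counts),
      alien_flower_share = res$alien_share,
      trait_similarity_mean = if (!is.null(res$sim)) res$sim$mean else NA_real_,
      trait_similarity_sd = if (!is.null(res$sim)) res$sim$sd else NA_real_,
      stringsAsFactors = FALSE)
    metric_rows[[length(metric_rows) + 1L]] <- data.frame(
      site = comm$site_id,
      n_plants = sum(rowSums(comm$counts) > 0),
      n_visitors = sum(colSums(comm$counts) > 0),
      h2prime = res$nm$h2prime, nodf = res$nm$nodf,
      modularity_q = res$nm$modularity_q, robustness = res$nm$robustness,
      connectance = res$nm$connectance,
      links_per_species = res$nm$links_per_species,
      n_pairwise_interactions = res$nm$n_pairwise_interactions,
      stringsAsFactors = FALSE)
    sp_rows[[length(sp_rows) + 1L]] <- cbind(site = comm$site_id, res$spm)
    null_rows[[length(null_rows) + 1L]] <- data.frame(
      site = comm$site_id,
      metric = c("nodf", "modularity_q"),
      observed = c(res$nt_nodf$observed, res$nt_mod$observed),
      null_mean = c(res$nt_nodf$null_mean, res$nt_mod$null_mean),
      null_sd = c(res$nt_nodf$null_sd, res$nt_mod$null_sd),
      z = c(res$nt_nodf$z, res$nt_mod$z),
      p_value = c(res$nt_nodf$p_value, res$nt_mod$p_value),
      stringsAsFactors = FALSE)
    if (!is.null(res$comp)) {
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        site = comm$site_id, s_obs = res$comp$chao1$s_obs,
        f1 = res$comp$chao1$f1, f2 = res$comp$chao1$f2,
        chao1 = res$comp$chao1$chao1,
        completeness_pct = res$comp$completeness,
        stringsAsFactors = FALSE)
    }
  }

  scen <- eff <- NULL
  if (length(ok_sites) >= 2) {
    scen <- run_scenarios(ok_sites, n_replicates = config$scenario_replicates,
                          seed = config$seed,
                          n_orders = config$robustness_orders,
                          sa = config$sa)
    eff <- scenario_effects(scen)
  }

  out <- structure(list(
    site_summary = do.call(rbind, site_rows),
    metric_table = do.call(rbind, metric_rows),
    species_metrics = do.call(rbind, sp_rows),
    null_tests = do.call(rbind, null_rows),
    completeness = if (length(comp_rows)) do.call(rbind, comp_rows),
    scenarios = scen, effects = eff,
    failures = failures,
    config = config), class = "pipeline_result")

  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE)
    wcsv(out$site_summary, "site_summary.csv")
    wcsv(out$metric_table, "metric_table.csv")
    wcsv(out$species_metrics, "species_metrics.csv")
    wcsv(out$null_tests, "null_tests.csv")
    wcsv(out$completeness, "completeness.csv")
    if (!is.null(scen)) {
      wcsv(scen$values, "scenarios.csv")
      wcsv(eff, "effects.csv")
    }
    meta <- list(seed = config$seed,
                 nodf_replicates = config$nodf_replicates,
                 modularity_replicates = config$modularity_replicates,
                 scenario_replicates = config$scenario_replicates,
                 robustness_orders = config$robustness_orders,
                 rarefaction_randomizations = config$rarefaction_randomizations,
                 sa = config$sa,
                 n_failures = length(failures),
                 failures = lapply(failures, function(f)
                   list(site = f$site, message = f$message)))
    jsonlite::write_json(meta, file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d site(s) analysed, %d failure(s)\n",
              nrow(x$metric_table) %||% 0L, length(x$failures)))
  if (!is.null(x$metric_table)) {
    print(x$metric_table[c("site", "h2prime", "nodf", "modularity_q",
                           "robustness")], digits = 3)
  }
  invisible(x)
}
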