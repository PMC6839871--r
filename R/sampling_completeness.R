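#' Interaction accumulation curve
#'
#' Randomized accumulation of distinct plant-visitor interaction pairs as
#' survey samples are added without replacement. The sample unit is the
#' site-day by default (the underlying design surveys each site on nine
#' days).
#'
#' @param events long-format visit records with columns `plant_id`,
#'   `visitor_id`, and the grouping column.
#' @param n_randomizations number of random sample permutations (default 500).
#' @param seed integer seed.
#' @param sample_by name of the grouping column (default `"date_id"`).
#' @return list of class `rarefaction_result`: `curve` (data frame `samples,
#'   mean, sd`), `s_obs`, `n_samples`.
#' @export
interaction_accumulation <- function(events, n_randomizations = 500, seed = 1,
                                     sample_by = "date_id") {
  if (is.null(events) || nrow(events) == 0) {
    stop_invanet("empty_events", "no visit records")
  }
  pair <- paste(events$plant_id, events$visitor_id, sep = "\r")
  groups <- split(pair, events[[sample_by]])
  n <- length(groups)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  acc <- matrix(0, n_randomizations, n)
  for (r in seq_len(n_randomizations)) {
    seen <- character(0)
    ord <- sample(n)
    for (k in seq_len(n)) {
      seen <- union(seen, groups[[ord[k]]])
      acc[r, k] <- length(seen)
    }
  }
  structure(list(
    curve = data.frame(samples = seq_len(n), mean = colMeans(acc),
                       sd = apply(acc, 2, stats::sd)),
    s_obs = length(unique(pair)), n_samples = n),
    class = "rarefaction_result")
}

#' Chao1 asymptotic interaction richness
#'
#' Estimates the asymptotic number of distinct pairwise interactions from the
#' frequencies of the observed ones. With F1 interactions observed exactly
#' once and F2 exactly twice: classic form `S_obs + F1^2 / (2 F2)` when
#' `F2 > 0`, bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` when
#' `F2 = 0`.
#'
#' @param frequencies positive integer frequencies of each observed pairwise
#'   interaction (e.g. the non-zero cells of the count matrix).
#' @return list: `s_obs`, `f1`, `f2`, `chao1` (the variant the switching rule
#'   selects), `chao1_classic`, `chao1_bias_corrected`.
#' @export
chao1 <- function(frequencies) {
  f <- frequencies[frequencies > 0]
  if (length(f) == 0) stop_invanet("empty_events", "no observed interactions")
  s_obs <- length(f)
  f1 <- sum(f == 1); f2 <- sum(f == 2)
  classic <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else NA_real_
  bc <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  list(s_obs = s_obs, f1 = f1, f2 = f2,
       chao1 = if (f2 > 0) classic else bc,
       chao1_classic = classic, chao1_bias_corrected = bc)
}

#' Percent sampling completeness
#'
#' Observed interaction richness as a percentage of the Chao1 asymptotic
#' estimate.
#'
#' @param s_obs observed number of distinct pairwise interactions (> 0).
#' @param chao1_estimate Chao1 estimate, `>= s_obs`.
#' @return completeness in percent, `(0, 100]`.
#' @export
completeness_percent <- function(s_obs, chao1_estimate) {
  if (chao1_estimate <= 0) stop_invanet("zero_estimate", "Chao1 estimate must be positive")
  if (s_obs <= 0 || s_obs > chao1_estimate) {
    stop_invanet("bad_input", "need 0 < s_obs <= chao1_estimate")
  }
  100 * s_obs / chao1_estimate
}

#' Sampling-completeness summary for one community
#'
#' Convenience wrapper: accumulation curve over site-days, Chao1 from the
#' interaction count matrix, and percent completeness.
#'
#' @param community a `site_community` with survey records.
#' @param n_randomizations permutations for the accumulation curve.
#' @param seed integer seed.
#' @return list: `rarefaction`, `chao1`, `completeness`.
#' @export
sampling_completeness <- function(community, n_randomizations = 500, seed = 1) {
  rar <- interaction_accumulation(community$surveys, n_randomizations, seed)
  ch <- chao1(community$counts[community$counts > 0])
  list(rarefaction = rar, chao1 = ch,
       completeness = completeness_percent(ch$s_obs, ch$chao1))
}
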