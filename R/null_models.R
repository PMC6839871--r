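#' CE (degree-proportional) null-model probabilities
#'
#' Probability of each interaction occurring under the CE null model: the
#' cell probability is the mean of its row's and its column's degree
#' fractions, p_ij = (k_i / c + d_j / r) / 2, where k_i is the number of
#' presences in row i (out of c columns) and d_j the presences in column j
#' (out of r rows). The matrix is binarized before degrees are taken.
#'
#' @param matrix non-empty count or binary matrix.
#' @return matrix of probabilities in `[0, 1]`.
#' @export
ce_probability_matrix <- function(matrix) {
  b <- as.matrix(matrix) > 0
  if (length(b) == 0) stop_invanet("empty_matrix", "empty matrix")
  r <- nrow(b); c <- ncol(b)
  k <- rowSums(b); d <- colSums(b)
  (outer(k / c, rep(1, c)) + outer(rep(1, r), d / r)) / 2
}

#' Draw one null matrix from cell probabilities
#'
#' Independent Bernoulli draw per cell. Draws containing an empty row or
#' column are redrawn up to `max_attempts` times; if none succeeds the last
#' draw is returned with attribute `degenerate = TRUE`.
#'
#' @param probabilities matrix of probabilities in `[0, 1]`.
#' @param seed integer seed (same seed, same draw).
#' @param max_attempts redraw cap for degenerate matrices (default 100).
#' @return binary matrix of the same dimensions.
#' @export
sample_null <- function(probabilities, seed = NULL, max_attempts = 100) {
  p <- as.matrix(probabilities)
  if (any(p < 0 | p > 1)) stop_invanet("bad_probability", "probabilities must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  for (attempt in seq_len(max_attempts)) {
    draw <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p))
    if (all(rowSums(draw) > 0) && all(colSums(draw) > 0)) return(draw)
  }
  attr(draw, "degenerate") <- TRUE
  draw
}

#' Null-model significance test for a structural metric
#'
#' Monte-Carlo test of NODF nestedness or optimized Barber modularity against
#' the CE null model. Replicate matrices are Bernoulli draws from
#' [ce_probability_matrix()]; the observed value is compared with the null
#' distribution via z = (obs - mean) / sd and a one-sided p-value, the
#' fraction of null values >= observed (both metrics read "large = more
#' structured"). Defaults follow common practice for these tests: 1000
#' replicates for NODF, 100 for modularity.
#'
#' @param matrix observed count matrix.
#' @param metric "nodf" or "modularity_q".
#' @param n_replicates number of null draws; default 1000 for NODF and 100
#'   for modularity.
#' @param seed integer seed.
#' @param sa annealing settings used when `metric = "modularity_q"`.
#' @return list of class `null_ensemble`: `metric`, `observed`, `null_values`,
#'   `null_mean`, `null_sd`, `z` (NA when sd is 0 or undefined), `p_value`,
#'   `n_replicates`, `n_degenerate`.
#' @export
significance_test <- function(matrix, metric = c("nodf", "modularity_q"),
                              n_replicates = NULL, seed = 1,
                              sa = sa_config()) {
  metric <- match.arg(metric)
  if (is.null(n_replicates)) {
    n_replicates <- if (metric == "nodf") 1000L else 100L
  }
  if (n_replicates < 1) stop_invanet("bad_replicates", "n_replicates must be >= 1")
  m <- drop_empty(as.matrix(matrix), warn = FALSE)
  metric_fun <- switch(metric,
    nodf = function(x, s) nodf(x),
    modularity_q = function(x, s) optimize_modularity(x, sa, seed = s)$Q)
  observed <- metric_fun(m, seed)
  p <- ce_probability_matrix(m)
  vals <- numeric(n_replicates)
  n_degenerate <- 0L
  for (i in seq_len(n_replicates)) {
    sub_seed <- (seed + 104729L * i) %% 2147483647L
    draw <- sample_null(p, seed = sub_seed)
    if (isTRUE(attr(draw, "degenerate"))) n_degenerate <- n_degenerate + 1L
    draw2 <- drop_empty(draw, warn = FALSE)
    vals[i] <- if (nrow(draw2) < 2 || ncol(draw2) < 2) NA_real_
               else metric_fun(draw2, sub_seed)
  }
  ok <- !is.na(vals)
  mu <- mean(vals[ok])
  sdv <- if (sum(ok) >= 2) stats::sd(vals[ok]) else NA_real_
  # a degenerate null (sd 0) still pins z = 0 when the observed value
  # coincides with it; otherwise z is undefined
  z <- if (!is.na(sdv) && sdv > 0) (observed - mu) / sdv
       else if (!is.na(sdv) && observed == mu) 0 else NA_real_
  structure(list(metric = metric, observed = observed,
                 null_values = vals, null_mean = mu, null_sd = sdv, z = z,
                 p_value = mean(vals[ok] >= observed),
                 n_replicates = n_replicates, n_degenerate = n_degenerate),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("CE null test of %s: observed %.3f, null %.3f +/- %.3f (n = %d), z = %s, p = %.4f\n",
              x$metric, x$observed, x$null_mean,
              ifelse(is.na(x$null_sd), NaN, x$null_sd), x$n_replicates,
              ifelse(is.na(x$z), "NA", sprintf("%.2f", x$z)), x$p_value))
  invisible(x)
}
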