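#' Drop empty rows and columns from an interaction matrix
#'
#' Plants recorded flowering but never visited (and visitors with no visits)
#' carry no interactions; they are kept in community metadata but removed
#' before any network metric is computed.
#'
#' @param matrix plants x visitors count matrix.
#' @param warn emit a warning naming what was dropped (default TRUE).
#' @return the matrix without all-zero rows/columns.
#' @export
drop_empty <- function(matrix, warn = TRUE) {
  m <- as.matrix(matrix)
  er <- rowSums(m) == 0
  ec <- colSums(m) == 0
  if (any(er) || any(ec)) {
    if (warn) {
      warning(sprintf("dropping %d empty row(s) and %d empty column(s) before metric computation",
                      sum(er), sum(ec)), call. = FALSE)
    }
    m <- m[!er, !ec, drop = FALSE]
  }
  m
}

#' NODF nestedness
#'
#' Nestedness metric based on overlap and decreasing fill, computed on the
#' binarized matrix. For every pair of rows (and of columns) whose marginal
#' totals strictly differ, the paired overlap is 100 times the fraction of the
#' poorer species' presences shared with the richer one; pairs with tied
#' totals contribute 0. NODF is the mean paired overlap over all
#' r(r-1)/2 + c(c-1)/2 pairs, ranging 0 (no nesting) to 100 (perfect nesting).
#'
#' @param matrix count or binary matrix with at least 2 rows and 2 columns;
#'   counts are binarized as `> 0`.
#' @return NODF value in `[0, 100]`.
#' @examples
#' nodf(rbind(c(1,1,1), c(1,1,0), c(1,0,0)))  # 100
#' nodf(diag(2))                              # 0
#' @export
nodf <- function(matrix) {
  b <- as.matrix(matrix) > 0
  storage.mode(b) <- "double"
  if (nrow(b) < 2 || ncol(b) < 2) {
    stop_invanet("too_small", "NODF needs at least 2 rows and 2 columns")
  }
  axis_sum <- function(m) {
    # m: entities x attributes (rows of the bipartite incidence)
    deg <- rowSums(m)
    shared <- m %*% t(m)
    poorer <- outer(deg, deg, pmin)
    contrib <- 100 * shared / ifelse(poorer > 0, poorer, 1)
    contrib[outer(deg, deg, "==") | poorer == 0] <- 0
    sum(contrib[upper.tri(contrib)])
  }
  r <- nrow(b); c <- ncol(b)
  npairs <- r * (r - 1) / 2 + c * (c - 1) / 2
  (axis_sum(b) + axis_sum(t(b))) / npairs
}

#' Two-dimensional Shannon entropy of an interaction matrix
#' @keywords internal
h2_entropy <- function(matrix) {
  p <- matrix / sum(matrix)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Extreme entropies compatible with observed marginal totals
#'
#' Heuristic minimum and maximum two-dimensional Shannon entropies over
#' non-negative integer matrices with the observed row and column totals.
#' The minimum (maximal specialization) comes from greedy packing: repeatedly
#' allocate min(largest remaining row total, largest remaining column total)
#' to that cell. The maximum (maximal generalization) comes from the
#' proportional table r_i c_j / m with a largest-remainder integer repair that
#' respects both margins.
#'
#' @param matrix count matrix (used only for its marginal totals).
#' @return list with `h2min`, `h2max`, and the packed/proportional matrices
#'   `m_min`, `m_max`.
#' @export
h2_extremes <- function(matrix) {
  m <- as.matrix(matrix)
  rt <- rowSums(m); ct <- colSums(m)
  tot <- sum(rt)
  if (tot <= 0) stop_invanet("empty_matrix", "matrix has no interactions")

  # -- minimum entropy: greedy specialist packing
  r <- rt; c <- ct
  m_min <- array(0, dim(m))
  while (sum(r) > 0) {
    i <- which.max(r); j <- which.max(c)
    a <- min(r[i], c[j])
    m_min[i, j] <- m_min[i, j] + a
    r[i] <- r[i] - a; c[j] <- c[j] - a
  }

  # -- maximum entropy: proportional fill + integer repair
  expected <- outer(rt, ct) / tot
  m_max <- floor(expected)
  repeat {
    rrem <- rt - rowSums(m_max)
    crem <- ct - colSums(m_max)
    if (sum(rrem) == 0) break
    frac <- expected - m_max
    # only cells whose row and column still have capacity are eligible
    elig <- outer(rrem > 0, crem > 0)
    frac[!elig] <- -Inf
    best <- arrayInd(which.max(frac), dim(frac))
    m_max[best[1], best[2]] <- m_max[best[1], best[2]] + 1
  }

  # Polish both tables with margin-preserving 2x2 rebalances; every accepted
  # move keeps an integer matrix with the observed margins, so the results
  # remain inside the exact enumeration bounds by construction. Only worth it
  # at small totals, where the integer grid is coarse; for well-sampled
  # matrices the packing/repair tables are already near the extremes.
  if (tot <= 500) {
    m_min <- rebalance_entropy(m_min, tot, maximize = FALSE)
    m_max <- rebalance_entropy(m_max, tot, maximize = TRUE)
  }

  list(h2min = h2_entropy(m_min), h2max = h2_entropy(m_max),
       m_min = m_min, m_max = m_max)
}

# hill-climb entropy over margin-preserving unit moves along 2x2 cycles:
# (i,j)--, (i2,j2)--, (i,j2)++, (i2,j)++
rebalance_entropy <- function(tab, tot, maximize = TRUE, max_sweeps = 60) {
  r <- nrow(tab); cc <- ncol(tab)
  if (r < 2 || cc < 2) return(tab)
  h <- function(x) ifelse(x > 0, -(x / tot) * log(x / tot), 0)
  sgn <- if (maximize) 1 else -1
  exhaustive <- (r * cc) <= 100
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    pairs_i <- if (exhaustive) utils::combn(r, 2, simplify = FALSE)
               else lapply(seq_len(300), function(k) sample(r, 2))
    for (ij in pairs_i) {
      i <- ij[1]; i2 <- ij[2]
      cols <- if (exhaustive) utils::combn(cc, 2, simplify = FALSE)
              else lapply(seq_len(10), function(k) sample(cc, 2))
      for (jj in cols) {
        for (ord in 1:2) {
          j <- jj[ord]; j2 <- jj[3 - ord]
          if (tab[i, j] < 1 || tab[i2, j2] < 1) next
          dH <- h(tab[i, j] - 1) + h(tab[i2, j2] - 1) +
                h(tab[i, j2] + 1) + h(tab[i2, j] + 1) -
                h(tab[i, j]) - h(tab[i2, j2]) -
                h(tab[i, j2]) - h(tab[i2, j])
          if (sgn * dH > 1e-12) {
            tab[i, j] <- tab[i, j] - 1; tab[i2, j2] <- tab[i2, j2] - 1
            tab[i, j2] <- tab[i, j2] + 1; tab[i2, j] <- tab[i2, j] + 1
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  tab
}

#' H2' network-level specialization
#'
#' Standardized two-dimensional Shannon entropy of the interaction
#' frequencies: H2' = (H2max - H2) / (H2max - H2min), where H2 is the entropy
#' of the observed proportions and H2min/H2max are the extreme entropies
#' achievable under the observed marginal totals (see [h2_extremes()]). Ranges
#' from 0 (no specialization: interactions as generalized as the margins
#' allow) to 1 (total specialization), and is comparable across networks of
#' different size.
#'
#' @param matrix non-empty count matrix.
#' @return H2' in `[0, 1]`.
#' @examples
#' h2prime(diag(5) * 10)          # 1: maximally specialized
#' h2prime(matrix(2, 2, 2))       # 0: as generalized as the margins allow
#' @export
h2prime <- function(matrix) {
  m <- as.matrix(matrix)
  if (length(m) == 0 || sum(m) <= 0) {
    stop_invanet("empty_matrix", "H2' needs a non-empty count matrix")
  }
  ex <- h2_extremes(m)
  if (ex$h2max - ex$h2min < .Machine$double.eps^0.5) return(0)
  h2 <- h2_entropy(m)
  min(1, max(0, (ex$h2max - h2) / (ex$h2max - ex$h2min)))
}

#' Barber bipartite modularity for a given partition
#'
#' Q = (1/m) * sum over plant-visitor pairs of (A_ij - k_i d_j / m) for pairs
#' assigned to the same module, with m the total interaction weight and
#' k_i, d_j the row and column totals. Q is 0 for the single-module partition
#' on any matrix.
#'
#' @param matrix count matrix.
#' @param partition integer/character vector of module labels of length
#'   `nrow + ncol` (plants first, then visitors), or a list with elements
#'   `rows` and `cols`.
#' @return modularity Q.
#' @export
barber_modularity <- function(matrix, partition) {
  A <- as.matrix(matrix)
  r <- nrow(A); c <- ncol(A)
  if (is.list(partition)) partition <- c(partition$rows, partition$cols)
  if (length(partition) != r + c) {
    stop_invanet("partition_mismatch", sprintf(
      "partition has %d labels for %d species", length(partition), r + c))
  }
  g_row <- partition[seq_len(r)]
  g_col <- partition[r + seq_len(c)]
  m <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  same <- outer(g_row, g_col, "==")
  sum((A - outer(k, d) / m) * same) / m
}

#' Default simulated annealing settings for modularity search
#'
#' @param cooling geometric cooling factor per temperature step.
#' @param moves_per_temp_factor moves per temperature = this factor times the
#'   number of species.
#' @param patience stop after this many improvement-free temperature steps.
#' @param t0_accept target acceptance rate of uphill moves used to set the
#'   initial temperature.
#' @param max_temps hard cap on temperature steps.
#' @return list of settings for [optimize_modularity()].
#' @export
sa_config <- function(cooling = 0.95, moves_per_temp_factor = 50,
                      patience = 20, t0_accept = 0.8, max_temps = 400) {
  list(cooling = cooling, moves_per_temp_factor = moves_per_temp_factor,
       patience = patience, t0_accept = t0_accept, max_temps = max_temps)
}

#' Maximize Barber modularity by simulated annealing
#'
#' Searches module partitions of the bipartite network with single-species
#' reassignments (including moves to a fresh module), module merges and random
#' module splits under geometric cooling. The initial temperature is set from
#' a pilot sample of uphill move sizes so that roughly `t0_accept` of them
#' would be accepted. Always returns Q >= 0: the single-module partition
#' (Q = 0) is the fallback when no split improves on it.
#'
#' @param matrix non-empty count matrix.
#' @param config settings from [sa_config()].
#' @param seed integer seed; the same seed gives the same partition.
#' @return list with `partition` (labels, plants first then visitors,
#'   relabelled 1..K), `Q`, and `n_modules`.
#' @export
optimize_modularity <- function(matrix, config = sa_config(), seed = 1) {
  A <- as.matrix(matrix)
  r <- nrow(A); c <- ncol(A)
  n <- r + c
  m <- sum(A)
  if (m <= 0) stop_invanet("empty_matrix", "cannot optimize an empty network")
  k <- rowSums(A); d <- colSums(A)
  B <- A - outer(k, d) / m   # modularity matrix; Q = sum(B[same]) / m

  q_of <- function(part) {
    same <- outer(part[seq_len(r)], part[r + seq_len(c)], "==")
    sum(B * same) / m
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  # start from singleton-ish random partition
  part <- sample(ceiling(n / 2), n, replace = TRUE)
  q_cur <- q_of(part)

  propose <- function(part) {
    kind <- sample(3, 1, prob = c(0.8, 0.1, 0.1))
    labs <- unique(part)
    if (kind == 1 || length(labs) == 1) {         # reassign one species
      i <- sample(n, 1)
      target <- c(setdiff(labs, part[i]), max(labs) + 1L)
      part[i] <- target[sample(length(target), 1)]
    } else if (kind == 2 && length(labs) >= 2) {  # merge two modules
      ab <- sample(labs, 2)
      part[part == ab[2]] <- ab[1]
    } else {                                      # split one module
      g <- sample(labs, 1)
      idx <- which(part == g)
      if (length(idx) >= 2) {
        take <- idx[as.logical(stats::rbinom(length(idx), 1, 0.5))]
        if (length(take) > 0 && length(take) < length(idx)) {
          part[take] <- max(labs) + 1L
        }
      }
    }
    part
  }

  # pilot run to set the initial temperature
  dq <- numeric(0)
  p <- part
  for (i in seq_len(100)) {
    p2 <- propose(p)
    dq <- c(dq, q_of(p2) - q_of(p))
    p <- p2
  }
  drops <- -dq[dq < 0]
  t0 <- if (length(drops)) stats::median(drops) / -log(config$t0_accept) else 0.05
  t0 <- max(t0, 1e-4)

  best <- part; q_best <- q_cur
  temp <- t0
  moves <- config$moves_per_temp_factor * n
  stale <- 0
  for (step in seq_len(config$max_temps)) {
    improved <- FALSE
    for (mv in seq_len(moves)) {
      cand <- propose(part)
      q_new <- q_of(cand)
      if (q_new >= q_cur || stats::runif(1) < exp((q_new - q_cur) / temp)) {
        part <- cand; q_cur <- q_new
        if (q_cur > q_best + 1e-12) {
          best <- part; q_best <- q_cur; improved <- TRUE
        }
      }
    }
    stale <- if (improved) 0 else stale + 1
    if (stale >= config$patience) break
    temp <- temp * config$cooling
  }

  if (q_best < 0) {            # single-module fallback
    best <- rep(1L, n); q_best <- 0
  }
  labs <- unique(best)
  part_out <- match(best, labs)
  list(partition = part_out, Q = q_best, n_modules = length(labs))
}

#' Robustness to sequential species loss
#'
#' Simulates random removal orders of one guild (plants by default). A species
#' of the opposite guild goes secondarily extinct once all of its interaction
#' partners are removed; no reallocation of interaction weight takes place.
#' For each order the attack-tolerance curve tracks the surviving fraction of
#' the opposite guild against the fraction removed (endpoints (0,1) and
#' (1,0)); robustness R is the trapezoidal area under the order-averaged
#' curve. R near 1 means the network tolerates species loss.
#'
#' @param matrix non-empty count matrix.
#' @param removal_guild "plants" (rows) or "visitors" (columns).
#' @param n_orders number of random removal orders to average (default 100).
#' @param seed integer seed.
#' @return list with `R`, `curve` (data frame: `removed_fraction`,
#'   `surviving_fraction` mean and sd), and `n_orders`.
#' @export
robustness <- function(matrix, removal_guild = c("plants", "visitors"),
                       n_orders = 100, seed = 1) {
  removal_guild <- match.arg(removal_guild)
  if (n_orders < 1) stop_invanet("bad_n_orders", "n_orders must be >= 1")
  A <- as.matrix(matrix)
  if (removal_guild == "visitors") A <- t(A)
  if (sum(A) <= 0) stop_invanet("empty_matrix", "cannot remove from an empty network")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nr <- nrow(A); nc <- ncol(A)
  curves <- matrix(0, n_orders, nr + 1)
  for (o in seq_len(n_orders)) {
    ord <- sample(nr)
    curves[o, ] <- survival_curve(A, ord)
  }
  mean_curve <- colMeans(curves)
  x <- (0:nr) / nr
  R <- sum(diff(x) * (utils::head(mean_curve, -1) + utils::tail(mean_curve, -1)) / 2)
  list(R = R,
       curve = data.frame(removed_fraction = x,
                          surviving_fraction = mean_curve,
                          sd = apply(curves, 2, stats::sd)),
       n_orders = n_orders)
}

# fraction of columns (opposite guild) surviving after removing rows in `ord`,
# including the pre-removal point; final point is 0 (all rows gone, every
# column partnerless)
survival_curve <- function(A, ord) {
  nr <- nrow(A); nc <- ncol(A)
  alive_cols <- colSums(A > 0) # partners remaining per column
  surv <- numeric(nr + 1)
  surv[1] <- 1
  n0 <- sum(alive_cols > 0)
  for (step in seq_len(nr)) {
    i <- ord[step]
    alive_cols <- alive_cols - (A[i, ] > 0)
    surv[step + 1] <- sum(alive_cols > 0) / n0
  }
  surv
}

#' Basic bipartite network descriptors
#'
#' Connectance (realized fraction of possible links), links per species
#' (number of realized links divided by total species), and the count of
#' distinct pairwise interactions (non-zero cells).
#'
#' @param matrix non-empty matrix.
#' @return list with `connectance`, `links_per_species`,
#'   `n_pairwise_interactions`.
#' @export
basic_descriptors <- function(matrix) {
  m <- as.matrix(matrix)
  if (length(m) == 0) stop_invanet("empty_matrix", "empty matrix")
  links <- sum(m > 0)
  list(connectance = links / (nrow(m) * ncol(m)),
       links_per_species = links / (nrow(m) + ncol(m)),
       n_pairwise_interactions = links)
}

#' All network-level metrics for one community
#'
#' Convenience wrapper computing the full set of structural metrics on a
#' community's interaction matrix (empty rows/columns dropped first): NODF
#' nestedness, H2' specialization, optimized Barber modularity, robustness to
#' plant loss, and the basic descriptors.
#'
#' @param community a `site_community` or a bare count matrix.
#' @param n_orders removal orders for robustness.
#' @param sa simulated-annealing settings, see [sa_config()].
#' @param seed integer seed shared by the stochastic components.
#' @return list of class `network_metrics` with fields `nodf`, `h2prime`,
#'   `modularity_q`, `partition`, `robustness`, `connectance`,
#'   `links_per_species`, `n_pairwise_interactions`.
#' @export
network_metrics <- function(community, n_orders = 100, sa = sa_config(),
                            seed = 1) {
  m <- if (inherits(community, "site_community")) community$counts else community
  m <- drop_empty(m, warn = FALSE)
  opt <- optimize_modularity(m, sa, seed = seed)
  rb <- robustness(m, n_orders = n_orders, seed = seed)
  bd <- basic_descriptors(m)
  structure(list(
    nodf = nodf(m), h2prime = h2prime(m),
    modularity_q = opt$Q, partition = opt$partition,
    robustness = rb$R,
    connectance = bd$connectance,
    links_per_species = bd$links_per_species,
    n_pairwise_interactions = bd$n_pairwise_interactions),
    class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network metrics: NODF %.2f | H2' %.3f | Q %.3f | ",
                     "R %.3f | connectance %.3f | links/sp %.2f | links %d\n"),
              x$nodf, x$h2prime, x$modularity_q, x$robustness,
              x$connectance, x$links_per_species, x$n_pairwise_interactions))
  invisible(x)
}
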