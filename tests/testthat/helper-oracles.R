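# Independent brute-force oracles used to pin expected values for the
# heuristic/stochastic routines. These deliberately share no code with the
# package implementation.

# all non-negative integer matrices with the given row and column totals
enum_margin_matrices <- function(row_totals, col_totals) {
  r <- length(row_totals); cc <- length(col_totals)
  out <- list()
  fill_row <- function(mat, i, col_rem) {
    if (i > r) {
      out[[length(out) + 1L]] <<- mat
      return(invisible())
    }
    # enumerate compositions of row_totals[i] bounded by col_rem
    comp <- function(row, j, rem) {
      if (j == cc) {
        if (rem <= col_rem[cc]) {
          row[cc] <- rem
          m2 <- mat; m2[i, ] <- row
          fill_row(m2, i + 1L, col_rem - row)
        }
        return(invisible())
      }
      for (v in 0:min(rem, col_rem[j])) {
        row[j] <- v
        comp(row, j + 1L, rem - v)
      }
    }
    comp(integer(cc), 1L, row_totals[i])
  }
  fill_row(matrix(0L, r, cc), 1L, col_totals)
  out
}

shannon2d <- function(m) {
  p <- m / sum(m); p <- p[p > 0]
  -sum(p * log(p))
}

# exact min/max entropy over all integer matrices with these margins
exact_h2_extremes <- function(row_totals, col_totals) {
  ents <- vapply(enum_margin_matrices(row_totals, col_totals), shannon2d,
                 numeric(1))
  c(min = min(ents), max = max(ents))
}

exact_h2prime <- function(m) {
  ex <- exact_h2_extremes(rowSums(m), colSums(m))
  if (ex["max"] - ex["min"] < 1e-12) return(0)
  unname(min(1, max(0, (ex["max"] - shannon2d(m)) / (ex["max"] - ex["min"]))))
}

# all set partitions of n items as label vectors in restricted growth form
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, k) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(k + 1L)) grow(c(labels, g), max(k, g))
  }
  grow(integer(0), 0L)
  out
}

# Barber Q evaluated from scratch (no package code)
oracle_q <- function(A, labels) {
  r <- nrow(A); cc <- ncol(A); m <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  tot <- 0
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    if (labels[i] == labels[r + j]) tot <- tot + A[i, j] - k[i] * d[j] / m
  }
  tot / m
}

# exhaustive maximum of Barber Q over all partitions (n = r + c <= 8 or so)
exhaustive_modularity <- function(A) {
  parts <- all_partitions(nrow(A) + ncol(A))
  qs <- vapply(parts, function(p) oracle_q(A, p), numeric(1))
  list(Q = max(qs), partition = parts[[which.max(qs)]])
}

# exact expected robustness: mean attack-tolerance area over every removal
# order of the rows (plants), secondary-extinction rule
exhaustive_robustness <- function(A) {
  A <- as.matrix(A)
  nr <- nrow(A)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  n0 <- sum(colSums(A > 0) > 0)
  areas <- vapply(perms(seq_len(nr)), function(ord) {
    alive <- colSums(A > 0)
    surv <- c(1, vapply(ord, function(i) {
      alive <<- alive - (A[i, ] > 0)
      sum(alive > 0) / n0
    }, numeric(1)))
    x <- (0:nr) / nr
    sum(diff(x) * (head(surv, -1) + tail(surv, -1)) / 2)
  }, numeric(1))
  mean(areas)
}

# random small count matrix with no empty rows/columns
random_count_matrix <- function(r, c, max_count = 5, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(r * c, 1.2), r, c)
    m[m > max_count] <- max_count
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
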