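# Independent brute-force oracles used by several test files. These are
# deliberately naive re-derivations, kept separate from the package code
# paths they check.

# All strict local maxima by direct scan; the leftmost point of a plateau
# counts as the maximum. Endpoints are excluded.
brute_local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] <= y[i - 1]) next
    # walk right across any plateau
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    if (j < n && y[j + 1] < y[i]) out <- c(out, i)
  }
  out
}

# Step-up FDR adjustment from its definition: sort ascending, multiply by
# m / rank, enforce monotonicity from the largest rank down, cap at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Minimum-total-distance one-to-one assignment between database wavenumbers
# and detected positions (within tolerance), by exhaustive enumeration over
# subsets and permutations. Returns the maximum number of matchable pairs
# (ties broken by total distance, which is what greedy should achieve on
# the tested instances).
brute_assignment_count <- function(db_wn, positions, tolerance) {
  k <- length(db_wn)
  best_n <- 0
  if (k == 0 || length(positions) == 0) return(0)
  feasible <- function(r, q) abs(db_wn[r] - positions[q]) <= tolerance
  # recursion over records, each record matched to an unused peak or skipped
  rec <- function(r, used, n) {
    if (r > k) {
      best_n <<- max(best_n, n)
      return(invisible())
    }
    rec(r + 1, used, n)
    for (q in seq_along(positions)) {
      if (!used[q] && feasible(r, q)) {
        used[q] <- TRUE
        rec(r + 1, used, n + 1)
        used[q] <- FALSE
      }
    }
  }
  rec(1, logical(length(positions)), 0)
  best_n
}

# Direct analytic evaluation of the planted-peak sum on a grid, written
# independently of the generator internals.
analytic_signal <- function(grid, centers, heights, fwhm, eta = 0.7) {
  y <- numeric(length(grid))
  for (i in seq_along(centers)) {
    u <- (grid - centers[i]) / (fwhm / 2)
    y <- y + heights[i] * (eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2))
  }
  y
}

# A minimal synthetic spectrum for unit tests.
simple_spectrum <- function(intensity, from = 880, by = 1, window = 2) {
  raman_spectrum(seq(from, by = by, length.out = length(intensity)),
                 intensity, window)
}

table2_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- signature_db_table2()
    db
  }
})
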