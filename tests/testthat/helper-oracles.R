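# Independent oracles used to validate the package's vectorized / greedy
# implementations. All are written directly from the definitions and stay
# deliberately naive.

# Benjamini-Hochberg step-up, evaluated literally:
# q_i = min_{j >= i} p_(j) * m / j, clipped at 1, back in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Jaccard index of two binary rows via explicit active-bin sets.
oracle_jaccard <- function(a, b) {
  A <- which(a == 1)
  B <- which(b == 1)
  u <- length(union(A, B))
  if (u == 0) return(NA_real_)
  length(intersect(A, B)) / u
}

# Forward smoothing evaluated literally from its definition.
oracle_forward_smooth <- function(y, lookahead) {
  n <- length(y)
  sapply(seq_len(n), function(t) {
    idx <- t:min(n, t + lookahead)
    as.integer(any(y[idx] == 1))
  })
}

# Maximum number of event-disjoint occurrences of an ordered motif, by
# exhaustive branch-and-bound over all candidate occurrences. `times` is a
# list of sorted per-cell event-time vectors (cell order = motif order).
oracle_max_disjoint <- function(times, gap, lag) {
  m <- length(times)
  cands <- list()
  rec <- function(level, prev, picks) {
    if (level > m) {
      cands[[length(cands) + 1]] <<- picks
      return(invisible())
    }
    tt <- times[[level]]
    for (i in seq_along(tt)) {
      ok <- if (level == 1) TRUE else (tt[i] > prev + gap && tt[i] <= prev + lag)
      if (ok) rec(level + 1, tt[i], c(picks, i))
    }
  }
  rec(1L, NA_real_, integer())
  n <- length(cands)
  if (n == 0) return(0L)
  cap <- min(lengths(times))
  best <- 0L
  sel <- function(k, used, cnt) {
    if (best >= cap) return(invisible())
    if (k > n) {
      best <<- max(best, cnt)
      return(invisible())
    }
    if (cnt + (n - k + 1) <= best) return(invisible())
    p <- cands[[k]]
    free <- all(vapply(seq_len(m), function(c) !used[[c]][p[c]], logical(1)))
    if (free) {
      used2 <- used
      for (c in seq_len(m)) used2[[c]][p[c]] <- TRUE
      sel(k + 1, used2, cnt + 1L)
    }
    sel(k + 1, used, cnt)
  }
  sel(1L, lapply(lengths(times), function(l) rep(FALSE, l)), 0L)
  best
}

# random tiny motif instance for the greedy-vs-oracle sweeps
random_motif_instance <- function(n_cells, max_events_per_cell, span = 10) {
  lapply(seq_len(n_cells), function(i)
    sort(round(runif(sample.int(max_events_per_cell, 1), 0, span), 2)))
}
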