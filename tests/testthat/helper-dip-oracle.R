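# Independent brute-force oracles for the dip statistic.
#
# Both oracles share only the definition of the statistic: the smallest
# sup-distance between the ECDF and a unimodal CDF (convex below the mode,
# concave above, atom allowed at the mode). They enumerate mode placements
# explicitly and evaluate convex minorants / concave majorants by brute
# chord search over all point pairs -- no incremental hulls, no shared code
# with the package implementation.

dip_blocks <- function(x) {
  x <- sort(x)
  v <- unique(x)
  top <- cumsum(tabulate(match(x, v)))
  list(v = v, bot = c(0, top[-length(top)]), top = top, n = length(x))
}

# Greatest convex minorant of points (v, y), evaluated at every v: the
# minimum over all chords through point pairs straddling each position.
brute_gcm <- function(v, y) {
  B <- length(v)
  vapply(seq_len(B), function(i) {
    best <- y[i]
    for (j in seq_len(i)) {
      ks <- setdiff(i:B, j)
      if (length(ks)) {
        vals <- y[j] + (y[ks] - y[j]) * (v[i] - v[j]) / (v[ks] - v[j])
        best <- min(best, vals)
      }
    }
    best
  }, numeric(1))
}

brute_lcm <- function(v, y) -brute_gcm(v, -y)

# Oracle 1: grid search over mode placements; for each placement the
# smallest attainable sup-distance on the convex side is half the largest
# gap between the ECDF's upper step corners and the greatest convex
# minorant of its lower corners (and mirrored on the concave side).
oracle_dip_gridsearch <- function(x) {
  b <- dip_blocks(x)
  B <- length(b$v)
  n <- b$n
  left_gap <- function(idx) {
    if (length(idx) == 0) return(0)
    g <- brute_gcm(b$v[idx], b$bot[idx])
    max(b$top[idx] - g)
  }
  right_gap <- function(idx) {
    if (length(idx) == 0) return(0)
    l <- brute_lcm(b$v[idx], b$top[idx])
    max(l - b$bot[idx])
  }
  best <- Inf
  for (a in 0:B) {          # convex side covers blocks seq_len(a)
    for (skip in 0:1) {     # optionally absorb one block into the mode atom
      q <- a + skip + 1     # concave side starts here
      if (q > B + 1) next
      gap <- max(left_gap(seq_len(a)),
                 right_gap(if (q <= B) q:B else integer(0)))
      if (gap < best) best <- gap
    }
  }
  max(best, 1) / (2 * n)
}

# Oracle 2: bisection on the sup-distance d. For a given d, a unimodal CDF
# within d of the ECDF exists iff for some mode placement a convex function
# fits inside the corridor [top - d, bot + d] on the left blocks and a
# concave one on the right blocks; each corridor test uses the brute-chord
# minorant/majorant of the corridor boundary. Quadratic-time per test and
# only meant for small n.
oracle_dip_bisection <- function(x, iters = 50) {
  b <- dip_blocks(x)
  B <- length(b$v)
  n <- b$n
  conv_ok <- function(idx, d) {
    if (length(idx) == 0) return(TRUE)
    up <- b$bot[idx] / n + d
    lo <- b$top[idx] / n - d
    all(brute_gcm(b$v[idx], up) >= lo - 1e-12)
  }
  conc_ok <- function(idx, d) {
    if (length(idx) == 0) return(TRUE)
    up <- b$bot[idx] / n + d
    lo <- b$top[idx] / n - d
    all(brute_lcm(b$v[idx], lo) <= up + 1e-12)
  }
  feasible <- function(d) {
    for (a in 0:B) {
      for (skip in 0:1) {
        q <- a + skip + 1
        if (q > B + 1) next
        if (conv_ok(seq_len(a), d) &&
            conc_ok(if (q <= B) q:B else integer(0), d)) return(TRUE)
      }
    }
    FALSE
  }
  lo <- 0; hi <- 0.5
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  max(hi, 1 / (2 * n))
}
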