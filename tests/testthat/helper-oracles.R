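# Independent oracles: deliberately naive re-implementations used only to
# check the package's fast paths.

# naive signed inner product by explicit summation
naive_ip <- function(g, r) {
  s <- 0
  for (i in seq_along(g)) s <- s + g[i] * r[i]
  s
}

# One brute-force matching-pursuit step: loops over all atoms with naive
# sums, returns the argmax of the normalized signed inner product (earliest
# onset on ties) and the projection coefficient.
oracle_mp_step <- function(atoms, norms, r) {
  best <- -Inf
  best_j <- NA_integer_
  for (j in seq_len(ncol(atoms))) {
    crit <- naive_ip(atoms[, j], r) / norms[j]
    if (is.na(best_j) || crit > best + 1e-15 * max(1, abs(best))) {
      best <- crit
      best_j <- j
    }
  }
  list(j = best_j, crit = best,
       a = naive_ip(atoms[, best_j], r) / norms[best_j]^2)
}

# normal-equations least squares
oracle_lsq <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Greedy nearest-in-time matching, re-implemented with flat pair lists and
# repeated full scans (no matrices): earlier true onset wins ties, then
# earlier estimated onset.
oracle_greedy_match <- function(tr, es) {
  tr <- sort(tr); es <- sort(es)
  cand <- expand.grid(i = seq_along(tr), j = seq_along(es))
  cand$d <- abs(tr[cand$i] - es[cand$j])
  pairs <- NULL
  while (nrow(cand) > 0) {
    m <- min(cand$d)
    hit <- cand[cand$d <= m, , drop = FALSE]
    hit <- hit[order(hit$i, hit$j), , drop = FALSE][1, ]
    pairs <- rbind(pairs, hit)
    cand <- cand[cand$i != hit$i & cand$j != hit$j, , drop = FALSE]
  }
  pairs[order(pairs$i), c("i", "j"), drop = FALSE]
}
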