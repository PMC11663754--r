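# shared test helpers

# a reproducible random value system on an arbitrary scheme, drawn like the
# generator draws truth (Dirichlet weights, stick-breaking level spacings)
random_value_system <- function(scheme, seed) {
  set.seed(seed)
  nc <- length(scheme$criteria); L <- scheme$n_levels
  w <- stats::rgamma(nc, shape = 3); w <- 100 * w / sum(w)
  v <- matrix(0, nc, L)
  for (ci in seq_len(nc)) {
    inc <- stats::rgamma(L - 1L, shape = 1)
    v[ci, ] <- w[ci] * c(0, cumsum(inc / sum(inc)))
  }
  v[, L] <- w
  value_system(v * (100 / sum(v[, L])), scheme)
}

# all alternatives of a scheme as a matrix (rows = alternatives)
enumerate_alternatives <- function(scheme) {
  g <- do.call(expand.grid, rep(list(seq_len(scheme$n_levels)),
                                length(scheme$criteria)))
  as.matrix(g)
}

total_value <- function(truth, alt) {
  sum(truth$values[cbind(seq_along(alt), alt)])
}

# the undominated two-criterion alternative pairs of a scheme
two_criterion_pairs <- function(scheme) {
  alts <- enumerate_alternatives(scheme)
  n <- nrow(alts)
  out <- list()
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    d <- which(alts[a, ] != alts[b, ])
    if (length(d) != 2L) next
    s <- sign(alts[a, d] - alts[b, d])
    if (s[1] == s[2]) next                    # one dominates the other
    out[[length(out) + 1L]] <- c(a, b)
  }
  list(alts = alts, pairs = do.call(rbind, out))
}

# signs of solved/true increment differences over a session's comparisons
comparison_signs <- function(session, values, tol = 1e-9) {
  inc <- session$inc
  d <- values[cbind(inc$crit, inc$hi)] -
    ifelse(inc$lo > 1L, values[cbind(inc$crit, inc$lo)], 0)
  diff <- d[session$comp$i] - d[session$comp$j]
  ifelse(abs(diff) < tol, 0L, ifelse(diff > 0, 1L, -1L))
}
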