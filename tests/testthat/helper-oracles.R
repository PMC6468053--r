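# Independent oracles used by the property and acceptance suites. These
# deliberately re-derive everything with their own numerical path (direct
# quadrature, per-cell root finding, exhaustive enumeration) so they never
# share code with the implementations they check.

# --- matrix temperature -----------------------------------------------------

oracle_cell_weights <- function(n, m, fill) {
  iso <- function(x, p) 1 - (1 - (1 - x)^p)^(1/p)
  p <- uniroot(function(p)
    integrate(iso, 0, 1, p = p)$value - fill, c(1e-6, 30),
    extendInt = "downX", tol = 1e-10)$root
  r <- (seq_len(n) - 0.5) / n
  cc <- (seq_len(m) - 0.5) / m
  xs <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    xs[i, j] <- uniroot(function(x) iso(x, p) - (cc[j] - r[i]) - x,
                        c(0, 1), tol = 1e-10)$root
  list(u = (matrix(r, n, m) - xs) / (1 - abs(outer(r, cc, "-"))))
}

oracle_packed_temperature <- function(packed, w) {
  u <- w$u
  u[u < 0 & packed == 1] <- 0
  u[u > 0 & packed == 0] <- 0
  100 * sum(u^2) / length(packed) / 0.04145
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

oracle_min_temperature <- function(m) {
  w <- oracle_cell_weights(nrow(m), ncol(m), mean(m))
  best <- Inf
  for (rp in all_perms(nrow(m))) for (cp in all_perms(ncol(m))) {
    t <- oracle_packed_temperature(m[rp, cp, drop = FALSE], w)
    if (t < best) best <- t
  }
  best
}

# --- Newman-Girvan modularity ----------------------------------------------

edge_list <- function(m) {
  pres <- which(unclass(m) == 1L, arr.ind = TRUE)
  cbind(pres[, 1L], nrow(m) + pres[, 2L])   # items offset past individuals
}

q_of_partition <- function(edges, membership) {
  L <- nrow(edges)
  cls <- sort(unique(membership))
  sum(vapply(cls, function(c) {
    within <- sum(membership[edges[, 1]] == c & membership[edges[, 2]] == c)
    dc <- sum(membership[edges[, 1]] == c) + sum(membership[edges[, 2]] == c)
    within / L - (dc / (2 * L))^2
  }, numeric(1)))
}

# exhaustive maximum over all set partitions (restricted growth strings)
max_q_exhaustive <- function(edges, n_nodes) {
  best <- -Inf
  grow <- function(memb, next_max) {
    if (length(memb) == n_nodes) {
      best <<- max(best, q_of_partition(edges, memb))
      return(invisible())
    }
    for (c in seq_len(next_max + 1L))
      grow(c(memb, c), max(next_max, c))
  }
  grow(integer(0), 0L)
  best
}
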