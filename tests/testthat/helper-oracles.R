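# Independent oracles used to cross-check the implementation.

# Brute-force recursive enumeration of simple paths with <= max_edges edges
# on an undirected adjacency matrix.  Deliberately naive.
brute_paths <- function(adj, src, dst, max_edges) {
  out <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    if (last == dst && length(path) >= 2) {
      out[[length(out) + 1]] <<- path
      return()
    }
    if (length(path) - 1 >= max_edges) return()
    for (nxt in which(adj[last, ])) {
      if (nxt %in% path) next
      if (nxt == dst) {
        out[[length(out) + 1]] <<- c(path, nxt)
      } else if (length(path) < max_edges) {
        recurse(c(path, nxt))
      }
    }
  }
  recurse(as.integer(src))
  if (length(out) == 0) return(list())
  out[order(vapply(out, function(p) paste(sprintf("%06d", p), collapse = ","),
                   character(1)))]
}

# Floyd-Warshall all-pairs shortest distances on a cost matrix
# (Inf = no edge).
floyd_warshall <- function(cost) {
  n <- nrow(cost)
  D <- cost
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Random small undirected test graph as a connectome (edge weights 0.1,
# distances uniform), guaranteed at least one edge.
random_small_connectome <- function(n, p = 0.5) {
  repeat {
    A <- matrix(stats::runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    if (any(A)) break
  }
  C <- ifelse(A, 0.1, 0)
  L <- matrix(0, n, n)
  L[A] <- stats::runif(sum(A), 10, 160)
  L <- (L + t(L)) / 2
  diag(L) <- 0
  connectome(C, L)
}

# Classical RK4 for a generic ODE, used to integrate the isolated synapse
# equations independently of the package integrator.
rk4 <- function(f, y0, dt, n_steps) {
  y <- matrix(NA_real_, n_steps + 1, length(y0))
  y[1, ] <- y0
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    k1 <- f(t, y[s, ])
    k2 <- f(t + dt / 2, y[s, ] + dt / 2 * k1)
    k3 <- f(t + dt / 2, y[s, ] + dt / 2 * k2)
    k4 <- f(t + dt, y[s, ] + dt * k3)
    y[s + 1, ] <- y[s, ] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}
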