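# Independent oracles used to validate package computations.
# These deliberately use different algorithms from the implementation.

# Brute-force Benjamini-Hochberg step-up: for the i-th smallest p-value,
# adj = min over j >= i of min(1, m * p_(j) / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive shortest-path betweenness via matrix-power path counting:
# the number of walks of length d(s,t) between s and t equals the number
# of shortest paths; a vertex v lies on one iff d(s,v) + d(v,t) = d(s,t).
# Ordered-pair convention (s != v != t counted in both directions).
betweenness_oracle <- function(A) {
  n <- nrow(A)
  INF <- n + 1L
  D <- matrix(INF, n, n)
  diag(D) <- 0L
  S <- array(0, c(n, n))
  P <- diag(n)
  for (d in seq_len(n - 1)) {
    P <- P %*% A
    newly <- D == INF & P > 0
    D[newly] <- d
    S[newly] <- P[newly]
  }
  diag(S) <- 1
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == v || t == v || s == t) next
        if (D[s, t] > n) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  bc
}

# Random connected graph: random spanning tree plus extra random edges.
# Returns a list(net = ppi_network, A = adjacency matrix).
random_connected_graph <- function(n, extra = n) {
  labels <- sprintf("N%03d", seq_len(n))
  edges <- if (n > 1) {
    cbind(labels[vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))],
          labels[2:n])
  } else {
    matrix(character(0), 0, 2)
  }
  if (extra > 0 && n > 2) {
    a <- sample.int(n, extra, replace = TRUE)
    b <- sample.int(n, extra, replace = TRUE)
    keep <- a != b
    edges <- rbind(edges, cbind(labels[a[keep]], labels[b[keep]]))
  }
  net <- ppi_network(edges, nodes = labels)
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  if (nrow(net$edges)) {
    ia <- match(net$edges[, 1], labels)
    ib <- match(net$edges[, 2], labels)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  list(net = net, A = A)
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
# from a universe with K marked elements.
hypergeom_enum_oracle <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}
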