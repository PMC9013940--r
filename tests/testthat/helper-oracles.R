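# Independent brute-force oracles used to check graph metrics, centrality
# measures and the diffusion engine. Everything here is computed from plain
# adjacency matrices with hand-written algorithms (Floyd-Warshall, geodesic
# enumeration, dense eigen/linear solves, Markov-chain enumeration), so the
# oracles share no code path with the package implementation.

adj_from_igraph <- function(net) {
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  A <- matrix(0, n, n)
  A[el] <- 1
  A[el[, 2:1, drop = FALSE]] <- 1
  A
}

graph_from_adj <- function(A, genders = NULL) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$gender <- genders %||% rep("M", nrow(A))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-pairs shortest path distances by Floyd-Warshall
fw_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_apl <- function(A) {
  D <- fw_distances(A)
  vals <- D[upper.tri(D)]
  mean(vals[is.finite(vals)])
}

oracle_local_cc <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    sum(A[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, numeric(1)))
}

# enumerate every geodesic between two nodes by depth-first search over the
# distance structure; returns the list of paths (vertex sequences)
all_geodesics <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (v in which(A[s, ] > 0)) {
    if (D[v, t] == D[s, t] - 1) {
      for (p in all_geodesics(A, D, v, t)) out <- c(out, list(c(s, p)))
    }
  }
  out
}

oracle_betweenness <- function(A, normalized = TRUE) {
  n <- nrow(A)
  D <- fw_distances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_geodesics(A, D, s, t)
    if (length(paths) == 0) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner))
      b <- b + tabulate(inner, nbins = n) / length(paths)
  }
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach) == 0) return(0)
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, numeric(1))
}

oracle_eigenvector <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  # dominant eigenvector of the component with the largest spectral radius
  v <- abs(e$vectors[, which.max(e$values)])
  v / max(v)
}

oracle_pagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  deg <- rowSums(A)
  M <- t(A / ifelse(deg == 0, 1, deg))     # column j: out-distribution of j
  M[, deg == 0] <- 1 / n                   # isolated nodes teleport
  x <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  x / sum(x)
}

# exact state distribution of the per-tick-reversion contagion chain on a
# tiny graph: state = influenced bitmask over nodes, seeds immune
markov_chain <- function(A, seeds, spread, resist, immune = TRUE) {
  n <- nrow(A)
  nstates <- 2^n
  bits <- function(s) as.logical(bitwAnd(s, 2^(0:(n - 1))) > 0)
  P <- matrix(0, nstates, nstates)
  for (s in 0:(nstates - 1)) {
    inf <- bits(s)
    if (any(!inf[seeds])) next      # unreachable: seeds always influenced
    p_on <- numeric(n)
    for (i in seq_len(n)) {
      if (inf[i]) {
        p_on[i] <- if (immune && i %in% seeds) 1 else 1 - resist[i]
      } else {
        keep <- prod(1 - spread[i, inf & A[i, ] > 0])
        p_on[i] <- 1 - keep
      }
    }
    for (s2 in 0:(nstates - 1)) {
      inf2 <- bits(s2)
      if (any(!inf2[seeds])) next
      P[s + 1, s2 + 1] <- prod(ifelse(inf2, p_on, 1 - p_on))
    }
  }
  P
}

state_index <- function(influenced) sum(2^(which(influenced) - 1)) + 1

markov_distribution_after <- function(A, seeds, spread, resist, t, immune = TRUE) {
  P <- markov_chain(A, seeds, spread, resist, immune)
  start <- numeric(nrow(P))
  start[state_index(seq_len(nrow(A)) %in% seeds)] <- 1
  for (k in seq_len(t)) start <- start %*% P
  as.numeric(start)
}

# expected absorption time (all influenced) for a resistance-0 chain
markov_expected_absorption <- function(A, seeds, spread, tmax = 2000) {
  n <- nrow(A)
  P <- markov_chain(A, seeds, spread, resist = rep(0, n))
  full <- 2^n
  start <- numeric(full); start[state_index(seq_len(n) %in% seeds)] <- 1
  p_absorbed <- numeric(tmax)
  d <- start
  for (t in seq_len(tmax)) {
    d <- d %*% P
    p_absorbed[t] <- d[full]
  }
  # E[T] = sum_{t>=0} P(T > t); the t = 0 term is P(not absorbed at start)
  (1 - start[full]) + sum(1 - p_absorbed)
}

# random connected graph on n nodes (edge probability p, retried)
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(runif(length(up)) < p)
    A <- A + t(A)
    D <- fw_distances(A)
    if (all(is.finite(D))) return(A)
  }
}

# every connected graph on n <= 5 labelled nodes (edge-subset enumeration)
all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in 1:(2^m - 1)) {
    A <- matrix(0, n, n)
    sel <- which(bitwAnd(mask, 2^(0:(m - 1))) > 0)
    for (e in sel) {
      A[pairs[e, 1], pairs[e, 2]] <- 1
      A[pairs[e, 2], pairs[e, 1]] <- 1
    }
    if (all(is.finite(fw_distances(A)))) out[[length(out) + 1]] <- A
  }
  out
}
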