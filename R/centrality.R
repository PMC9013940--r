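# Centrality measures used to select influential agents, plus top-fraction
# and random seed selection.

#' Centrality scores of a network
#'
#' Dispatcher over the four supported measures. Conventions:
#' * betweenness: shortest-path betweenness with fractional credit for
#'   multiple geodesics; normalised by `(n-1)(n-2)/2` when requested.
#' * closeness: Wasserman-Faust component-size-scaled closeness,
#'   `((r-1)/(n-1)) * ((r-1) / sum of distances)` with `r` the size of the
#'   node's component; equals `(n-1)/sum d` on connected graphs. Isolated
#'   nodes score 0.
#' * eigenvector: power iteration (see [eigenvector_centrality()]),
#'   rescaled so the maximum score is exactly 1.
#' * pagerank: undirected PageRank with damping 0.85; scores sum to 1.
#'
#' @param net igraph network.
#' @param measure one of `"betweenness"`, `"closeness"`, `"eigenvector"`,
#'   `"pagerank"`.
#' @param ... passed to the measure-specific function.
#' @return an object of class `centrality_scores`: list with `measure` and
#'   `scores` (numeric, one per node).
#' @export
centrality_scores <- function(net, measure = c("betweenness", "closeness",
                                               "eigenvector", "pagerank"),
                              ...) {
  measure <- match.arg(measure)
  scores <- switch(measure,
    betweenness = betweenness_centrality(net, ...),
    closeness = closeness_centrality(net, ...),
    eigenvector = eigenvector_centrality(net, ...),
    pagerank = pagerank_centrality(net, ...))
  structure(list(measure = measure, scores = scores),
            class = "centrality_scores")
}

#' Betweenness centrality
#'
#' @param net igraph network.
#' @param normalized divide by `(n-1)(n-2)/2`, the number of ordered pairs a
#'   node can mediate in an undirected graph.
#' @return numeric vector of scores.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  n <- igraph::vcount(net)
  if (normalized && n < 3)
    stop_config("normalised betweenness needs at least 3 nodes")
  as.numeric(igraph::betweenness(net, directed = FALSE, normalized = normalized))
}

#' Closeness centrality (component-size scaled)
#'
#' @param net igraph network.
#' @return numeric vector of scores in `[0, 1]`; carries attribute
#'   `has_isolates` when any node scores 0.
#' @export
closeness_centrality <- function(net) {
  n <- igraph::vcount(net)
  d <- igraph::distances(net)
  scores <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  attr(scores, "has_isolates") <- any(scores == 0)
  scores
}

#' Eigenvector centrality by power iteration
#'
#' Power iteration from a uniform positive start, L2-normalised each step,
#' declared converged when successive iterates differ by less than `tol` in
#' max-norm; the converged vector is rescaled so its maximum is exactly 1.
#' By default the iteration runs on `I + A` (`shift = 1`): the unit diagonal
#' shift leaves the eigenvectors unchanged while making the dominant
#' eigenvalue strictly largest in magnitude, so bipartite graphs - on which
#' the pure adjacency iteration oscillates between two accumulation points -
#' converge as well. Set `shift = 0` for the pure adjacency iteration; it
#' fails with a convergence error on bipartite structure.
#'
#' On disconnected graphs the iteration converges to the dominant
#' eigenvector of the component with the largest spectral radius; scores off
#' that component decay towards 0, and the attribute `support_component`
#' records which component carries the scores.
#'
#' @param net igraph network.
#' @param max_iter maximum iterations.
#' @param tol max-norm convergence tolerance.
#' @param shift diagonal shift added to the adjacency operator.
#' @return numeric vector of scores with maximum exactly 1.
#' @export
eigenvector_centrality <- function(net, max_iter = 10000, tol = 1e-12, shift = 1) {
  n <- igraph::vcount(net)
  if (n == 0) stop_config("empty network")
  A <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + shift * x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) break  # empty graph with shift 0: scores are uniform zeros
    y <- y / nrm
    if (max(abs(y - x)) < tol) {
      if (max(y) <= 0) break
      scores <- y / max(y)
      comp <- igraph::components(net)$membership
      attr(scores, "support_component") <- comp[which.max(scores)]
      return(scores)
    }
    x <- y
  }
  if (igraph::ecount(net) == 0) return(rep(1, n))
  stop_config("power iteration did not converge in ", max_iter,
              " iterations; the graph is likely bipartite - use shift = 1 ",
              "(default) or raise max_iter")
}

#' PageRank centrality
#'
#' Undirected PageRank (each edge acts as two directed links) with the
#' teleportation convention that a message moves randomly 15% of the time
#' (damping 0.85). Scores sum to 1.
#'
#' @param net igraph network.
#' @param damping damping factor.
#' @return numeric vector of scores summing to 1.
#' @export
pagerank_centrality <- function(net, damping = 0.85) {
  check_prob(damping, "damping")
  as.numeric(igraph::page_rank(net, damping = damping)$vector)
}

#' Select the top-fraction seed set from centrality scores
#'
#' The `floor(fraction * n)` highest-scoring nodes. Ties at the cut are
#' broken by lowest node id (deterministic, default) or at random under a
#' seed.
#'
#' @param scores a [centrality_scores()] object (or bare numeric vector).
#' @param fraction proportion of nodes to seed.
#' @param tiebreak `"lowest-id"` or `"random"`.
#' @param seed RNG seed for the random tie-break.
#' @return an object of class `seed_set`: list with `ids` (integer vector),
#'   `fraction`, `measure`.
#' @export
select_top_seeds <- function(scores, fraction = 0.15,
                             tiebreak = c("lowest-id", "random"), seed = NULL) {
  tiebreak <- match.arg(tiebreak)
  check_prob(fraction, "fraction")
  measure <- if (inherits(scores, "centrality_scores")) scores$measure else "scores"
  s <- if (inherits(scores, "centrality_scores")) scores$scores else scores
  n <- length(s)
  size <- floor(fraction * n)
  ids <- if (size == 0) integer(0)
  else if (tiebreak == "lowest-id") order(-s, seq_len(n))[seq_len(size)]
  else with_seed(seed, order(-s, sample.int(n))[seq_len(size)])
  structure(list(ids = as.integer(ids), fraction = fraction, measure = measure),
            class = "seed_set")
}

#' Select a uniform random seed set
#'
#' @param net igraph network.
#' @param fraction proportion of nodes to seed.
#' @param seed RNG seed (`NULL`: current stream).
#' @return a `seed_set` (see [select_top_seeds()]) with measure `"random"`.
#' @export
select_random_seeds <- function(net, fraction = 0.15, seed = NULL) {
  check_prob(fraction, "fraction")
  n <- igraph::vcount(net)
  size <- floor(fraction * n)
  ids <- with_seed(seed, sort(sample.int(n, size)))
  structure(list(ids = as.integer(ids), fraction = fraction, measure = "random"),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set: %d seeds (fraction %.2f, measure %s)\n",
              length(x$ids), x$fraction, x$measure))
  invisible(x)
}

#' Tabulate centrality scores with ranks and seed membership
#'
#' @param net igraph network.
#' @param scores a [centrality_scores()] object.
#' @param seeds a `seed_set`.
#' @return data.frame with columns `node_id`, `gender`, `measure`, `score`,
#'   `rank`, `is_seed`.
#' @export
scores_table <- function(net, scores, seeds) {
  s <- scores$scores
  data.frame(node_id = seq_along(s),
             gender = igraph::V(net)$gender,
             measure = scores$measure,
             score = as.numeric(s),
             rank = rank(-s, ties.method = "min"),
             is_seed = seq_along(s) %in% seeds$ids)
}
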