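# Gendered small-world network generation and structural metrics.
#
# A social network is an undirected simple igraph object whose vertices carry
# a "gender" attribute ("F" or "M"). Construction composes a ring lattice,
# gender assignment, and a gender-aware Watts-Strogatz-style rewiring pass.

GENDERS <- c("F", "M")

#' Network generation specification
#'
#' @param n number of agents.
#' @param n_female number of female agents.
#' @param ring_degree even ring-lattice degree `k` (each node links to
#'   `k/2` neighbours on either side).
#' @param rewire_prob probability `p` that a lattice edge is rewired.
#' @param homophily_prob probability `q` that a rewired endpoint is drawn
#'   from same-gender candidates only.
#' @param gender_layout `"blocks"` (two contiguous arcs), `"interleaved"`,
#'   or `"random"`.
#' @param seed RNG seed (`NULL`: use the current RNG stream).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(n = 234, n_female = 113, ring_degree = 4,
                         rewire_prob = 0.05, homophily_prob = 0,
                         gender_layout = c("blocks", "interleaved", "random"),
                         seed = NULL) {
  gender_layout <- match.arg(gender_layout)
  if (ring_degree %% 2 != 0 || ring_degree < 2 || ring_degree >= n)
    stop_config("ring_degree must be even, >= 2 and < n")
  if (n_female > n) stop_config("n_female must not exceed n")
  check_prob(rewire_prob, "rewire_prob")
  check_prob(homophily_prob, "homophily_prob")
  structure(list(n = n, n_female = n_female, ring_degree = ring_degree,
                 rewire_prob = rewire_prob, homophily_prob = homophily_prob,
                 gender_layout = gender_layout, seed = seed),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(paste0("network_spec: n=%d (%d F / %d M), k=%d, p=%.3f, ",
                     "q=%.2f, layout=%s\n"),
              x$n, x$n_female, x$n - x$n_female, x$ring_degree,
              x$rewire_prob, x$homophily_prob, x$gender_layout))
  invisible(x)
}

#' Build an ungendered ring lattice
#'
#' Each node `i` is linked to `i +/- 1 .. i +/- k/2` (mod `n`), giving
#' `n k / 2` edges.
#'
#' @param n number of nodes.
#' @param k even degree, `k < n`.
#' @return an igraph object with a `gender` vertex attribute set to `NA`.
#' @export
build_ring_lattice <- function(n, k) {
  if (k %% 2 != 0 || k < 2 || k >= n)
    stop_config("k must be even, >= 2 and < n")
  i <- rep(seq_len(n), k / 2)
  d <- rep(seq_len(k / 2), each = n)
  j <- (i - 1 + d) %% n + 1
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  igraph::V(g)$gender <- NA_character_
  g
}

#' Assign genders to the nodes of a network
#'
#' @param net igraph network.
#' @param n_female number of female nodes.
#' @param layout `"blocks"` (nodes `1..n_female` female, forming two
#'   contiguous arcs on a ring), `"interleaved"` (alternating as evenly as
#'   possible), or `"random"` (uniform placement).
#' @param seed RNG seed for the random layout.
#' @return the network with its `gender` vertex attribute set.
#' @export
assign_genders <- function(net, n_female,
                           layout = c("blocks", "interleaved", "random"),
                           seed = NULL) {
  layout <- match.arg(layout)
  n <- igraph::vcount(net)
  if (n_female > n) stop_config("n_female must not exceed node count")
  gender <- rep("M", n)
  if (layout == "blocks") {
    gender[seq_len(n_female)] <- "F"
  } else if (layout == "interleaved") {
    odd <- seq(1, n, by = 2)
    take <- head(odd, n_female)
    gender[take] <- "F"
    extra <- n_female - length(take)
    if (extra > 0) gender[head(seq(2, n, by = 2), extra)] <- "F"
  } else {
    gender[with_seed(seed, sample.int(n, n_female))] <- "F"
  }
  igraph::V(net)$gender <- gender
  net
}

#' Gender-aware rewiring of a network
#'
#' Each edge is independently selected with probability `p`. For a selected
#' edge `(u, v)` the far endpoint `v` is replaced by a node `w != u` not
#' already adjacent to `u`; with probability `q` the candidate pool is
#' restricted to nodes of `u`'s gender, otherwise all nodes are eligible.
#' Edges are processed sequentially so the simple-graph invariant holds at
#' every step; the edge count never changes, node degrees may. If no
#' admissible target exists the edge is left in place with a warning.
#'
#' @param net igraph network with genders assigned.
#' @param p rewiring probability per edge.
#' @param q homophily probability.
#' @param seed RNG seed (`NULL`: current stream).
#' @return the rewired network.
#' @export
gendered_rewire <- function(net, p, q, seed = NULL) {
  check_prob(p, "p"); check_prob(q, "q")
  gender <- igraph::V(net)$gender
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  with_seed(seed, {
    adj <- matrix(FALSE, n, n)
    adj[el] <- TRUE
    adj[el[, 2:1, drop = FALSE]] <- TRUE
    sel <- which(runif(nrow(el)) < p)
    for (e in sel) {
      u <- el[e, 1]; v <- el[e, 2]
      same_only <- runif(1) < q
      cand <- if (same_only) which(gender == gender[u]) else seq_len(n)
      cand <- cand[cand != u & !adj[u, cand]]
      if (length(cand) == 0) {
        warning("no admissible rewiring target for edge ", u, "-", v,
                "; edge left in place")
        next
      }
      w <- cand[sample.int(length(cand), 1)]
      adj[u, v] <- adj[v, u] <- FALSE
      adj[u, w] <- adj[w, u] <- TRUE
      el[e, ] <- c(u, w)
    }
  })
  out <- igraph::graph_from_edgelist(el, directed = FALSE)
  out <- igraph::add_vertices(out, max(0, n - igraph::vcount(out)))
  igraph::V(out)$gender <- gender
  out
}

#' Generate a gendered small-world network
#'
#' Composition of [build_ring_lattice()], [assign_genders()] and
#' [gendered_rewire()], reproducible under the spec's seed.
#'
#' @param spec a [network_spec()].
#' @return an igraph network with a `gender` vertex attribute.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(spec$seed, {
    net <- build_ring_lattice(spec$n, spec$ring_degree)
    net <- assign_genders(net, spec$n_female, spec$gender_layout, seed = NULL)
    gendered_rewire(net, spec$rewire_prob, spec$homophily_prob, seed = NULL)
  })
}

#' Structural metrics of a gendered network
#'
#' Mean local clustering coefficient (nodes of degree < 2 contribute 0),
#' average shortest-path length over connected pairs (computed on the
#' largest component if the graph is disconnected, with a flag), the
#' proportions of male-male / female-female / male-female links, and the
#' mean degree.
#'
#' @param net igraph network with genders assigned.
#' @return an object of class `network_metrics`: a list with
#'   `clustering_coefficient`, `average_path_length`, `link_proportions`
#'   (named `mm`, `ff`, `mf`), `degree_mean`, `disconnected`.
#' @export
compute_metrics <- function(net) {
  if (igraph::vcount(net) == 0) stop_config("empty network")
  cc <- igraph::transitivity(net, type = "localaverage", isolates = "zero")
  disconnected <- !igraph::is_connected(net)
  gc <- if (disconnected) {
    comp <- igraph::components(net)
    igraph::induced_subgraph(net, which(comp$membership == which.max(comp$csize)))
  } else net
  apl <- igraph::mean_distance(gc)
  el <- igraph::as_edgelist(net, names = FALSE)
  gender <- igraph::V(net)$gender
  g1 <- gender[el[, 1]]; g2 <- gender[el[, 2]]
  m <- nrow(el)
  props <- if (m == 0) c(mm = 0, ff = 0, mf = 0) else
    c(mm = sum(g1 == "M" & g2 == "M") / m,
      ff = sum(g1 == "F" & g2 == "F") / m,
      mf = sum(g1 != g2) / m)
  structure(list(clustering_coefficient = cc,
                 average_path_length = apl,
                 link_proportions = props,
                 degree_mean = mean(igraph::degree(net)),
                 disconnected = disconnected),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("network_metrics: CC=%.3f APL=%.3f degree=%.2f%s\n",
              x$clustering_coefficient, x$average_path_length, x$degree_mean,
              if (x$disconnected) " (APL on largest component)" else ""))
  cat(sprintf("  link proportions: MM=%.3f FF=%.3f MF=%.3f\n",
              x$link_proportions["mm"], x$link_proportions["ff"],
              x$link_proportions["mf"]))
  invisible(x)
}

#' Network I/O
#'
#' GraphML round-trip (with the `gender` vertex attribute) and a plain
#' tab-separated edge list with a side-car node-attribute file.
#'
#' @param net igraph network.
#' @param path output path (for the edge list, the side-car file is
#'   `<path>.nodes`).
#' @return the path (writers, invisibly) or an igraph network (readers).
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net, names = FALSE)
  utils::write.table(el, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  nodes <- data.frame(node_id = seq_len(igraph::vcount(net)),
                      gender = igraph::V(net)$gender)
  utils::write.table(nodes, paste0(path, ".nodes"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_edgelist <- function(path) {
  el <- as.matrix(utils::read.table(path, sep = "\t"))
  nodes <- utils::read.table(paste0(path, ".nodes"), sep = "\t", header = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(nodes) - igraph::vcount(g)))
  igraph::V(g)$gender <- nodes$gender[order(nodes$node_id)]
  g
}

#' Read / write a network spec as YAML or JSON
#'
#' @param spec a [network_spec()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return the path (writer, invisibly) or a [network_spec()] (reader).
#' @export
write_network_spec <- function(spec, path) {
  lst <- unclass(spec)
  if (grepl("\\.json$", path)) jsonlite::write_json(lst, path, auto_unbox = TRUE)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  network_spec(n = lst$n, n_female = lst$n_female,
               ring_degree = lst$ring_degree, rewire_prob = lst$rewire_prob,
               homophily_prob = lst$homophily_prob,
               gender_layout = lst$gender_layout, seed = lst$seed)
}
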