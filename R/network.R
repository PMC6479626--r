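#' Build a small-world household contact network
#'
#' Watts-Strogatz construction: households are placed on a ring (ordered
#' by map position, so ring neighbours are geographically close), each
#' linked to its `k` nearest ring neighbours, and each lattice edge is then
#' independently rewired with probability `p_rewire` by redirecting its
#' far endpoint to a uniformly chosen node that is neither the home node
#' nor already a neighbour of it. Rewiring preserves the edge count
#' (`n * k / 2`) and never creates self-loops or duplicate edges, so the
#' mean degree is exactly `k` while clustering stays high and path lengths
#' shrink -- the "small world" of an urban neighbourhood.
#'
#' @param n number of nodes; must exceed `k`. An edge whose home node is
#'   already linked to every other node is left in place.
#' @param k even number of lattice neighbours per node.
#' @param p_rewire per-edge rewiring probability.
#' @param seed optional integer seed.
#' @param order optional integer permutation giving the ring order of
#'   nodes (e.g. households sorted by location); default identity.
#' @return An object of class `fsabm_network`: list with `n`, `edges`
#'   (2-column matrix, each row an unordered pair), `adjacency` (list of
#'   integer neighbour vectors), `k`, `p_rewire`.
#' @examples
#' net <- build_small_world(100, 4, 0.2, seed = 1)
#' nrow(net$edges)  # 200 edges = n * k / 2
#' @export
build_small_world <- function(n, k = 4, p_rewire = 0.2, seed = NULL, order = NULL) {
  if (!is.numeric(n) || n != floor(n) || n <= k)
    stop("n must be an integer greater than k", call. = FALSE)
  if (k %% 2 != 0 || k < 2) stop("k must be a positive even integer", call. = FALSE)
  check_prob(p_rewire, "p_rewire")
  n <- as.integer(n); k <- as.integer(k)
  if (!is.null(seed)) set.seed(seed)
  ring <- if (is.null(order)) seq_len(n) else as.integer(order)

  # ring lattice: node i links to its k/2 successors (covers all k-neighbour
  # pairs once)
  from <- rep(ring, each = k %/% 2L)
  offs <- rep(seq_len(k %/% 2L), times = n)
  to <- ring[((rep(seq_len(n), each = k %/% 2L) + offs - 1L) %% n) + 1L]

  # adjacency as an environment-free list of sorted integer vectors
  adj <- vector("list", n)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }

  rewire <- stats::runif(length(from)) < p_rewire
  for (e in which(rewire)) {
    home <- from[e]; old <- to[e]
    forbidden <- c(home, adj[[home]])
    if (length(forbidden) >= n) next  # home already linked to everyone
    repeat {
      cand <- sample.int(n, 1L)
      if (!(cand %in% forbidden)) break
    }
    to[e] <- cand
    adj[[home]] <- c(setdiff(adj[[home]], old), cand)
    adj[[old]] <- setdiff(adj[[old]], home)
    adj[[cand]] <- c(adj[[cand]], home)
  }

  structure(list(
    n = n,
    edges = cbind(from = from, to = to),
    adjacency = lapply(adj, sort),
    k = k,
    p_rewire = p_rewire
  ), class = "fsabm_network")
}

as_igraph <- function(net) {
  igraph::graph_from_edgelist(net$edges, directed = FALSE)
}

#' Summary statistics of a contact network
#'
#' Mean degree (`2 * edges / n`), average local clustering coefficient and
#' mean shortest-path length. If the network is disconnected the path
#' length is computed on the largest connected component and this is
#' reported in the `component` field.
#'
#' @param net an `fsabm_network`.
#' @return List with `mean_degree`, `clustering_coefficient`,
#'   `mean_path_length`, `component` (`"full"` or `"largest"`).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "fsabm_network"))
  if (net$n == 0L || nrow(net$edges) == 0L)
    stop("network has no edges", call. = FALSE)
  g <- as_igraph(net)
  connected <- igraph::is_connected(g)
  gc <- if (connected) g else {
    comp <- igraph::components(g)
    igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  }
  list(
    mean_degree = 2 * nrow(net$edges) / net$n,
    clustering_coefficient = igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    mean_path_length = igraph::mean_distance(gc),
    component = if (connected) "full" else "largest"
  )
}

#' Write a network as an edge-list text file
#'
#' @param net an `fsabm_network`.
#' @param path output path; two node ids per line, whitespace-separated.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  utils::write.table(net$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.fsabm_network <- function(x, ...) {
  cat(sprintf("Small-world network: %d nodes, %d edges (k = %d, p_rewire = %g)\n",
              x$n, nrow(x$edges), x$k, x$p_rewire))
  invisible(x)
}
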