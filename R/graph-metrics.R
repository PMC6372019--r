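# Nodal graph metrics on group-consensus networks.
#
# Path-based metrics (betweenness, mean path length) use binary hop counts on
# the consensus topology even for the weighted network, matching the
# definition of path length as the lowest number of edges traversed; strength
# is the only weight-using nodal metric. A `weighted_paths` flag switches the
# path-based metrics to 1/weight edge lengths for sensitivity analysis.

net_graph <- function(net, weighted_paths = FALSE) {
  if (weighted_paths) {
    g <- igraph::graph_from_adjacency_matrix(net$weighted, mode = "undirected",
                                             weighted = TRUE)
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
    g
  } else {
    igraph::graph_from_adjacency_matrix(net$binary, mode = "undirected")
  }
}

assert_connected <- function(g) {
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    abort(sprintf(
      "graph is disconnected (%d components of sizes %s); path-based metrics undefined.",
      comp$no, sizes))
  }
}

#' Nodal degree and strength
#'
#' Degree is the binary row sum (number of edges at a node); strength is the
#' weighted row sum (sum of edge weights at a node).
#'
#' @param net A `cyto_group_network` (or any list with symmetric `binary` and
#'   `weighted` matrices).
#' @return Tibble with `region`, `degree`, `strength`.
#' @export
degree_strength <- function(net) {
  ids <- rownames(net$binary) %||% as.character(seq_len(nrow(net$binary)))
  tibble(
    region = as.integer(ids),
    degree = as.integer(rowSums(net$binary)),
    strength = unname(rowSums(net$weighted))
  )
}

#' Nodal betweenness centrality
#'
#' The fraction of shortest paths between other node pairs that traverse the
#' node: for node v, the sum over ordered pairs (s, t) of
#' `sigma_st(v) / sigma_st`, normalized by `(N - 1)(N - 2)`. Shortest paths
#' are hop-count paths on the consensus topology unless `weighted_paths`.
#' With `log_transform`, returns `log(b + eps)` with
#' `eps = 1 / ((N - 1)(N - 2))` (the scale of the smallest attainable
#' nonzero value), keeping zero-betweenness nodes finite.
#'
#' @param net A `cyto_group_network`.
#' @param log_transform Return natural-log-transformed values.
#' @param weighted_paths Use 1/weight edge lengths instead of hop counts.
#' @return Tibble with `region`, `betweenness` (and `log_betweenness` when
#'   requested).
#' @export
betweenness <- function(net, log_transform = FALSE, weighted_paths = FALSE) {
  g <- net_graph(net, weighted_paths)
  assert_connected(g)
  N <- igraph::vcount(g)
  b_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  b <- 2 * b_raw / ((N - 1) * (N - 2))
  ids <- rownames(net$binary) %||% as.character(seq_len(N))
  out <- tibble(region = as.integer(ids), betweenness = as.numeric(b))
  if (log_transform) {
    eps <- 1 / ((N - 1) * (N - 2))
    out$log_betweenness <- log(out$betweenness + eps)
  }
  out
}

#' Nodal clustering coefficient
#'
#' The proportion of edges present between a node's neighbours out of all
#' edges that could exist between them: `2 t_v / (k_v (k_v - 1))`, with 0 for
#' nodes of degree < 2.
#'
#' @param net A `cyto_group_network`.
#' @return Tibble with `region`, `clustering`.
#' @export
clustering <- function(net) {
  g <- net_graph(net)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  ids <- rownames(net$binary) %||% as.character(seq_len(nrow(net$binary)))
  tibble(region = as.integer(ids), clustering = as.numeric(cc))
}

#' Nodal mean shortest path length
#'
#' Per node, the mean over all other nodes of the hop-count shortest path
#' (breadth-first distances on the consensus topology).
#'
#' @param net A `cyto_group_network`.
#' @param weighted_paths Use 1/weight edge lengths instead of hop counts.
#' @return Tibble with `region`, `path_length`.
#' @export
path_length <- function(net, weighted_paths = FALSE) {
  g <- net_graph(net, weighted_paths)
  assert_connected(g)
  D <- igraph::distances(g)
  diag(D) <- NA
  ids <- rownames(net$binary) %||% as.character(seq_len(nrow(net$binary)))
  tibble(region = as.integer(ids),
         path_length = unname(rowMeans(D, na.rm = TRUE)))
}

#' All nodal metrics of a group network
#'
#' Computes degree, strength, betweenness (raw and log-transformed),
#' clustering coefficient and mean shortest path length for every node.
#'
#' @param net A `cyto_group_network`.
#' @param weighted_paths Use 1/weight edge lengths for path-based metrics.
#' @return Tibble with one row per region.
#' @export
nodal_metrics <- function(net, weighted_paths = FALSE) {
  degree_strength(net) %>%
    left_join(betweenness(net, log_transform = TRUE,
                          weighted_paths = weighted_paths), by = "region") %>%
    left_join(clustering(net), by = "region") %>%
    left_join(path_length(net, weighted_paths = weighted_paths), by = "region")
}
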