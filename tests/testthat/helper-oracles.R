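# Independent brute-force oracles and tiny fixtures shared across tests.
# These deliberately avoid the code paths (and libraries) they check.

# --- graph oracles (adjacency matrix in, plain loops/BFS, no igraph) -------

oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (dist[w] > dist[v] + 1) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_connected <- function(A) {
  all(is.finite(oracle_bfs_dist(A)))
}

# enumerate every simple path s -> t by depth-first search; count the ones of
# minimal length and how many pass through each intermediate vertex
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_bfs_dist(A)
  b <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      shortest <- D[s, t]
      paths <- list()
      walk <- function(v, visited) {
        if (v == t) {
          if (length(visited) - 1 == shortest) {
            paths[[length(paths) + 1L]] <<- visited
          }
          return(invisible())
        }
        if (length(visited) - 1 >= shortest) return(invisible())
        for (w in which(A[v, ] == 1)) {
          if (!(w %in% visited)) walk(w, c(visited, w))
        }
      }
      walk(s, s)
      sigma <- length(paths)
      if (sigma == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        for (v in inner) b[v] <- b[v] + 1 / sigma
      }
    }
  }
  b / ((n - 1) * (n - 2))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t_v <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        t_v <- t_v + A[nb[i], nb[j]]
      }
    }
    2 * t_v / (k * (k - 1))
  }, numeric(1))
}

oracle_path_length <- function(A) {
  D <- oracle_bfs_dist(A)
  diag(D) <- NA
  rowMeans(D, na.rm = TRUE)
}

adj_to_net <- function(A, W = NULL) {
  dimnames(A) <- list(seq_len(nrow(A)), seq_len(nrow(A)))
  if (is.null(W)) W <- A
  dimnames(W) <- dimnames(A)
  structure(list(binary = A, weighted = W,
                 prevalence = A, threshold = 0.5, n_subjects = 2L),
            class = "cyto_group_network")
}

random_connected_graph <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1L, p)
    A <- A + t(A)
    if (oracle_connected(A)) return(A)
  }
}

# --- small section fixture -------------------------------------------------

tiny_section <- function(n_regions = 4, size = 160, noise_sd = 0, seed = 7) {
  tp <- make_truth_profiles(n_regions, seed = seed)
  make_section(tp, default_ribbon_geometry(size), noise_sd = noise_sd,
               seed = seed)
}

# build a pair row in the shape sample_point_pairs() returns
pair_row <- function(id, pial, wm, section_id = 1L) {
  tibble::tibble(pair_id = id, section_id = section_id,
                 pial_x = pial[1], pial_y = pial[2],
                 wm_x = wm[1], wm_y = wm[2])
}
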