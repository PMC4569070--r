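# Shared fixtures and independent oracles for the test suite.

# Lazily built, file-local Monte Carlo P_ij table (cheap but reused a lot).
shared <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (is.null(cache[[name]])) cache[[name]] <- build()
    cache[[name]]
  }
})

toy_pij <- function() {
  shared("pij", function() {
    bin_pij(suppressWarnings(mc_generate(5e4, fg_default_geometry(), seed = 101)))
  })
}

# Uniformly random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Apply a rigid motion to a whole trajectory row.
rigid_move <- function(xyz_row, rot, shift) {
  m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
  as.vector(t(sweep(m %*% t(rot), 2, shift, `+`)))
}

# Brute-force breadth-first enumeration of all shortest paths between two
# vertices of an adjacency matrix; independent of igraph.
bfs_all_shortest_paths <- function(adj, s, t) {
  n <- nrow(adj)
  dist <- rep(Inf, n); dist[s] <- 0
  queue <- s
  preds <- vector("list", n)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in which(adj[v, ] > 0)) {
      if (dist[w] == Inf) {
        dist[w] <- dist[v] + 1
        preds[[w]] <- v
        queue <- c(queue, w)
      } else if (dist[w] == dist[v] + 1) {
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  if (!is.finite(dist[t])) return(list())
  expand <- function(v) {
    if (v == s) return(list(s))
    out <- list()
    for (p in preds[[v]]) {
      for (pre in expand(p)) out[[length(out) + 1L]] <- c(pre, v)
    }
    out
  }
  expand(t)
}

# Tiny hand-buildable P_ij table: 2 bins, only the (1,1) and (2,2) pairs
# adsorbing, with triangular alpha histograms peaked at opposite ends.
two_pair_pij <- function(n_alpha = 12) {
  grid <- bin_grid(c(60, 120, 180), c(-180, 180))
  edges <- seq(0, 180, length.out = n_alpha + 1)
  h11 <- (n_alpha:1); h11 <- h11 / sum(h11)
  h22 <- (1:n_alpha); h22 <- h22 / sum(h22)
  hist <- array(0, c(2, 2, n_alpha))
  hist[1, 1, ] <- h11
  hist[2, 2, ] <- h22
  mask <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  counts <- matrix(c(100, 0, 0, 100), 2, 2)
  structure(list(hist = hist, counts = counts, mask = mask,
                 alpha_edges = edges,
                 alpha_mids = (edges[-1] + edges[-(n_alpha + 1)]) / 2,
                 grid = grid),
            class = "pij_table")
}
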