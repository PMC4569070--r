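# Shortest-pathway enumeration, bottlenecks, threshold scans, control pairs.

test_that("adjacent source and target give one single-edge path", {
  m <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  m["a", "b"] <- m["b", "a"] <- 1
  g <- build_network(m, 0.5)
  pw <- find_pathways(g, "a", "b", max_len = 5)
  expect_length(pw$paths, 1)
  expect_equal(pw$paths[[1]], c("a", "b"))
  expect_setequal(pw$bottleneck, c("a", "b"))
})

test_that("an articulation vertex lies on every pathway", {
  # two squares joined only through vertex m
  edges <- rbind(c("s", "u"), c("s", "v"), c("u", "m"), c("v", "m"),
                 c("m", "x"), c("m", "y"), c("x", "t"), c("y", "t"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  pw <- find_pathways(g, "s", "t", max_len = 10)
  expect_length(pw$paths, 4)
  expect_true(all(c("s", "m", "t") %in% pw$bottleneck))
  expect_equal(unname(pw$fraction_paths[c("u", "v", "x", "y")]), rep(0.5, 4))
  # both counting conventions are reported
  expect_equal(unname(pw$fraction_pairs["m"]), 1)
})

test_that("pathway ensembles equal a brute-force BFS enumeration", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 50
    adj <- matrix(stats::rbinom(n * n, 1, 0.06), n, n)
    adj <- (adj + t(adj)) > 0; diag(adj) <- FALSE
    rownames(adj) <- colnames(adj) <- paste0("r", seq_len(n))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    src <- "r1"; tgt <- c("r40", "r47")
    pw <- find_pathways(g, src, tgt, max_len = n)
    oracle <- list()
    for (t in c(40, 47)) {
      for (p in bfs_all_shortest_paths(adj * 1, 1, t)) {
        oracle[[length(oracle) + 1L]] <- paste0("r", p)
      }
    }
    canon <- function(paths) sort(vapply(paths, paste, character(1), collapse = ">"))
    expect_equal(canon(pw$paths), canon(oracle))
  }
})

test_that("the length bound follows from the compounded-correlation floor", {
  expect_equal(max_pathway_length(0.85), 22)
  # generic property: largest N with r^N > p_min, checked by direct search
  for (r in c(0.5, 0.7, 0.85, 0.95)) {
    n <- max_pathway_length(r)
    expect_gt(r^n, 0.025)
    expect_lte(r^(n + 1), 0.025)
  }
  # boundary: r^2 exactly at the floor is excluded by the strict inequality
  expect_equal(max_pathway_length(0.5, p_min = 0.25), 1)
  expect_equal(max_pathway_length(1), Inf)
})

test_that("paths beyond the length bound are discarded", {
  # chain of 6 vertices: s to t distance 5
  m <- matrix(0, 6, 6, dimnames = rep(list(paste0("v", 1:6)), 2))
  for (k in 1:5) m[k, k + 1] <- m[k + 1, k] <- 1
  g <- build_network(m, 0.5)
  expect_length(find_pathways(g, "v1", "v6", max_len = 5)$paths, 1)
  expect_length(find_pathways(g, "v1", "v6", max_len = 4)$paths, 0)
  # with r_crit given, the bound comes from the formula
  expect_length(find_pathways(g, "v1", "v6", r_crit = 0.45)$paths, 0) # N = 4
  expect_length(find_pathways(g, "v1", "v6", r_crit = 0.5)$paths, 1)  # N = 5
})

test_that("threshold scan finds the first connecting threshold", {
  m <- matrix(0, 4, 4, dimnames = rep(list(c("s", "a", "b", "t")), 2))
  m["s", "a"] <- m["a", "s"] <- 0.9
  m["a", "b"] <- m["b", "a"] <- 0.86 # weakest link on the only route
  m["b", "t"] <- m["t", "b"] <- 0.95
  sc <- threshold_scan(m, "s", "t", r_start = 1, step = 0.05)
  expect_true(sc$connected)
  expect_equal(sc$r_crit, 0.85)
  # already connected at the start
  sc2 <- threshold_scan(m, "s", "a", r_start = 0.85, step = 0.05)
  expect_equal(sc2$r_crit, 0.85)
  # disconnected matrix reports no connection
  m0 <- matrix(0, 3, 3, dimnames = rep(list(c("s", "x", "t")), 2))
  sc3 <- threshold_scan(m0, "s", "t", r_start = 1, step = 0.2)
  expect_false(sc3$connected)
  expect_true(is.na(sc3$r_crit))
})

test_that("control pairs are exactly the distance-filtered residue pairs", {
  # compact cloud: nothing 6 nm apart
  set.seed(61)
  compact <- matrix(stats::rnorm(60, sd = 5), 20, 3)
  expect_equal(nrow(control_pairs(compact)), 0)
  two <- rbind(c(0, 0, 0), c(70, 0, 0))
  cp <- control_pairs(two)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$distance, 70)
  # 50-residue cloud against a direct pairwise filter
  cloud <- matrix(stats::rnorm(150, sd = 40), 50, 3)
  cp2 <- control_pairs(cloud, min_sep = 60)
  d <- as.matrix(stats::dist(cloud))
  expect_equal(nrow(cp2), sum(d >= 60 & upper.tri(d)))
  expect_true(all(cp2$distance >= 60))
})
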