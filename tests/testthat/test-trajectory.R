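# helper: wrap an edge list into the graph structure the trajectory
# functions consume
graph_from_edges <- function(edges, n) {
  adj <- Matrix::sparseMatrix(i = c(edges$from, edges$to),
                              j = c(edges$to, edges$from),
                              x = c(edges$weight, edges$weight),
                              dims = c(n, n))
  list(edges = tibble::tibble(from = edges$from, to = edges$to,
                              weight = edges$weight),
       adjacency = adj, k = NA_integer_)
}

test_that("the largest connected piece represents each cluster", {
  # cluster A: nodes 1-5 split 3 + 2; cluster B: nodes 6-7 connected
  e <- tibble::tibble(from = c(1L, 2L, 4L, 6L), to = c(2L, 3L, 5L, 7L),
                      weight = rep(1, 4))
  g <- graph_from_edges(e, 7)
  labels <- c(rep("A", 5), rep("B", 2))
  comp <- largest_component_per_cluster(g, labels)
  expect_equal(comp$A, 1:3)            # the 3-node side wins
  expect_equal(comp$B, 6:7)
  expect_error(largest_component_per_cluster(g, labels[1:3]), "cover")

  # brute-force component enumeration oracle on a random labeled graph
  set.seed(13)
  d <- random_distance(20, seed = 13)
  kg <- knn_graph(d, k = 2)
  labs <- sample(paste0("Q", 1:4), 20, replace = TRUE)
  comp2 <- largest_component_per_cluster(kg, labs)
  ig <- igraph::graph_from_adjacency_matrix(kg$adjacency != 0, "undirected")
  for (cl in names(comp2)) {
    members <- which(labs == cl)
    sub <- igraph::components(igraph::induced_subgraph(ig, members))
    best_size <- max(sub$csize)
    expect_equal(length(comp2[[cl]]), best_size)
    expect_true(all(labs[comp2[[cl]]] == cl))
  }
})

test_that("cluster merging follows the quarter-sum and carry-over rules", {
  # cluster A = {1, 2}; outside nodes 3 (connected to both) and 4 (only to 2)
  e <- tibble::tibble(from = c(1L, 1L, 2L, 2L),
                      to   = c(2L, 3L, 3L, 4L),
                      weight = c(1, 2, 6, 5))
  g <- graph_from_edges(e, 4)
  labels <- c("A", "A", "B", "C")
  merged <- merge_clusters(g, labels)
  # both connect to 3: (2 + 6) / 4 = 2; only node 2 connects to 4: keep 5
  expect_equal(merged$weights["A", "B"], 2)
  expect_equal(merged$weights["A", "C"], 5)
  expect_true(is.na(merged$weights["B", "C"]))

  # merging a 2-cell cluster with no outside edges leaves an isolated node
  e2 <- tibble::tibble(from = 1L, to = 2L, weight = 1)
  g2 <- graph_from_edges(e2, 3)
  m2 <- merge_clusters(g2, c("A", "A", "B"),
                       retained = list(A = 1:2, B = 3L))
  expect_true(all(is.na(m2$weights)))
})

test_that("cluster pseudotime rescales means to the 0-10 range", {
  rpt <- c(1, 1, 2, 2, 3, 3)
  retained <- list(A = 1:2, B = 3:4, C = 5:6)
  pt <- cluster_pseudotime(rpt, retained)
  expect_equal(unname(pt), c(0, 5, 10))

  pt2 <- cluster_pseudotime(c(1, 3), list(A = 1L, B = 2L))
  expect_equal(unname(pt2), c(0, 10))

  expect_warning(pt3 <- cluster_pseudotime(c(2, 2), list(A = 1L, B = 2L)),
                 "equal")
  expect_equal(unname(pt3), c(0, 0))
})

test_that("tick distance is f(x) = x + 1/x on pseudotime gaps", {
  pt <- c(A = 0, B = 1, C = 3)
  d <- tick_distance(pt)
  expect_equal(d["A", "B"], 2)           # the minimum of f
  expect_equal(d["B", "C"], 2.5)         # f(2) = 2 + 1/2
  expect_equal(d["A", "C"], 3 + 1 / 3)
  expect_equal(d, t(d))
  # zero gaps floored, not infinite
  d0 <- tick_distance(c(A = 5, B = 5))
  expect_true(is.finite(d0["A", "B"]))
  expect_error(tick_distance(c(A = 1)), "2 clusters")
})

test_that("cluster adjacency adds scaled weights and tick distances", {
  merged <- list(weights = rbind(c(NA, 2, NA), c(2, NA, 4), c(NA, 4, NA)),
                 clusters = c("A", "B", "C"))
  dimnames(merged$weights) <- list(c("A", "B", "C"), c("A", "B", "C"))
  d_pt <- tick_distance(c(A = 0, B = 5, C = 10))
  w <- cluster_adjacency(merged, d_pt)
  # hat-W: 2/4 = 0.5 -> plus 0.2 * f(5) = 0.2 * 5.2
  expect_equal(w["A", "B"], 0.5 + 0.2 * (5 + 1 / 5))
  expect_equal(w["B", "C"], 1 + 0.2 * (5 + 1 / 5))
  expect_true(is.na(w["A", "C"]))        # no merged edge, default mask
  w2 <- cluster_adjacency(merged, d_pt, allow_pt_edges = TRUE)
  expect_equal(w2["A", "C"], 0.2 * (10 + 1 / 10))
})

test_that("cluster MST minimizes total weight (brute-force oracle)", {
  # 3-cluster triangle with weights 1, 2, 3 keeps the two lightest edges
  w <- rbind(c(NA, 1, 3), c(1, NA, 2), c(3, 2, NA))
  dimnames(w) <- list(c("A", "B", "C"), c("A", "B", "C"))
  mst <- cluster_mst(w)
  expect_equal(nrow(mst), 2L)
  expect_equal(sum(mst$weight), 3)
  expect_setequal(paste(mst$from, mst$to), c("A B", "B C"))

  # disconnected components get one tree each
  w2 <- matrix(NA_real_, 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  w2["A", "B"] <- w2["B", "A"] <- 1
  w2["C", "D"] <- w2["D", "C"] <- 2
  mst2 <- cluster_mst(w2)
  expect_equal(nrow(mst2), 2L)

  # random weight matrices vs exhaustive spanning-forest enumeration
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:6, 1)
    w3 <- matrix(NA_real_, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.75) w3[i, j] <- w3[j, i] <- round(runif(1, 0.1, 5), 3)
    }
    mst3 <- cluster_mst(w3)
    expect_equal(sum(mst3$weight), brute_force_msf_weight(w3),
                 tolerance = 1e-12)
  }
})

test_that("pruning keeps intra-cluster and backbone edges only", {
  e <- tibble::tibble(from = c(1L, 1L, 2L, 3L, 1L),
                      to   = c(2L, 3L, 4L, 4L, 4L),
                      weight = c(1, 2, 3, 4, 5))
  g <- graph_from_edges(e, 4)
  labels <- c("A", "A", "B", "B")
  cmst <- tibble::tibble(from = "A", to = "B", weight = 1)
  res <- prune_and_cell_mst(g, cmst, labels)
  # all five edges are intra-cluster or A-B, so all survive
  expect_equal(nrow(res$pruned_edges), 5L)

  cmst0 <- tibble::tibble(from = character(), to = character(),
                          weight = numeric())
  res0 <- prune_and_cell_mst(g, cmst0, labels)
  # only intra-cluster edges remain: (1,2) and (3,4)
  expect_equal(sort(paste(res0$pruned_edges$from, res0$pruned_edges$to)),
               c("1 2", "3 4"))

  # brute-force filter oracle on a random labeled graph
  set.seed(17)
  d <- random_distance(15, seed = 17)
  kg <- knn_graph(d, k = 2)
  labs <- sample(c("X", "Y", "Z"), 15, replace = TRUE)
  cm <- tibble::tibble(from = "X", to = "Y", weight = 1)
  out <- prune_and_cell_mst(kg, cm, labs)
  manual <- kg$edges[
    labs[kg$edges$from] == labs[kg$edges$to] |
      (pmin(labs[kg$edges$from], labs[kg$edges$to]) == "X" &
       pmax(labs[kg$edges$from], labs[kg$edges$to]) == "Y"), ]
  expect_equal(out$pruned_edges, manual)
  # the cell MST is a spanning forest of the pruned graph
  ig <- igraph::graph_from_data_frame(out$pruned_edges[, 1:2],
                                      directed = FALSE,
                                      vertices = as.character(1:15))
  expect_equal(nrow(out$mst_edges), 15 - igraph::components(ig)$no)
})

test_that("edges orient away from the root, by pseudotime elsewhere", {
  cmst <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                         weight = c(1, 1))
  pt <- c(A = 0, B = 5, C = 10)
  d <- orient_edges(cmst, pt, "A")
  expect_equal(d, tibble::tibble(source = c("A", "B"), target = c("B", "C")))

  # star with the root at the center
  star <- tibble::tibble(from = c("A", "A", "A"), to = c("B", "C", "D"),
                         weight = rep(1, 3))
  pts <- c(A = 0, B = 1, C = 2, D = 3)
  ds <- orient_edges(star, pts, "A")
  expect_equal(ds$source, rep("A", 3))

  # rootless component falls back to the pseudotime direction
  two <- tibble::tibble(from = c("A", "C"), to = c("B", "D"),
                        weight = c(1, 1))
  pt2 <- c(A = 0, B = 1, C = 10, D = 4)
  d2 <- orient_edges(two, pt2, "A")
  expect_equal(d2[2, ], tibble::tibble(source = "D", target = "C"))
  expect_error(orient_edges(cmst, pt, "nope"), "not a cluster")
})

test_that("final pseudotime is the scaled tree geodesic from the root", {
  mst <- tibble::tibble(from = c(1L, 2L), to = c(2L, 3L), weight = c(1, 2))
  fpt <- final_pseudotime(mst, rpt = c(0, 1, 2), root_cell = 1, n_cells = 3)
  expect_equal(fpt$pseudotime, c(0, 1 / 3, 1))
  expect_true(all(fpt$reachable))

  # unreachable cells get the rough-pseudotime rank fallback, flagged
  fpt2 <- final_pseudotime(mst, rpt = c(0, 1, 2, 5), root_cell = 1,
                           n_cells = 4)
  expect_false(fpt2$reachable[4])
  expect_equal(fpt2$pseudotime[4], 1)    # highest RPT rank -> 1
  expect_error(final_pseudotime(mst, c(0, 1, 2), 7, 3), "invalid root")
})

test_that("pseudotime grows monotonically along any root-to-leaf path", {
  set.seed(23)
  d <- random_distance(25, seed = 23)
  kg <- knn_graph(d, k = 3)
  ig <- igraph::graph_from_data_frame(kg$edges[, 1:2], directed = FALSE,
                                      vertices = as.character(1:25))
  igraph::E(ig)$weight <- kg$edges$weight
  mst <- igraph::mst(ig)
  me <- igraph::as_data_frame(mst)
  mst_tbl <- tibble::tibble(from = as.integer(me$from),
                            to = as.integer(me$to), weight = me$weight)
  fpt <- final_pseudotime(mst_tbl, rpt = runif(25), root_cell = 1)
  geo <- igraph::distances(mst, v = "1")
  expect_equal(order(fpt$pseudotime), order(as.numeric(geo)))
})
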