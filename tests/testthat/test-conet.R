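test_that("the abundance filter is strictly 'more than min_total'", {
  counts <- matrix(c(2L, 1L, 1L, 1L,   # total 5 -> excluded
                     2L, 2L, 1L, 1L,   # total 6 -> kept
                     3L, 1L, 1L, 2L),  # total 7 -> kept
                   4, 3, dimnames = list(paste0("s", 1:4), c("o5", "o6", "o7")))
  cm <- spearman_matrix(otu_table(counts), min_total = 5)
  expect_setequal(rownames(cm$rho), c("o6", "o7"))
})

test_that("Spearman rho matches perfect monotone and the midrank oracle", {
  counts <- matrix(c(1L, 2L, 3L, 4L,
                     2L, 4L, 6L, 8L,
                     3L, 1L, 1L, 0L,
                     1L, 2L, 2L, 4L), 4, 4,
                   dimnames = list(paste0("s", 1:4),
                                   c("a", "b", "ties1", "ties2")))
  cm <- spearman_matrix(otu_table(counts), min_total = 0, profile = "count")
  expect_equal(cm$rho["a", "b"], 1)
  expect_equal(cm$rho["ties1", "ties2"],
               oracle_spearman(c(3, 1, 1, 0), c(1, 2, 2, 4)),
               tolerance = 1e-12)
})

test_that("the full rho matrix equals the rank-then-Pearson oracle on tied data", {
  set.seed(44)
  counts <- random_table(9, 7, lambda = 2)   # lots of ties
  cm <- spearman_matrix(otu_table(counts), min_total = 0, profile = "count")
  ids <- rownames(cm$rho)
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
    expect_equal(cm$rho[ids[i], ids[j]],
                 oracle_spearman(counts[, ids[i]], counts[, ids[j]]),
                 tolerance = 1e-12)
  }
})

test_that("relative-abundance profiles remove the library-size confound", {
  # independent OTUs, library sizes spanning an order of magnitude: raw
  # count profiles co-rank through depth, normalized profiles do not
  set.seed(91)
  sizes <- round(exp(runif(24, log(50), log(500))))
  probs <- rep(1 / 30, 30)
  counts <- t(vapply(sizes, function(n)
    as.vector(rmultinom(1, n, probs)), integer(30)))
  dimnames(counts) <- list(paste0("s", 1:24), sprintf("o%02d", 1:30))
  tab <- otu_table(counts[, colSums(counts) > 0])
  raw <- spearman_matrix(tab, min_total = 5, profile = "count")
  rel <- spearman_matrix(tab, min_total = 5)
  expect_gt(mean(raw$rho[upper.tri(raw$rho)]), 0.2)
  expect_lt(abs(mean(rel$rho[upper.tri(rel$rho)])), 0.1)
})

test_that("edges require both strict thresholds and positive correlation", {
  rho <- matrix(c(1, 0.61, 0.9, -0.95,
                  0.61, 1, 0.1, 0.2,
                  0.9, 0.1, 1, 0.3,
                  -0.95, 0.2, 0.3, 1), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  p <- matrix(c(0, 0.005, 0.02, 1e-6,
                0.005, 0, 0.5, 0.4,
                0.02, 0.5, 0, 0.3,
                1e-6, 0.4, 0.3, 0), 4, 4,
              dimnames = dimnames(rho))
  cm <- structure(list(rho = rho, p = p, n_sites = 20),
                  class = "corr_matrix")
  g <- build_network(cm, keep_isolated = TRUE)
  expect_true(igraph::are_adjacent(g, "a", "b"))    # 0.61, 0.005
  expect_false(igraph::are_adjacent(g, "a", "c"))   # p = 0.02 fails
  expect_false(igraph::are_adjacent(g, "a", "d"))   # negative rho
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.61)
  g2 <- build_network(cm, signed = TRUE, keep_isolated = TRUE)
  expect_true(igraph::are_adjacent(g2, "a", "d"))
})

test_that("topology indices on hand-enumerable graphs", {
  path3 <- igraph::graph_from_literal(A - B - C)
  tp <- topology(path3)
  expect_equal(tp$diameter_largest, 2)
  expect_equal(tp$avg_path_length_largest, 4 / 3)
  expect_equal(tp$n_shortest_paths, 3)
  nodes <- tp$nodes
  expect_equal(nodes$betweenness[nodes$node == "B"], 1)
  expect_equal(nodes$degree[nodes$node == "B"], 2)
  expect_equal(nodes$closeness[nodes$node == "B"], 1)        # (3-1)/2
  expect_equal(nodes$closeness_raw[nodes$node == "B"], 0.5)

  k4 <- igraph::make_full_graph(4)
  tk <- topology(k4)
  expect_equal(tk$diameter_largest, 1)
  expect_true(all(tk$nodes$betweenness == 0))

  two_edges <- igraph::graph_from_literal(A - B, C - D)
  td <- topology(two_edges)
  expect_equal(td$n_components, 2)
  expect_equal(td$diameter_largest, 1)
  expect_equal(td$diameter_weighted, 1)
  expect_equal(td$n_shortest_paths, 2)
})

test_that("Louvain closed forms: two triangles give Q = 0.5, a clique gives Q = 0", {
  tri2 <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    directed = FALSE)
  res <- louvain(tri2, seed = 1)
  expect_equal(res$n_modules, 2)
  expect_equal(res$modularity, 0.5)
  expect_equal(sort(unique(unname(res$membership))), 1:2)   # dense ids
  expect_equal(unname(res$membership[1]), unname(res$membership[2]))
  expect_false(res$membership[[1]] == res$membership[[4]])

  k5 <- igraph::make_full_graph(5)
  rk <- louvain(k5, seed = 2)
  expect_equal(rk$n_modules, 1)
  expect_equal(rk$modularity, 0)
  expect_error(louvain(igraph::make_empty_graph(3, directed = FALSE)),
               "no edges")
})

test_that("returned Q equals the independent modularity formula and igraph's", {
  set.seed(64)
  for (i in 1:5) {
    g <- igraph::sample_gnp(24, 0.12)
    if (igraph::ecount(g) < 2) next
    res <- louvain(g, seed = i)
    expect_equal(res$modularity, oracle_modularity(g, res$membership),
                 tolerance = 1e-12)
    expect_equal(res$modularity,
                 igraph::modularity(g, res$membership), tolerance = 1e-12)
    # and it should do at least as well as trivial partitions
    expect_gte(res$modularity, 0)
  }
})

test_that("two 5-cliques joined by one edge are recovered across seeds", {
  el <- rbind(t(utils::combn(1:5, 2)), t(utils::combn(6:10, 2)), c(5, 6))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  hits <- 0
  for (s in 1:20) {
    res <- louvain(g, seed = s)
    ok <- res$n_modules == 2 &&
      length(unique(res$membership[1:5])) == 1 &&
      length(unique(res$membership[6:10])) == 1
    if (ok) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("module-habitat Fisher tests match hypergeometric enumeration", {
  # module of 3 OTUs detected only in peat, 3 others only in soil
  counts <- matrix(0L, 4, 6, dimnames = list(
    paste0("s", 1:4), paste0("o", 1:6)))
  counts[1:2, 1:3] <- 2L
  counts[3:4, 4:6] <- 2L
  tab <- otu_table(counts)
  md <- make_metadata(paste0("s", 1:4), c("peat", "peat", "soil", "soil"))
  part <- structure(list(membership = setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                                               paste0("o", 1:6)),
                         modularity = NA, n_modules = 2),
                    class = "module_partition")
  res <- module_habitat_fisher(part, tab, md)
  row <- res[res$module == 1 & res$habitat == "peat", ]
  expect_equal(row$p, oracle_fisher_p(3, 0, 0, 3), tolerance = 1e-12)
  expect_equal(row$p, 0.1, tolerance = 1e-12)   # 2 / C(6,3)
})
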