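test_that("weighted UniFrac closed forms on the star tree", {
  st <- star_tree(4)
  counts <- matrix(0L, 2, 4, dimnames = list(c("A", "B"), paste0("t", 1:4)))
  counts["A", c("t1", "t2")] <- 5L
  counts["B", c("t3", "t4")] <- 5L
  tab <- otu_table(counts)
  expect_equal(weighted_unifrac(tab, st)["A", "B"], 1)       # disjoint
  expect_equal(weighted_unifrac(tab, st, normalized = FALSE)["A", "B"], 2)
  same <- otu_table(matrix(c(2L, 4L, 1L, 2L), 2, 2,
                           dimnames = list(c("A", "B"), c("t1", "t2"))))
  expect_equal(weighted_unifrac(same, st)["A", "B"], 0)      # identical p
})

test_that("weighted UniFrac matches the per-branch enumeration oracle", {
  set.seed(55)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    counts <- matrix(rpois(20, 3), 2, 10,
                     dimnames = list(c("A", "B"), tr$tip.label))
    counts[1, 1] <- counts[1, 1] + 1L   # keep sites non-empty
    counts[2, 2] <- counts[2, 2] + 1L
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    tab <- otu_table(counts)
    d <- weighted_unifrac(tab, tr)
    orc <- oracle_unifrac(counts["A", ], counts["B", ], tr)
    expect_lt(abs(d["A", "B"] - orc), 1e-10)
    d_raw <- weighted_unifrac(tab, tr, normalized = FALSE)
    orc_raw <- oracle_unifrac(counts["A", ], counts["B", ], tr,
                              normalized = FALSE)
    expect_lt(abs(d_raw["A", "B"] - orc_raw), 1e-10)
    expect_gte(d["A", "B"], 0)
    expect_lte(d["A", "B"], 1 + 1e-12)
  }
})

test_that("UniFrac rejects OTUs absent from the tree and drops empty sites", {
  st <- star_tree(3)
  bad <- otu_table(matrix(1L, 1, 1, dimnames = list("A", "zzz")))
  expect_error(weighted_unifrac(bad, st), "missing from tree")
})

test_that("PCoA closed forms: two sites and three collinear points", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  p2 <- pcoa(d2)
  expect_equal(ncol(p2$coords), 1)
  expect_equal(unname(sort(abs(p2$coords[, 1]))), c(1.5, 1.5))
  expect_equal(p2$axis_explained, 1)

  d3 <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  p3 <- pcoa(d3)
  expect_equal(p3$axis_explained[1], 1, tolerance = 1e-12)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA reconstructs Euclidean configurations exactly", {
  set.seed(66)
  pts <- matrix(rnorm(20), 10, 2)
  dm <- as.matrix(stats::dist(pts))
  p <- pcoa(dm)
  expect_lt(abs(sum(p$axis_explained[1:2]) - 1), 1e-9)
  rec <- as.matrix(stats::dist(p$coords[, 1:2]))
  expect_lt(max(abs(rec - dm)), 1e-9)
  expect_lt(p$negative_mass, 1e-9)
  # explained fractions are non-increasing
  expect_true(all(diff(p$axis_explained) <= 1e-12))
})

test_that("PERMANOVA recovers the exhaustive-enumeration p on a forced design", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 1e-9
  d[3, 4] <- d[4, 3] <- 1e-9
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  labels <- c("g1", "g1", "g2", "g2")
  res <- permanova(d, labels, n_perm = 999, seed = 2)
  # 6 distinct labelings; only the 2 aligned with the structure reach F_obs
  expect_lt(abs(res$p[1] - 1/3), 0.05)
  expect_gt(res$pseudo_f[1], 1e6)   # within-group SS is essentially zero
  expect_equal(sum(res$r_squared), 1, tolerance = 1e-12)
})

test_that("PERMANOVA matches vegan::adonis2 sums of squares and pseudo-F", {
  skip_if_not_installed("vegan")
  set.seed(88)
  pts <- matrix(rnorm(36), 12, 3)
  dm <- as.matrix(stats::dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:12)
  grp <- rep(c("a", "b", "c"), each = 4)
  cov1 <- rnorm(12)
  ours <- permanova(dm, data.frame(habitat = grp, cov1 = cov1),
                    n_perm = 199, seed = 1)
  theirs <- vegan::adonis2(stats::as.dist(dm) ~ habitat + cov1,
                           data = data.frame(habitat = grp, cov1 = cov1),
                           permutations = 199, by = "terms")
  expect_equal(ours$ss[1:2], theirs$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(ours$pseudo_f[1:2], theirs$F[1:2], tolerance = 1e-10)
  expect_equal(ours$df[1:2], theirs$Df[1:2])
})

test_that("PERMANOVA input validation", {
  d <- as.matrix(stats::dist(matrix(rnorm(8), 4)))
  expect_error(permanova(d, rep("g", 4)), ">= 2 groups")
  expect_error(permanova(d, c(1, 1, 2, 2)), "distinct values")
  expect_error(permanova(d, c("a", "a", "b", "b"), n_perm = 0), "n_perm")
})
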