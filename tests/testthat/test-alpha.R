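test_that("Shannon index matches closed forms and hand computation", {
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  # -(0.5 ln 0.5 + 2 * 0.25 ln 0.25)
  expect_equal(shannon(c(2, 1, 1)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannon(c(0, 0)), "zero")
})

test_that("Shannon is invariant to count scaling and respects the base option", {
  set.seed(3)
  for (i in 1:10) {
    x <- rpois(8, 4) + 1
    expect_equal(shannon(2 * x), shannon(x))
  }
  expect_equal(shannon(c(1, 1), base = 2), 1)
})

test_that("Faith PD sums the spanning subtree including the root stem", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd(c("A", "B", "C"), tr), 5)    # whole tree
  expect_equal(faith_pd(c("A", "B"), tr), 3)         # 2 pendants + stem
  expect_equal(faith_pd("C", tr), 2)
  st <- star_tree(6)
  expect_equal(faith_pd(paste0("t", 1:4), st), 4)    # k unit pendants
  expect_error(faith_pd("nope", tr), "unknown tip")
})

test_that("the no-root PD variant drops the shared stem", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(faith_pd(c("A", "B"), tr, include_root = FALSE), 2)
})

test_that("adding a tip never decreases PD", {
  set.seed(9)
  for (i in 1:5) {
    tr <- ape::rtree(12)
    tips <- sample(tr$tip.label)
    pd_seq <- vapply(seq_along(tips), function(k)
      faith_pd(tips[1:k], tr), numeric(1))
    expect_true(all(diff(pd_seq) >= -1e-12))
  }
})

test_that("PD agrees with picante on random communities", {
  skip_if_not_installed("picante")
  set.seed(15)
  tr <- ape::rtree(10)
  comm <- matrix(rbinom(30, 1, 0.6), 3, 10,
                 dimnames = list(paste0("s", 1:3), tr$tip.label))
  comm[1, ] <- 1
  ours <- vapply(1:3, function(i)
    faith_pd(colnames(comm)[comm[i, ] > 0], tr), numeric(1))
  theirs <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("rarefied PD reduces to plain PD at full depth and is exact at depth 1 on a star tree", {
  st <- star_tree(4)
  counts <- matrix(c(3L, 2L, 1L, 4L), 1, 4,
                   dimnames = list("s1", paste0("t", 1:4)))
  tab <- otu_table(counts)
  md <- make_metadata("s1", "peat")
  full <- rarefied_pd(tab, st, md, depth = 10, n_subsamples = 20, seed = 1)
  expect_equal(full$pd_mean, faith_pd(paste0("t", 1:4), st))
  expect_equal(full$pd_sd, 0)
  one <- rarefied_pd(tab, st, md, depth = 1, n_subsamples = 50, seed = 1)
  expect_equal(one$pd_mean, 1)          # any single clone spans one pendant
  expect_error(rarefied_pd(tab, st, md, depth = 11), "exceeds")
  expect_error(rarefied_pd(tab, st, md, depth = 0), "positive")
})

test_that("rarefied PD at depth 2 matches the hypergeometric expectation", {
  st <- star_tree(2)
  counts <- matrix(c(5L, 5L), 1, 2, dimnames = list("s1", c("t1", "t2")))
  tab <- otu_table(counts)
  md <- make_metadata("s1", "peat")
  res <- rarefied_pd(tab, st, md, depth = 2, n_subsamples = 1000, seed = 4)
  # P(two clones hit the same tip) = 2 C(5,2)/C(10,2) = 4/9
  p_same <- 2 * choose(5, 2) / choose(10, 2)
  expected <- 1 * p_same + 2 * (1 - p_same)
  se <- res$pd_sd / sqrt(1000)
  expect_lt(abs(res$pd_mean - expected), 3 * max(se, 1e-3) + 0.02)
})

test_that("rarefied PD mean is non-decreasing in depth", {
  set.seed(31)
  tr <- ape::rtree(8)
  counts <- matrix(rpois(8, 4) + 1L, 1, 8,
                   dimnames = list("s1", tr$tip.label))
  tab <- otu_table(counts)
  md <- make_metadata("s1", "peat")
  means <- vapply(c(2, 6, 12), function(d)
    rarefied_pd(tab, tr, md, depth = d, n_subsamples = 300, seed = 2)$pd_mean,
    numeric(1))
  expect_true(all(diff(means) > -0.05))
})

test_that("the per-habitat diversity table assembles all indices", {
  set.seed(41)
  tr <- ape::rtree(6)
  counts <- matrix(rpois(12, 3) + 1L, 2, 6,
                   dimnames = list(c("s1", "s2"), tr$tip.label))
  tab <- otu_table(counts)
  md <- make_metadata(c("s1", "s2"), c("peat", "soil"))
  dt <- diversity_table(tab, tr, md, n_subsamples = 20, seed = 1)
  expect_setequal(dt$habitat, c("peat", "soil"))
  expect_true(all(dt$pd > 0))
  expect_true(all(dt$shannon_mean >= 0))
  expect_equal(dt$n_clones, unname(rowSums(counts)[order(c("peat", "soil"))]))
})
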