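test_that("p-distances follow the pairwise-deletion gap rule", {
  aln <- structure(list(id = c("a", "b", "c", "d"), site_id = rep("s", 4),
                        seq = c("ACGT", "ACGT", "ACGA", "AC-T")),
                   class = "aln_set")
  d <- pairwise_pdistance(aln)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.25)          # 1 mismatch / 4 columns
  expect_equal(d["a", "d"], 0)             # gap column excluded: 0/3
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("a pair with no comparable columns is an error naming the pair", {
  aln <- structure(list(id = c("a", "b"), site_id = c("s", "s"),
                        seq = c("AC--", "--GT")), class = "aln_set")
  expect_error(pairwise_pdistance(aln), "no comparable columns")
})

test_that("complete-linkage OTU clustering honours the distance cutoff", {
  dm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm["A", "B"] <- dm["B", "A"] <- 0.01
  dm["A", "C"] <- dm["C", "A"] <- 0.02
  dm["B", "C"] <- dm["C", "B"] <- 0.05
  # cutoff 0.03: {A,B} merge at 0.01; adding C needs max(0.02, 0.05) > 0.03
  tab <- cluster_otus(dm, identity = 0.97)
  asg <- attr(tab, "assignment")
  expect_equal(ncol(tab), 2)
  expect_equal(asg[["A"]], asg[["B"]])
  expect_false(asg[["A"]] == asg[["C"]])

  # all distances zero collapse to a single OTU
  z <- matrix(0, 3, 3, dimnames = dimnames(dm))
  expect_equal(ncol(cluster_otus(z, identity = 0.97)), 1)

  # cutoff ~0 with positive distances keeps every sequence apart
  expect_equal(ncol(cluster_otus(dm, identity = 1 - 1e-9)), 3)
})

test_that("coarser identity never yields more OTUs and counts are conserved", {
  set.seed(11)
  n <- 30
  pts <- matrix(runif(n * 2), n)
  dm <- as.matrix(stats::dist(pts)) / 4   # distances in [0, ~0.35]
  dimnames(dm) <- list(paste0("q", 1:n), paste0("q", 1:n))
  sites <- sample(paste0("s", 1:4), n, replace = TRUE)
  t97 <- cluster_otus(dm, 0.97, site_ids = sites)
  t90 <- cluster_otus(dm, 0.90, site_ids = sites)
  expect_lte(ncol(t90), ncol(t97))
  expect_equal(sum(t97), n)
  expect_equal(sum(t90), n)
})

test_that("relative abundances normalize per site and average per habitat", {
  counts <- matrix(c(3L, 2L, 1L, 8L), 2, 2,
                   dimnames = list(c("s1", "s2"), c("o1", "o2")))
  tab <- otu_table(counts)
  ra <- relative_abundance(tab)
  expect_equal(ra["s1", ], c(o1 = 0.75, o2 = 0.25))
  expect_equal(unname(rowSums(ra)), c(1, 1), tolerance = 1e-12)

  md <- make_metadata(c("s1", "s2"), c("peat", "peat"))
  hra <- relative_abundance(tab, group = "habitat", metadata = md)
  expect_equal(hra["peat", "o1"], mean(c(0.75, 0.2)))
  expect_equal(attr(hra, "variance")["peat", "o1"],
               stats::var(c(0.75, 0.2)))
})

test_that("single-OTU table yields all fractions 1", {
  tab <- otu_table(matrix(c(4L, 7L), 2, 1,
                          dimnames = list(c("s1", "s2"), "o1")))
  expect_equal(unname(relative_abundance(tab)[, 1]), c(1, 1))
})

test_that("occupancy-abundance regression matches the normal-equations oracle", {
  set.seed(21)
  counts <- random_table(6, 12)
  lin <- setNames(rep(sprintf("L%02d", 1:4), each = 3), colnames(counts))
  # thin some lineages out so occurrence varies
  counts[1:4, lin[colnames(counts)] == "L01"] <- 0L
  counts[1:2, lin[colnames(counts)] == "L02"] <- 0L
  counts <- counts[, colSums(counts) > 0]
  tab <- otu_table(counts, lineage = lin[colnames(counts)])
  res <- sad_regression(tab)
  orc <- oracle_ols(res$occurrence, res$mean_relative_abundance)
  expect_equal(res$slope, orc$slope, tolerance = 1e-10)
  expect_equal(res$r_squared, orc$r_squared, tolerance = 1e-10)
  expect_gte(res$r_squared, 0)
  expect_lte(res$r_squared, 1)
})

test_that("the occupancy-abundance regression needs at least 3 lineages", {
  tab <- otu_table(matrix(c(1L, 2L), 1, 2,
                          dimnames = list("s1", c("o1", "o2"))),
                   lineage = c(o1 = "A", o2 = "B"))
  expect_error(sad_regression(tab), "3 lineages")
})
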