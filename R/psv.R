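#' Phylogenetic correlation matrix of a tree
#'
#' For tips i and j, `C_ij` is the branch length shared by their root-to-tip
#' paths divided by the mean of their root-to-tip depths; the diagonal is 1.
#' For ultrametric trees this is the standard phylogenetic correlation
#' matrix with off-diagonals in \[0, 1\]; for non-ultrametric trees the same
#' ratio is used as an approximation.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
phylo_corr <- function(tree) {
  V <- ape::vcv(tree)
  depth <- diag(V)
  C <- V / outer(depth, depth, function(a, b) (a + b) / 2)
  diag(C) <- 1
  C
}

# PSV of an index subset of a precomputed correlation matrix
psv_from_corr <- function(C, idx) {
  n <- length(idx)
  sub <- C[idx, idx]
  (n * sum(diag(sub)) - sum(sub)) / (n * (n - 1))
}

#' Phylogenetic species variability
#'
#' PSV of a community: `(n * tr(C) - sum(C)) / (n * (n - 1))` over the
#' phylogenetic correlation matrix of the tips present.  PSV lies in
#' \[0, 1\]: 1 for phylogenetically unrelated tips (a star phylogeny) and
#' approaching 0 as the tips become closely related.  Presence/absence
#' only; abundances play no role.
#'
#' @param tips_present Character vector of tip labels present (>= 2).
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return PSV, a scalar in \[0, 1\].
#' @export
psv <- function(tips_present, tree) {
  tips_present <- unique(as.character(tips_present))
  if (length(tips_present) < 2)
    stop("PSV is undefined for fewer than 2 tips")
  unknown <- setdiff(tips_present, tree$tip.label)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  C <- phylo_corr(tree)
  psv_from_corr(C, match(tips_present, rownames(C)))
}

#' PSV null-model comparison per habitat
#'
#' Compares the observed PSV of each habitat's pooled community against two
#' randomization null models: `null1` shuffles tip labels across the whole
#' phylogeny (destroying phylogenetic structure but keeping each habitat's
#' membership pattern), `null2` redraws each habitat's OTU set uniformly at
#' random from the full OTU pool, preserving observed richness.  The
#' one-sided p-value tests whether the community is more phylogenetically
#' clustered (lower PSV) than expected by chance, with the add-one
#' correction `p = (1 + #(null <= observed)) / (1 + n_rand)`.
#'
#' @param table An [otu_table].
#' @param tree Rooted [ape::phylo] covering all OTUs in the table.
#' @param metadata Per-site metadata with habitat labels.
#' @param model `"null1"` (tip shuffle) or `"null2"` (richness-preserving
#'   random draw).
#' @param n_rand Number of randomizations (default 999).
#' @param seed Integer seed.
#' @return A data.frame of class `psv_result`, one row per habitat with >= 2
#'   OTUs: `habitat`, `richness`, `psv_observed`, `null_mean`, `null_sd`,
#'   `p`, `n_rand`.  Attribute `pooled` holds the across-habitat mean
#'   comparison (observed mean PSV, null mean, p).
#' @export
psv_null <- function(table, tree, metadata, model = c("null1", "null2"),
                     n_rand = 999L, seed = 1L) {
  model <- match.arg(model)
  if (n_rand < 1) stop("n_rand must be >= 1")
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips))
    stop("OTUs missing from tree: ", paste(missing_tips, collapse = ", "))
  hab <- site_habitats(table, metadata)
  pooled <- rowsum(unclass(table), hab)
  C <- phylo_corr(tree)
  pool <- match(colnames(table), rownames(C))
  comm <- lapply(rownames(pooled), function(h)
    pool[pooled[h, ] > 0])
  names(comm) <- rownames(pooled)
  ok <- vapply(comm, length, integer(1)) >= 2
  if (!all(ok))
    warning("habitats with < 2 OTUs skipped: ",
            paste(names(comm)[!ok], collapse = ", "))
  comm <- comm[ok]
  observed <- vapply(comm, function(i) psv_from_corr(C, i), numeric(1))
  ntips <- nrow(C)
  nulls <- with_seed(seed, vapply(seq_len(n_rand), function(r) {
    if (model == "null1") {
      perm <- sample.int(ntips)
      vapply(comm, function(i) psv_from_corr(C, perm[i]), numeric(1))
    } else {
      vapply(comm, function(i)
        psv_from_corr(C, sample_vec(pool, length(i))), numeric(1))
    }
  }, numeric(length(comm))))
  nulls <- matrix(nulls, nrow = length(comm))
  p <- (1 + rowSums(nulls <= observed)) / (1 + n_rand)
  out <- data.frame(habitat = names(comm),
                    richness = vapply(comm, length, integer(1)),
                    psv_observed = unname(observed),
                    null_mean = rowMeans(nulls),
                    null_sd = apply(nulls, 1, stats::sd),
                    p = unname(p), n_rand = n_rand)
  rownames(out) <- NULL
  null_means <- colMeans(nulls)
  attr(out, "pooled") <- c(
    psv_observed_mean = mean(observed),
    null_mean = mean(null_means),
    p = (1 + sum(null_means <= mean(observed))) / (1 + n_rand))
  attr(out, "model") <- model
  class(out) <- c("psv_result", "data.frame")
  out
}

#' @export
print.psv_result <- function(x, ...) {
  cat(sprintf("PSV vs %s null (%d randomizations)\n", attr(x, "model"),
              x$n_rand[1]))
  print.data.frame(x, digits = 3)
  pl <- attr(x, "pooled")
  cat(sprintf("pooled mean: observed %.3f vs null %.3f (p = %.3g)\n",
              pl["psv_observed_mean"], pl["null_mean"], pl["p"]))
  invisible(x)
}
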