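#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * log(p_i))` over taxa with positive counts, where
#' `p_i` is the relative abundance.  Reported in nats by default; pass
#' `base = 2` for bits.
#'
#' @param counts Non-negative numeric vector of taxon counts with at least
#'   one positive entry.
#' @param base Logarithm base (default `exp(1)`, i.e. natural log).
#' @return The index, a non-negative scalar; 0 iff exactly one taxon is
#'   present.
#' @examples
#' shannon(c(1, 1, 1, 1))  # log(4)
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all counts are zero")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree spanning a set of tips.
#' By default the subtree is connected to the root (the classic definition),
#' so a single tip has PD equal to its root-to-tip depth; with
#' `include_root = FALSE` only branches on paths between the present tips
#' are summed.
#'
#' @param tips_present Character vector (or set) of tip labels present in
#'   the community; must be non-empty and a subset of the tree's tips.
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @param include_root Connect the spanning subtree to the root (default
#'   `TRUE`).
#' @return PD in branch-length units.
#' @export
faith_pd <- function(tips_present, tree, include_root = TRUE) {
  tips_present <- unique(as.character(tips_present))
  if (!length(tips_present)) stop("tips_present must be non-empty")
  unknown <- setdiff(tips_present, tree$tip.label)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  # mark every edge on a path from a present tip up to the root
  up <- integer(max(child))
  up[child] <- parent
  on_path <- logical(max(child))
  for (tip in match(tips_present, tree$tip.label)) {
    v <- tip
    while (v != root && !on_path[v]) {
      on_path[v] <- TRUE
      v <- up[v]
    }
  }
  keep <- on_path[child]
  if (!include_root && length(tips_present) > 1) {
    # drop the shared stem above the MRCA of the present tips
    mrca <- if (length(tips_present) == ntip) root else
      ape::getMRCA(tree, tips_present)
    v <- mrca
    while (v != root) {
      keep[child == v] <- FALSE
      v <- up[v]
    }
  }
  sum(tree$edge.length[keep])
}

#' Rarefied phylogenetic diversity per habitat
#'
#' Corrects Faith PD for unequal clone-library sizes: clones of all sites
#' in a habitat are pooled, `depth` clones are drawn without replacement,
#' the PD of the OTUs hit is computed, and the draw is repeated
#' `n_subsamples` times with a seeded generator.
#'
#' @param table An [otu_table].
#' @param tree Rooted [ape::phylo] covering the table's OTUs.
#' @param metadata Per-site metadata with habitat labels.
#' @param depth Number of clones per subsample; defaults to the smallest
#'   habitat clone total.
#' @param n_subsamples Number of random subsamples (default 1000).
#' @param seed Integer seed for the subsampling generator.
#' @return A data.frame, one row per habitat: `habitat`, `n_clones`,
#'   `depth`, `pd_mean`, `pd_sd`.
#' @export
rarefied_pd <- function(table, tree, metadata, depth = NULL,
                        n_subsamples = 1000L, seed = 1L) {
  if (n_subsamples < 1) stop("n_subsamples must be >= 1")
  hab <- site_habitats(table, metadata)
  pooled <- rowsum(unclass(table), hab)
  if (is.null(depth)) depth <- min(rowSums(pooled))
  if (depth <= 0) stop("depth must be positive")
  if (depth > min(rowSums(pooled)))
    stop("depth (", depth, ") exceeds the smallest habitat clone total (",
         min(rowSums(pooled)), ")")
  res <- with_seed(seed, lapply(rownames(pooled), function(h) {
    clones <- rep(colnames(pooled), pooled[h, ])
    pd <- vapply(seq_len(n_subsamples), function(i) {
      faith_pd(unique(sample_vec(clones, depth)), tree)
    }, numeric(1))
    data.frame(habitat = h, n_clones = sum(pooled[h, ]), depth = depth,
               pd_mean = mean(pd), pd_sd = stats::sd(pd))
  }))
  do.call(rbind, res)
}

#' Per-habitat diversity summary table
#'
#' Shannon-Wiener index (mean +/- sd over a habitat's clone libraries),
#' plain and rarefied Faith PD, and clone/library totals per habitat.
#' Libraries containing a single OTU can be excluded from the Shannon mean,
#' mirroring the practice of excluding uninformative one-OTU libraries.
#'
#' @inheritParams rarefied_pd
#' @param exclude_single_otu Exclude one-OTU libraries from the per-library
#'   Shannon mean (default `FALSE`).
#' @return A data.frame, one row per habitat: library and clone counts,
#'   `shannon_mean`, `shannon_sd`, `pd`, `pd_rarefied_mean`, `pd_rarefied_sd`.
#' @export
diversity_table <- function(table, tree, metadata, depth = NULL,
                            n_subsamples = 1000L, seed = 1L,
                            exclude_single_otu = FALSE) {
  hab <- site_habitats(table, metadata)
  rare <- rarefied_pd(table, tree, metadata, depth = depth,
                      n_subsamples = n_subsamples, seed = seed)
  m <- unclass(table)
  per_site_h <- apply(m, 1, shannon)
  n_otus_site <- rowSums(m > 0)
  res <- lapply(sort(unique(hab)), function(h) {
    rows <- hab == h
    hs <- per_site_h[rows]
    if (exclude_single_otu) hs <- hs[n_otus_site[rows] > 1]
    pooled <- colSums(m[rows, , drop = FALSE])
    data.frame(habitat = h, n_libraries = sum(rows),
               n_clones = sum(pooled),
               shannon_mean = mean(hs), shannon_sd = stats::sd(hs),
               pd = faith_pd(colnames(m)[pooled > 0], tree))
  })
  out <- do.call(rbind, res)
  merge(out, rare[, c("habitat", "pd_mean", "pd_sd")], by = "habitat")
}
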