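# Independent brute-force oracles used to verify the package's metric
# implementations.  Each one is written from the metric's definition with
# naive loops, sharing no code with the implementation under test.

# tips (labels) descending from the child node of each edge, by repeated
# frontier expansion on the raw edge table
oracle_edge_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    frontier <- tree$edge[e, 2]
    tips <- integer()
    while (length(frontier)) {
      v <- frontier[1]
      frontier <- frontier[-1]
      if (v <= ntip) tips <- c(tips, v)
      frontier <- c(frontier, tree$edge[tree$edge[, 1] == v, 2])
    }
    tree$tip.label[tips]
  })
}

# weighted UniFrac by per-branch enumeration with explicit loops
oracle_unifrac <- function(counts_a, counts_b, tree, normalized = TRUE) {
  pa <- counts_a / sum(counts_a)
  pb <- counts_b / sum(counts_b)
  et <- oracle_edge_tips(tree)
  num <- 0
  den <- 0
  for (e in seq_along(et)) {
    wa <- sum(pa[names(pa) %in% et[[e]]])
    wb <- sum(pb[names(pb) %in% et[[e]]])
    num <- num + tree$edge.length[e] * abs(wa - wb)
    den <- den + tree$edge.length[e] * (wa + wb)
  }
  if (normalized) num / den else num
}

# PSV by path-by-path enumeration of shared branch lengths
oracle_psv <- function(tips, tree) {
  root <- length(tree$tip.label) + 1L
  edge_len <- function(a, b) {
    tree$edge.length[tree$edge[, 1] == a & tree$edge[, 2] == b]
  }
  path_edges <- function(tip) {
    nodes <- ape::nodepath(tree, root, which(tree$tip.label == tip))
    cbind(nodes[-length(nodes)], nodes[-1])
  }
  n <- length(tips)
  C <- diag(n)
  depth <- vapply(tips, function(t) {
    pe <- path_edges(t)
    sum(vapply(seq_len(nrow(pe)), function(k) edge_len(pe[k, 1], pe[k, 2]),
               numeric(1)))
  }, numeric(1))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pi_ <- path_edges(tips[i])
    pj <- path_edges(tips[j])
    shared <- 0
    for (k in seq_len(nrow(pi_))) {
      hit <- any(pj[, 1] == pi_[k, 1] & pj[, 2] == pi_[k, 2])
      if (hit) shared <- shared + edge_len(pi_[k, 1], pi_[k, 2])
    }
    C[i, j] <- C[j, i] <- shared / ((depth[i] + depth[j]) / 2)
  }
  (n * sum(diag(C)) - sum(C)) / (n * (n - 1))
}

# midranks by hand: average position of tied values
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    less <- sum(x < x[i])
    tied <- sum(x == x[i])
    r[i] <- less + (tied + 1) / 2
  }
  r
}

# Spearman rho = Pearson on midranks, Pearson by explicit sums
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration:
# sum the probabilities of all tables (fixed margins) no more probable
# than the observed one
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Newman modularity of a partition, straight from the definition
oracle_modularity <- function(graph, membership) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(graph)
  q <- 0
  for (c_id in unique(membership)) {
    inside <- which(membership == c_id)
    e_c <- sum(el[, 1] %in% inside & el[, 2] %in% inside)
    d_c <- sum(deg[inside])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# exhaustive best split: all covariates x all midpoint thresholds,
# minimizing total within-child SS (complete cases only)
oracle_best_split <- function(y, x, min_leaf = 2) {
  ss <- function(Y) if (nrow(Y) <= 1) 0 else sum(sweep(Y, 2, colMeans(Y))^2)
  best <- NULL
  for (j in seq_along(x)) {
    u <- sort(unique(x[[j]]))
    if (length(u) < 2) next
    for (t in (u[-1] + u[-length(u)]) / 2) {
      l <- x[[j]] <= t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      cur <- ss(y[l, , drop = FALSE]) + ss(y[!l, , drop = FALSE])
      if (is.null(best) || cur < best$ss - 1e-12)
        best <- list(var = names(x)[j], threshold = t, ss = cur)
    }
  }
  best
}

# OLS slope/R^2 from the normal equations, by explicit sums
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
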