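# edge-by-tip incidence: M[e, t] = 1 if tip t descends from the child node
# of edge e; tips ordered as tree$tip.label
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tree$edge)
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(post$edge))) {
    par <- post$edge[k, 1]
    chd <- post$edge[k, 2]
    below[par, ] <- below[par, ] | below[chd, ]
  }
  M <- below[tree$edge[, 2], , drop = FALSE] * 1
  colnames(M) <- tree$tip.label
  M
}

#' Weighted UniFrac distances between clone libraries
#'
#' For two communities A and B, the raw weighted UniFrac is
#' `sum_i b_i * |p_i^A - p_i^B|` over tree branches i, where `b_i` is the
#' branch length and `p_i^X` the fraction of community X's clones whose
#' OTUs descend from branch i.  The normalized variant (default) divides by
#' `sum_i b_i * (p_i^A + p_i^B)`, bounding the distance in \[0, 1\].
#'
#' @param table An [otu_table]; every OTU must be a tree tip.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param normalized Return the normalized variant (default `TRUE`).
#' @return Symmetric site-by-site distance matrix, zero diagonal.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  missing_tips <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_tips))
    stop("OTUs missing from tree: ", paste(missing_tips, collapse = ", "))
  m <- unclass(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("excluding empty sites: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  frac_full <- matrix(0, nrow(m), length(tree$tip.label),
                      dimnames = list(rownames(m), tree$tip.label))
  frac_full[, colnames(m)] <- m / tot
  M <- edge_tip_incidence(tree)
  P <- M %*% t(frac_full)              # edges x sites descendant fractions
  b <- tree$edge.length
  n <- ncol(P)
  d <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    raw <- sum(b * abs(P[, i] - P[, j]))
    d[i, j] <- d[j, i] <- if (normalized)
      raw / sum(b * (P[, i] + P[, j])) else raw
  }
  attr(d, "normalized") <- normalized
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: Gower double-centering of
#' the squared distances followed by eigendecomposition.  Axes are ordered
#' by eigenvalue and the fraction of variance explained by each positive
#' axis is `lambda_k / sum(positive lambda)`; the total magnitude of
#' negative eigenvalues is reported separately (no correction by default).
#'
#' @param dm Square symmetric non-negative distance matrix.
#' @param correction `"none"` (default) or `"lingoes"` (adds the minimal
#'   constant to off-diagonal squared distances making the matrix
#'   Euclidean).
#' @return A list of class `pcoa_result`: `coords` (site x axis matrix),
#'   `eig` (all eigenvalues), `axis_explained` (fractions for positive
#'   axes, non-increasing), `negative_mass` (sum of |negative eigenvalues|).
#' @export
pcoa <- function(dm, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be non-negative")
  n <- nrow(dm)
  G <- gower_center(dm)
  if (correction == "lingoes") {
    lam_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    if (lam_min < 0) {
      d2 <- dm^2 + 2 * abs(lam_min)
      diag(d2) <- 0
      G <- gower_center(sqrt(d2))
    }
  }
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  pos <- which(lam > max(lam) * 1e-12 & lam > 0)
  coords <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lam[pos]), length(pos))
  dimnames(coords) <- list(rownames(dm), paste0("Axis", seq_along(pos)))
  structure(list(
    coords = coords,
    eig = lam,
    axis_explained = lam[pos] / sum(lam[pos]),
    negative_mass = sum(abs(lam[lam < 0]))
  ), class = "pcoa_result")
}

# Gower double-centered matrix G = -(1/2) J D^2 J
# (two sequential sweeps give A_ij - rowmean_i - colmean_j + grandmean)
gower_center <- function(dm) {
  A <- -0.5 * dm^2
  A <- sweep(A, 1, rowMeans(A))
  sweep(A, 2, colMeans(A))
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d sites, %d positive axes\n", nrow(x$coords),
              ncol(x$coords)))
  cat(sprintf("axis 1-2 explain %.1f%% and %.1f%% of positive variance\n",
              100 * x$axis_explained[1],
              if (length(x$axis_explained) > 1)
                100 * x$axis_explained[2] else 0))
  invisible(x)
}

#' Permutational MANOVA on a distance matrix
#'
#' Distance-based multivariate analysis of variance (Anderson's
#' decomposition): sums of squares are read off the Gower-centered matrix
#' of squared distances through hat matrices of the design, pseudo-F is
#' `(SS_term / df_term) / (SS_residual / df_residual)`, and significance
#' comes from permuting site labels with a seeded generator, with the
#' add-one correction `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#' Multiple covariates are assessed sequentially (Type-I, in supplied
#' order) by default, or marginally with `by = "margin"`.
#'
#' @param dm Square symmetric distance matrix.
#' @param rhs Grouping factor / character vector, numeric covariate, or
#'   data.frame of covariates (one term per column, tested in order).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param by `"sequential"` (default) or `"margin"`.
#' @return A data.frame of class `permanova_result`, one row per term plus
#'   a residual row: `term`, `df`, `ss`, `r_squared`, `pseudo_f`, `p`.
#' @export
permanova <- function(dm, rhs, n_perm = 1000L, seed = 1L,
                      by = c("sequential", "margin")) {
  by <- match.arg(by)
  if (n_perm < 1) stop("n_perm must be >= 1")
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (is.atomic(rhs)) {
    nm <- if (is.numeric(rhs)) "covariate" else "habitat"
    rhs <- stats::setNames(data.frame(rhs), nm)
  }
  rhs <- as.data.frame(rhs)
  if (any(is.na(rhs))) stop("rhs contains missing values")
  if (nrow(rhs) != n) stop("rhs length must match distance matrix")
  terms <- lapply(rhs, function(v) {
    if (is.numeric(v)) {
      if (length(unique(v)) < 3)
        stop("numeric covariate needs >= 3 distinct values")
      cbind(v)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2)
        stop("grouping factor must have >= 2 groups")
      stats::model.matrix(~f)[, -1, drop = FALSE]
    }
  })
  G <- gower_center(dm)
  ss_total <- sum(diag(G))

  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  ones <- matrix(1, n, 1)
  X_cum <- Reduce(function(a, b) cbind(a, b), terms, accumulate = TRUE)
  H_prev <- c(list(hat(ones)),
              lapply(X_cum[-length(X_cum)], function(X) hat(cbind(ones, X))))
  H_full <- hat(cbind(ones, X_cum[[length(X_cum)]]))
  # per-term projector differences; for marginal tests, term vs all others
  P_term <- if (by == "sequential") {
    lapply(seq_along(terms), function(k)
      hat(cbind(ones, X_cum[[k]])) - H_prev[[k]])
  } else {
    lapply(seq_along(terms), function(k) {
      others <- do.call(cbind, c(list(ones), terms[-k]))
      H_full - hat(others)
    })
  }
  df_term <- vapply(seq_along(terms), function(k)
    round(sum(diag(P_term[[k]]))), numeric(1))
  df_resid <- n - round(sum(diag(H_full)))
  if (df_resid <= 0) stop("no residual degrees of freedom")
  R <- diag(n) - H_full

  stat <- function(Gp) {
    ss_r <- max(sum(R * Gp), 0)   # guard tiny negative round-off
    ss_t <- vapply(P_term, function(P) sum(P * Gp), numeric(1))
    (ss_t / df_term) / (ss_r / df_resid)
  }
  f_obs <- stat(G)
  ss_obs <- vapply(P_term, function(P) sum(P * G), numeric(1))
  exceed <- with_seed(seed, {
    cnt <- numeric(length(terms))
    for (r in seq_len(n_perm)) {
      pi <- sample.int(n)
      cnt <- cnt + (stat(G[pi, pi]) >= f_obs - 1e-12)
    }
    cnt
  })
  p <- (1 + exceed) / (1 + n_perm)
  ss_resid <- max(if (by == "sequential") ss_total - sum(ss_obs)
                  else sum(R * G), 0)
  out <- data.frame(
    term = c(names(rhs), "residual"),
    df = c(df_term, df_resid),
    ss = c(ss_obs, ss_resid),
    r_squared = c(ss_obs, ss_resid) / ss_total,
    pseudo_f = c(f_obs, NA),
    p = c(p, NA))
  attr(out, "n_perm") <- n_perm
  attr(out, "ss_total") <- ss_total
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations)\n", attr(x, "n_perm")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
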