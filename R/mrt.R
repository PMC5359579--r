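# within-node multivariate sum of squares (squared Euclidean deviations
# from the column means)
node_ss <- function(Y) {
  if (nrow(Y) <= 1) return(0)
  sum(sweep(Y, 2, colMeans(Y))^2)
}

#' Fit a multivariate regression tree
#'
#' Greedy binary recursive partitioning of a multi-group abundance matrix
#' by environmental covariates.  At each node the (covariate, threshold)
#' pair minimizing the total within-child multivariate sum of squared
#' Euclidean deviations from the child means is chosen; candidate
#' thresholds are midpoints between consecutive sorted covariate values,
#' and sites with a missing value for the splitting covariate follow the
#' majority child.  The tree is grown best-first (each step splits the leaf
#' giving the largest SS decrease) to `max_leaves`, producing a nested
#' sequence of subtree sizes whose final size is chosen by cross-validated
#' relative error with the 1-SE rule.
#'
#' @param y Site-by-group numeric response matrix (typically per-site
#'   relative abundances).
#' @param x Data.frame of numeric covariates (rows matching `y`); a
#'   `sample_metadata` object may be passed, in which case its numeric
#'   covariate columns are used.
#' @param min_leaf Minimum sites per leaf (default 2).
#' @param max_leaves Maximum leaves to grow (default
#'   `min(10, floor(n / min_leaf))`).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed (controls CV fold assignment only; the fit
#'   itself is deterministic).
#' @param size Optional fixed tree size, bypassing CV selection.
#' @return An object of class `mrt_tree`: `nodes` (flat list of node
#'   records with split variable, threshold, majority side and SS),
#'   `size`, `explained_variance` (resubstitution, for the selected size),
#'   `cv` (data.frame of size, relative error, CV error, CV se),
#'   `ss_total`, plus the data used.
#' @export
mrt_fit <- function(y, x, min_leaf = 2L, max_leaves = NULL,
                    cv_folds = 10L, seed = 1L, size = NULL) {
  y <- as.matrix(y)
  if (inherits(x, "sample_metadata") || is.data.frame(x)) {
    x <- as.data.frame(x)
    keep <- vapply(x, is.numeric, logical(1))
    drop_cols <- setdiff(names(x)[!keep], c("site_id", "habitat"))
    if (length(drop_cols))
      stop("non-numeric covariate(s): ", paste(drop_cols, collapse = ", "))
    x <- x[, keep, drop = FALSE]
  } else x <- as.data.frame(x)
  if (!ncol(x)) stop("at least one numeric covariate required")
  n <- nrow(y)
  if (nrow(x) != n) stop("x and y must have the same number of rows")
  if (n < 2 * min_leaf) stop("need at least 2 * min_leaf sites")
  if (is.null(max_leaves)) max_leaves <- min(10L, floor(n / min_leaf))
  ss_total <- node_ss(y)

  full <- grow_mrt(y, x, seq_len(n), min_leaf, max_leaves)
  n_sizes <- sum(!vapply(full, function(nd) is.null(nd$split), logical(1))) + 1L

  if (n_sizes == 1L) {
    if (max_leaves > 1) warning("no valid split found; single-leaf tree")
    if (is.null(size)) size <- 1L
  }

  # cross-validated relative error per tree size (per-observation errors)
  cv <- NULL
  if (is.null(size)) {
    folds <- with_seed(child_seed(seed, "mrt_cv"),
                       sample(rep(seq_len(cv_folds), length.out = n)))
    err <- matrix(NA_real_, n, n_sizes)
    for (f in seq_len(cv_folds)) {
      test <- which(folds == f)
      train <- setdiff(seq_len(n), test)
      if (length(train) < 2 * min_leaf) next
      tr <- grow_mrt(y, x, train, min_leaf, max_leaves)
      for (s in seq_len(n_sizes)) {
        leaf <- route_rows(tr, x, test, s)
        for (k in seq_along(test)) {
          mu <- colMeans(y[tr[[leaf[k]]]$rows, , drop = FALSE])
          err[test[k], s] <- sum((y[test[k], ] - mu)^2)
        }
      }
    }
    rel <- vapply(seq_len(n_sizes), function(s) {
      leaves <- leaves_at_size(full, s)
      1 - (ss_total - sum(vapply(leaves, function(id)
        node_ss(y[full[[id]]$rows, , drop = FALSE]), numeric(1)))) / ss_total
    }, numeric(1))
    cv_err <- colSums(err, na.rm = TRUE) / ss_total
    cv_se <- apply(err * n / ss_total, 2, stats::sd, na.rm = TRUE) / sqrt(n)
    cv <- data.frame(size = seq_len(n_sizes), rel_error = rel,
                     cv_error = cv_err, cv_se = cv_se)
    best <- which.min(cv_err)
    size <- min(which(cv_err <= cv_err[best] + cv_se[best]))
  }
  size <- min(size, n_sizes)
  leaves <- leaves_at_size(full, size)
  ss_leaves <- sum(vapply(leaves, function(id)
    node_ss(y[full[[id]]$rows, , drop = FALSE]), numeric(1)))
  structure(list(
    nodes = full, size = size,
    explained_variance = if (ss_total > 0) 1 - ss_leaves / ss_total else 0,
    cv = cv, ss_total = ss_total, y = y, x = x
  ), class = "mrt_tree")
}

# best (covariate, threshold) split of a row set; NULL when no valid split
best_split_mrt <- function(y, x, rows, min_leaf) {
  best <- NULL
  for (j in seq_along(x)) {
    v <- x[rows, j]
    ok <- !is.na(v)
    u <- sort(unique(v[ok]))
    if (length(u) < 2) next
    thr <- (u[-1] + u[-length(u)]) / 2
    for (t in thr) {
      left_ok <- ok & v <= t
      right_ok <- ok & v > t
      majority <- if (sum(left_ok) >= sum(right_ok)) "left" else "right"
      left <- left_ok | (!ok & majority == "left")
      right <- right_ok | (!ok & majority == "right")
      if (sum(left) < min_leaf || sum(right) < min_leaf) next
      ssc <- node_ss(y[rows[left], , drop = FALSE]) +
        node_ss(y[rows[right], , drop = FALSE])
      if (is.null(best) || ssc < best$ss_children - 1e-12)
        best <- list(var = names(x)[j], threshold = t, majority = majority,
                     left_rows = rows[left], right_rows = rows[right],
                     ss_children = ssc)
    }
  }
  best
}

# best-first growth; returns a flat node list (split order gives the
# nested subtree sequence)
grow_mrt <- function(y, x, rows, min_leaf, max_leaves) {
  nodes <- list(list(id = 1L, rows = rows, n = length(rows),
                     ss = node_ss(y[rows, , drop = FALSE]), split = NULL))
  cand <- list(best_split_mrt(y, x, rows, min_leaf))
  n_leaves <- 1L
  order_k <- 0L
  while (n_leaves < max_leaves) {
    gains <- vapply(seq_along(nodes), function(i) {
      if (!is.null(nodes[[i]]$split) || is.null(cand[[i]])) return(-Inf)
      nodes[[i]]$ss - cand[[i]]$ss_children
    }, numeric(1))
    i <- which.max(gains)
    if (!is.finite(gains[i]) || gains[i] <= 1e-12) break
    sp <- cand[[i]]
    order_k <- order_k + 1L
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    nodes[[lid]] <- list(id = lid, rows = sp$left_rows, n = length(sp$left_rows),
                         ss = node_ss(y[sp$left_rows, , drop = FALSE]),
                         split = NULL)
    nodes[[rid]] <- list(id = rid, rows = sp$right_rows,
                         n = length(sp$right_rows),
                         ss = node_ss(y[sp$right_rows, , drop = FALSE]),
                         split = NULL)
    nodes[[i]]$split <- list(var = sp$var, threshold = sp$threshold,
                             majority = sp$majority, order = order_k,
                             left = lid, right = rid)
    cand[lid] <- list(best_split_mrt(y, x, sp$left_rows, min_leaf))
    cand[rid] <- list(best_split_mrt(y, x, sp$right_rows, min_leaf))
    n_leaves <- n_leaves + 1L
  }
  nodes
}

# leaf node ids of the size-s nested subtree (splits with order < s active)
leaves_at_size <- function(nodes, s) {
  active <- function(nd) !is.null(nd$split) && nd$split$order <= s - 1
  leaf <- logical(length(nodes))
  walk <- function(id) {
    nd <- nodes[[id]]
    if (active(nd)) {
      walk(nd$split$left); walk(nd$split$right)
    } else leaf[id] <<- TRUE
  }
  walk(1L)
  which(leaf)
}

# route rows of x down the size-s subtree; returns leaf node id per row
route_rows <- function(nodes, x, row_idx, s) {
  vapply(row_idx, function(r) {
    id <- 1L
    repeat {
      nd <- nodes[[id]]
      if (is.null(nd$split) || nd$split$order > s - 1) return(id)
      v <- x[r, nd$split$var]
      go_left <- if (is.na(v)) nd$split$majority == "left" else
        v <= nd$split$threshold
      id <- if (go_left) nd$split$left else nd$split$right
    }
  }, integer(1))
}

#' Per-leaf composition summary of a fitted MRT
#'
#' Mean relative-abundance vector, site count, within-leaf SS and (when
#' metadata is supplied) the habitat tally of each leaf of the selected
#' tree.
#'
#' @param tree A fitted [mrt_fit] object.
#' @param metadata Optional per-site metadata (rows of `y` must be named by
#'   site id to tally habitats).
#' @return A list, one entry per leaf: `n_sites`, `sites`, `mean_abundance`,
#'   `ss`, and `habitats` (a named tally) when metadata is given.
#' @export
mrt_leaf_summary <- function(tree, metadata = NULL) {
  stopifnot(inherits(tree, "mrt_tree"))
  leaves <- leaves_at_size(tree$nodes, tree$size)
  lapply(leaves, function(id) {
    rows <- tree$nodes[[id]]$rows
    out <- list(node = id, n_sites = length(rows),
                sites = rownames(tree$y)[rows],
                mean_abundance = colMeans(tree$y[rows, , drop = FALSE]),
                ss = node_ss(tree$y[rows, , drop = FALSE]))
    if (!is.null(metadata) && !is.null(rownames(tree$y))) {
      hab <- metadata$habitat[match(rownames(tree$y)[rows],
                                    metadata$site_id)]
      out$habitats <- base::table(hab)
    }
    out
  })
}

#' Serialize a fitted MRT to JSON
#' @param tree A fitted [mrt_fit] object.
#' @param path Output path.
#' @export
write_mrt_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(nd) {
    rec <- list(id = nd$id, n = nd$n, ss = nd$ss,
                sites = rownames(tree$y)[nd$rows])
    if (!is.null(nd$split) && nd$split$order <= tree$size - 1)
      rec$split <- nd$split
    rec
  })
  jsonlite::write_json(
    list(size = tree$size, explained_variance = tree$explained_variance,
         ss_total = tree$ss_total, nodes = nodes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.mrt_tree <- function(x, ...) {
  cat(sprintf(
    "multivariate regression tree: %d leaves, explained variance %.3f\n",
    x$size, x$explained_variance))
  splits <- Filter(function(nd) !is.null(nd$split) &&
                     nd$split$order <= x$size - 1, x$nodes)
  splits <- splits[order(vapply(splits, function(nd) nd$split$order,
                                numeric(1)))]
  for (nd in splits)
    cat(sprintf("  split %d: %s <= %.4g (n = %d)\n", nd$split$order,
                nd$split$var, nd$split$threshold, nd$n))
  if (!is.null(x$cv)) {
    best <- x$cv[which.min(x$cv$cv_error), ]
    cat(sprintf("CV: min error %.3f at size %d; selected size %d (1-SE)\n",
                best$cv_error, best$size, x$size))
  }
  invisible(x)
}
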