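#' Dufrene-Legendre indicator value analysis
#'
#' For each group (lineage or OTU) g and habitat h, specificity
#' `A_gh = mean relative abundance of g in h / sum over habitats of g's
#' mean relative abundances`, fidelity `B_gh = fraction of h's sites where
#' g occurs`, and `IndVal_gh = A_gh * B_gh`.  A group's reported IndVal is
#' its maximum over habitats; significance comes from permuting site
#' habitat labels (habitat sizes fixed) and comparing each permuted
#' max-IndVal with the observed one, with the add-one correction.
#'
#' @param table An [otu_table] (or a plain site-by-group abundance matrix).
#' @param metadata Per-site metadata with habitat labels (>= 2 habitats).
#' @param by Aggregation level, `"lineage"` (default, as in subgroup-level
#'   analyses) or `"otu"`.
#' @param n_perm Number of label permutations (default 999).
#' @param alpha Significance threshold for flagging indicators (default
#'   0.05).
#' @param seed Integer seed.
#' @param type Specificity based on `"abundance"` (classic, default) or
#'   `"presence"`.
#' @return A data.frame of class `indval_result`, one row per group:
#'   `group`, `habitat` (argmax), `A`, `B`, `indval`, `p`, `significant`.
#'   Attribute `indval_matrix` holds the full group-by-habitat IndVal
#'   matrix.
#' @export
indval <- function(table, metadata, by = c("lineage", "otu"),
                   n_perm = 999L, alpha = 0.05, seed = 1L,
                   type = c("abundance", "presence")) {
  by <- match.arg(by)
  type <- match.arg(type)
  if (n_perm < 1) stop("n_perm must be >= 1")
  is_counts <- inherits(table, "otu_table")
  m <- if (is_counts) {
    if (by == "lineage") lineage_table(table) else unclass(table)
  } else as.matrix(table)
  hab <- factor(site_habitats(m, metadata))
  if (nlevels(hab) < 2) stop("IndVal requires >= 2 habitats")
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning("groups absent everywhere excluded: ",
            paste(colnames(m)[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  # OTU tables are converted to within-site relative abundance; a plain
  # abundance matrix is used as supplied
  frac <- if (is_counts) m / rowSums(m) else m
  if (type == "presence") frac <- (m > 0) * 1
  pres <- (m > 0) * 1

  iv_matrix <- function(perm_hab) {
    n_h <- as.vector(base::table(perm_hab))
    mean_ra <- rowsum(frac, perm_hab) / n_h          # habitat x group
    A <- sweep(mean_ra, 2, colSums(mean_ra), "/")
    B <- rowsum(pres, perm_hab) / n_h
    A * B
  }
  iv_obs <- iv_matrix(hab)
  obs_max <- apply(iv_obs, 2, max)
  exceed <- with_seed(seed, {
    cnt <- numeric(ncol(m))
    for (r in seq_len(n_perm)) {
      iv_p <- iv_matrix(sample(hab))
      cnt <- cnt + (apply(iv_p, 2, max) >= obs_max - 1e-12)
    }
    cnt
  })
  p <- (1 + exceed) / (1 + n_perm)
  best <- apply(iv_obs, 2, which.max)
  n_h <- as.vector(base::table(hab))
  mean_ra <- rowsum(frac, hab) / n_h
  A_obs <- sweep(mean_ra, 2, colSums(mean_ra), "/")
  B_obs <- rowsum(pres, hab) / n_h
  out <- data.frame(
    group = colnames(m),
    habitat = rownames(iv_obs)[best],
    A = A_obs[cbind(best, seq_along(best))],
    B = B_obs[cbind(best, seq_along(best))],
    indval = unname(obs_max),
    p = unname(p),
    significant = unname(p <= alpha))
  rownames(out) <- NULL
  attr(out, "indval_matrix") <- t(iv_obs)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("indval_result", "data.frame")
  out
}

#' @export
print.indval_result <- function(x, ...) {
  cat(sprintf("IndVal analysis (%d permutations): %d of %d groups ",
              attr(x, "n_perm"), sum(x$significant), nrow(x)))
  cat("are significant indicators\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}
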