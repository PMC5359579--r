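#' Pairwise p-distances between aligned sequences
#'
#' Uncorrected proportion of mismatching sites between each pair of aligned
#' sequences.  Columns with a gap in either member of a pair are excluded
#' for that pair only (pairwise deletion), the conservative convention.  A
#' Jukes-Cantor correction is available as a switch.
#'
#' @param seqs An `aln_set` of equal-length aligned sequences.
#' @param model Distance model, `"raw"` (p-distance, default) or `"JC69"`.
#' @return A symmetric numeric matrix of distances in \[0, 1\] (\[0, Inf) for
#'   JC69), zero diagonal, dimnames = sequence ids.
#' @export
pairwise_pdistance <- function(seqs, model = c("raw", "JC69")) {
  model <- match.arg(model)
  stopifnot(inherits(seqs, "aln_set"))
  if (!length(seqs$id)) return(matrix(numeric(), 0, 0))
  chars <- do.call(rbind, strsplit(tolower(seqs$seq), ""))
  rownames(chars) <- seqs$id
  bin <- ape::as.DNAbin(chars)
  d <- as.matrix(ape::dist.dna(bin, model = model, pairwise.deletion = TRUE))
  if (anyNA(d) || any(!is.finite(d))) {
    bad <- which(!is.finite(d) | is.na(d), arr.ind = TRUE)[1, ]
    stop("no comparable columns between '", rownames(d)[bad[1]], "' and '",
         colnames(d)[bad[2]], "'")
  }
  diag(d) <- 0
  d
}

#' Cluster sequences into OTUs at a fixed identity threshold
#'
#' Furthest-neighbour (complete-linkage) agglomeration of a pairwise
#' distance matrix, cut at distance `1 - identity`: two clusters merge only
#' if the maximum pairwise distance between their members is at or below
#' the cutoff.  OTU ids are assigned `OTU_0001`, `OTU_0002`, ... in order of
#' first member appearance, and per-site counts are aggregated when the
#' sequences carry site ids.
#'
#' @param dm Symmetric distance matrix with sequence ids as dimnames (as
#'   from [pairwise_pdistance]).
#' @param identity Identity threshold in (0, 1); the distance cutoff is
#'   `1 - identity` (e.g. 0.97 for diversity, 0.90 for networks).
#' @param site_ids Character vector of site ids, one per sequence (in
#'   `rownames(dm)` order).  When `NULL` all sequences are pooled into a
#'   single site `"all"`.
#' @param lineage Optional per-sequence lineage labels; each OTU takes the
#'   majority label of its members.
#' @return An [otu_table] with attribute `assignment`, a named character
#'   vector mapping each sequence id to its OTU id.
#' @export
cluster_otus <- function(dm, identity = 0.97, site_ids = NULL,
                         lineage = NULL) {
  stopifnot(identity > 0, identity < 1)
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n == 0) stop("empty distance matrix")
  ids <- rownames(dm)
  cutoff <- 1 - identity
  memb <- if (n == 1) stats::setNames(1L, ids) else {
    hc <- stats::hclust(stats::as.dist(dm), method = "complete")
    stats::cutree(hc, h = cutoff)
  }
  # relabel clusters in order of first member appearance
  first <- match(unique(memb), memb)
  relab <- match(memb, memb[sort(first)])
  otu_ids <- sprintf("OTU_%04d", relab)
  names(otu_ids) <- ids
  if (is.null(site_ids)) site_ids <- rep("all", n)
  counts <- as.matrix(table(factor(site_ids), otu_ids))
  counts <- counts[, unique(otu_ids[order(relab)]), drop = FALSE]
  lin <- NULL
  if (!is.null(lineage)) {
    lin <- vapply(split(as.character(lineage), otu_ids), function(l)
      names(sort(table(l), decreasing = TRUE))[1], character(1))
  }
  out <- otu_table(counts, lineage = lin, identity = identity)
  attr(out, "assignment") <- otu_ids
  out
}

#' Relative abundances per site or per habitat
#'
#' Converts counts to within-site fractions (each non-empty site row sums
#' to 1), at OTU or lineage resolution, optionally averaged per habitat.
#'
#' @param table An [otu_table].
#' @param by Resolution: `"otu"` or `"lineage"`.
#' @param group `"site"` (default) for one row per site, or `"habitat"` for
#'   the mean of member-site fractions per habitat (with the between-site
#'   variance attached as attribute `variance`).
#' @param metadata Required when `group = "habitat"`.
#' @return Numeric matrix of fractions.
#' @export
relative_abundance <- function(table, by = c("otu", "lineage"),
                               group = c("site", "habitat"),
                               metadata = NULL) {
  by <- match.arg(by)
  group <- match.arg(group)
  m <- if (by == "lineage") lineage_table(table) else unclass(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("excluding sites with zero total count: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  frac <- m / tot
  if (group == "site") return(frac)
  if (is.null(metadata)) stop("metadata required for group = \"habitat\"")
  hab <- site_habitats(frac, metadata)
  sums <- rowsum(frac, hab)
  n_h <- as.vector(base::table(hab)[rownames(sums)])
  mean_h <- sums / n_h
  var_h <- t(vapply(rownames(sums), function(h)
    apply(frac[hab == h, , drop = FALSE], 2, stats::var),
    numeric(ncol(frac))))
  structure(mean_h, variance = var_h)
}

#' Occupancy-abundance regression across lineages
#'
#' Ordinary least-squares regression of each lineage's mean relative
#' abundance on its occurrence (the number of sites where it was detected).
#' A strong positive relationship indicates that widespread lineages are
#' also the abundant ones.
#'
#' @param table An [otu_table].
#' @param metadata Optional metadata (used only to validate site coverage).
#' @return A list of class `sad_result` with the per-lineage data
#'   (`lineage`, `mean_relative_abundance`, `occurrence`), `slope`,
#'   `intercept`, `r_squared`, and the two-sided `p` for the slope.
#' @export
sad_regression <- function(table, metadata = NULL) {
  if (!is.null(metadata)) validate_sites(table, metadata)
  m <- lineage_table(table)
  frac <- relative_abundance(table, by = "lineage", group = "site")
  if (ncol(m) < 3)
    stop("at least 3 lineages required for the occupancy-abundance ",
         "regression")
  mra <- colMeans(frac)
  occ <- colSums(m > 0)
  fit <- stats::lm(mra ~ occ)
  sm <- summary(fit)
  structure(list(
    lineage = colnames(m),
    mean_relative_abundance = unname(mra),
    occurrence = unname(occ),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  ), class = "sad_result")
}

#' @export
print.sad_result <- function(x, ...) {
  cat(sprintf(
    "occupancy-abundance regression over %d lineages:\n  slope = %.4g, R^2 = %.3f, p = %.3g\n",
    length(x$lineage), x$slope, x$r_squared, x$p))
  invisible(x)
}
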