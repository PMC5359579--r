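#' Spearman correlation matrix between OTU abundance profiles
#'
#' Rank correlations (midrank ties) between the site-abundance profiles of
#' all OTU pairs, after excluding poorly represented OTUs whose total count
#' is not strictly greater than `min_total`.  Profiles are normalized to
#' within-site relative abundances before ranking, so unequal clone-library
#' sizes do not induce spurious positive co-occurrence (with raw counts,
#' every OTU pair inherits a common rank dependence on library depth).
#' Two-sided p-values use the t-distribution approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param table An [otu_table] with at least 4 sites.
#' @param min_total Exclusive total-count threshold (default 5: OTUs with
#'   more than 5 clones are kept).
#' @param profile `"relative"` (default) correlates within-site relative
#'   abundances; `"count"` correlates raw count profiles.
#' @return A list of class `corr_matrix`: `rho` and `p` (symmetric
#'   matrices over the surviving OTUs), `n_sites`.
#' @export
spearman_matrix <- function(table, min_total = 5L,
                            profile = c("relative", "count")) {
  profile <- match.arg(profile)
  m <- unclass(table)
  if (nrow(m) < 4) stop("at least 4 sites required")
  keep <- colSums(m) > min_total
  if (sum(keep) < 2)
    stop("fewer than 2 OTUs with total count > ", min_total)
  tot <- rowSums(m)
  m <- m[, keep, drop = FALSE]
  if (profile == "relative") {
    if (any(tot == 0)) stop("sites with zero total count: ",
                            paste(rownames(m)[tot == 0], collapse = ", "))
    m <- m / tot
  }
  n <- nrow(m)
  rho <- stats::cor(m, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  structure(list(rho = rho, p = p, n_sites = n), class = "corr_matrix")
}

#' Build the co-occurrence network from thresholded correlations
#'
#' An undirected edge joins OTUs i and j iff `rho_ij > rho_min` and
#' `p_ij < p_max` (strict inequalities; only positive correlations form
#' edges).  No multiple-testing correction is applied by default;
#' Benjamini-Hochberg is available via `adjust = "BH"`.  Isolated nodes
#' are dropped unless `keep_isolated = TRUE`.
#'
#' @param corr A `corr_matrix` from [spearman_matrix].
#' @param rho_min Correlation threshold (default 0.6, exclusive).
#' @param p_max Significance threshold (default 0.01, exclusive).
#' @param keep_isolated Keep nodes without any edge (default `FALSE`).
#' @param adjust p-value adjustment method (`"none"` default; any
#'   [stats::p.adjust] method).
#' @param signed Also admit edges with `rho < -rho_min` (default `FALSE`).
#' @param lineage Optional named lineage labels to attach to nodes.
#' @return An [igraph::graph] with edge attribute `weight` (rho) and node
#'   attributes `name`, and `lineage` when given.
#' @export
build_network <- function(corr, rho_min = 0.6, p_max = 0.01,
                          keep_isolated = FALSE, adjust = "none",
                          signed = FALSE, lineage = NULL) {
  stopifnot(inherits(corr, "corr_matrix"),
            rho_min >= 0, rho_min <= 1, p_max > 0, p_max <= 1)
  rho <- corr$rho
  p <- corr$p
  if (adjust != "none") {
    up <- p[upper.tri(p)]
    p[upper.tri(p)] <- stats::p.adjust(up, method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  pass <- (rho > rho_min) & (p < p_max)
  if (signed) pass <- pass | ((rho < -rho_min) & (p < p_max))
  pass[is.na(pass)] <- FALSE
  diag(pass) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(pass, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g)
  if (nrow(el))
    igraph::E(g)$weight <- rho[el]
  if (!keep_isolated)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (!is.null(lineage))
    igraph::V(g)$lineage <- unname(lineage[igraph::V(g)$name])
  g
}

#' Topology indices of a co-occurrence network
#'
#' Unweighted shortest-path indices.  Path-based graph indices (diameter,
#' average path length, number of shortest paths) are computed within
#' connected components: values for the largest component and the
#' component-size-weighted mean are both reported, and cross-component
#' pairs are excluded.  Node indices: degree (incident edges), closeness
#' (normalized `(n_comp - 1) / sum d`, and the unnormalized reciprocal
#' farness `1 / sum d`), and betweenness (shortest paths through the node,
#' counted with multiplicity fractions, unnormalized).
#'
#' @param net An [igraph::graph].
#' @return A list of class `conet_topology`: `n_nodes`, `n_edges`,
#'   `n_components`, `diameter`, `avg_path_length`, `n_shortest_paths`
#'   (geodesics over unordered connected pairs, counting multiplicity),
#'   each with `_largest` and `_weighted` variants where applicable, and a
#'   data.frame `nodes` of per-node indices.
#' @export
topology <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty graph")
  comp <- igraph::components(net)
  D <- igraph::distances(net, weights = NA)   # unweighted hops
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE,
                             weights = NA)
  clos_norm <- clos_raw <- numeric(n)
  for (c_id in seq_len(comp$no)) {
    vs <- which(comp$membership == c_id)
    nc <- length(vs)
    if (nc == 1) { clos_norm[vs] <- NA; clos_raw[vs] <- NA; next }
    far <- rowSums(D[vs, vs, drop = FALSE])
    clos_norm[vs] <- (nc - 1) / far
    clos_raw[vs] <- 1 / far
  }
  per_comp <- lapply(seq_len(comp$no), function(c_id) {
    vs <- which(comp$membership == c_id)
    if (length(vs) == 1)
      return(list(size = 1L, diameter = 0, apl = NA_real_, npaths = 0))
    sub <- D[vs, vs]
    sg <- igraph::induced_subgraph(net, vs)
    npaths <- sum(vapply(seq_along(vs), function(i) {
      cnt <- count_geodesics(sg, i)
      sum(cnt[-i])
    }, numeric(1))) / 2
    list(size = length(vs), diameter = max(sub),
         apl = mean(sub[upper.tri(sub)]), npaths = npaths)
  })
  sizes <- vapply(per_comp, `[[`, numeric(1), "size")
  big <- which.max(sizes)
  wmean <- function(v) {
    ok <- !is.na(v) & sizes > 1
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * sizes[ok]) / sum(sizes[ok])
  }
  structure(list(
    n_nodes = n, n_edges = igraph::ecount(net), n_components = comp$no,
    diameter_largest = per_comp[[big]]$diameter,
    diameter_weighted = wmean(vapply(per_comp, `[[`, numeric(1), "diameter")),
    avg_path_length_largest = per_comp[[big]]$apl,
    avg_path_length_weighted = wmean(vapply(per_comp, `[[`, numeric(1), "apl")),
    n_shortest_paths = sum(vapply(per_comp, `[[`, numeric(1), "npaths")),
    nodes = data.frame(
      node = igraph::V(net)$name %||% as.character(seq_len(n)),
      degree = unname(deg), betweenness = unname(btw),
      closeness = unname(clos_norm), closeness_raw = unname(clos_raw))
  ), class = "conet_topology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of geodesics from vertex v to every other vertex of graph g
# (BFS with path counting)
count_geodesics <- function(g, v) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  dist <- rep(Inf, n)
  cnt <- numeric(n)
  dist[v] <- 0
  cnt[v] <- 1
  queue <- v
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (w in as.integer(adj[[u]])) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[u] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[u] + 1) cnt[w] <- cnt[w] + cnt[u]
    }
  }
  cnt
}

#' @export
print.conet_topology <- function(x, ...) {
  cat(sprintf(
    "network: %d nodes, %d edges, %d component(s)\n", x$n_nodes, x$n_edges,
    x$n_components))
  cat(sprintf(
    "largest component: diameter %g, avg path length %.3f; %g shortest paths\n",
    x$diameter_largest, x$avg_path_length_largest, x$n_shortest_paths))
  invisible(x)
}

#' Louvain community detection
#'
#' Two-phase greedy modularity maximization on the unweighted graph:
#' (1) local moves — each node is moved to the neighbouring community
#' giving the largest modularity gain until no move improves Q;
#' (2) aggregation — communities collapse into super-nodes and phase 1
#' repeats on the aggregated graph, until modularity can no longer be
#' increased.  Node visit order is shuffled by a seeded generator.
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` with `e_c` intra-community edges,
#' `d_c` community degree sum, `m` total edges.
#'
#' @param net An [igraph::graph] with at least one edge.
#' @param seed Integer seed for the node visit order.
#' @return A list of class `module_partition`: `membership` (named integer
#'   vector, module ids dense from 1), `modularity` (Q of the returned
#'   partition), `n_modules`.
#' @export
louvain <- function(net, seed = 1L) {
  m_edges <- igraph::ecount(net)
  if (m_edges < 1) stop("graph has no edges")
  el <- igraph::as_edgelist(net, names = FALSE)
  n <- igraph::vcount(net)
  # current-level graph as weighted adjacency lists (self-loops allowed
  # after aggregation); node2orig maps level nodes to original node sets
  w_el <- cbind(el, 1)
  membership <- seq_len(n)
  repeat {
    res <- with_seed(child_seed(seed, paste0("louvain", n)),
                     louvain_level(w_el, n, 2 * m_edges))
    if (res$n_comm == n && all(res$membership == seq_len(n))) break
    membership <- res$membership[membership]
    n_new <- res$n_comm
    agg <- aggregate_edges(w_el, res$membership)
    if (n_new == n) break        # no further improvement possible
    w_el <- agg
    n <- n_new
  }
  memb <- match(membership, unique(membership))
  names(memb) <- igraph::V(net)$name %||% as.character(seq_along(memb))
  q <- modularity_value(el, memb, m_edges)
  structure(list(membership = memb, modularity = q,
                 n_modules = length(unique(memb))),
            class = "module_partition")
}

# one Louvain level: local moves on a weighted multigraph given as an
# edge list (from, to, weight); two_m is fixed at the original 2m
louvain_level <- function(w_el, n, two_m) {
  # build weighted adjacency (excluding self-loops for neighbour scans)
  self_w <- numeric(n)
  loops <- w_el[, 1] == w_el[, 2]
  if (any(loops)) {
    agg_loop <- rowsum(w_el[loops, 3], w_el[loops, 1])
    self_w[as.integer(rownames(agg_loop))] <- agg_loop[, 1]
  }
  ext <- w_el[!loops, , drop = FALSE]
  nbr <- vector("list", n)
  nbw <- vector("list", n)
  if (nrow(ext)) {
    both <- rbind(ext, ext[, c(2, 1, 3)])
    sp <- split(seq_len(nrow(both)), both[, 1])
    for (u in names(sp)) {
      i <- as.integer(u)
      nbr[[i]] <- both[sp[[u]], 2]
      nbw[[i]] <- both[sp[[u]], 3]
    }
  }
  k <- self_w * 2 + vapply(nbw, function(w) sum(w %||% 0), numeric(1))
  comm <- seq_len(n)
  sigma_tot <- k                 # total degree per community
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (u in sample.int(n)) {
      if (is.null(nbr[[u]]) || !length(nbr[[u]])) next
      cu <- comm[u]
      # weights to neighbouring communities
      wc <- rowsum(nbw[[u]], comm[nbr[[u]]])
      cands <- as.integer(rownames(wc))
      sigma_tot[cu] <- sigma_tot[cu] - k[u]
      w_cu <- if (cu %in% cands) wc[match(cu, cands)] else 0
      gain_stay <- w_cu - sigma_tot[cu] * k[u] / two_m
      gains <- wc[, 1] - sigma_tot[cands] * k[u] / two_m
      best <- which.max(gains)
      if (gains[best] > gain_stay + 1e-12 && cands[best] != cu) {
        comm[u] <- cands[best]
        sigma_tot[cands[best]] <- sigma_tot[cands[best]] + k[u]
        improved <- TRUE
      } else {
        sigma_tot[cu] <- sigma_tot[cu] + k[u]
      }
    }
  }
  dense <- match(comm, unique(comm))
  list(membership = dense, n_comm = length(unique(comm)))
}

# collapse an edge list onto community super-nodes, summing weights
aggregate_edges <- function(w_el, membership) {
  a <- membership[w_el[, 1]]
  b <- membership[w_el[, 2]]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi)
  w <- rowsum(w_el[, 3], key)
  parts <- do.call(rbind, strsplit(rownames(w), " "))
  cbind(as.integer(parts[, 1]), as.integer(parts[, 2]), as.vector(w))
}

# Q of a partition from the original simple edge list
modularity_value <- function(el, membership, m_edges) {
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = length(membership))
  intra <- vapply(seq_len(max(membership)), function(c_id)
    sum(membership[el[, 1]] == c_id & membership[el[, 2]] == c_id),
    numeric(1))
  d_c <- vapply(seq_len(max(membership)), function(c_id)
    sum(deg[membership == c_id]), numeric(1))
  sum(intra / m_edges - (d_c / (2 * m_edges))^2)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d modules, Q = %.4f\n", x$n_modules,
              x$modularity))
  invisible(x)
}

#' Fisher tests of module-habitat association
#'
#' For each (module, habitat) pair, a 2x2 contingency table — OTU in/out of
#' the module crossed with OTU detected/undetected in the habitat — is
#' tested with a two-sided Fisher's exact test.  A small p indicates the
#' module's OTUs are concentrated in (or excluded from) that habitat, i.e.
#' the module marks an ecological niche.
#'
#' @param partition A `module_partition` from [louvain].
#' @param table An [otu_table] covering the partition's OTUs.
#' @param metadata Per-site metadata with habitat labels.
#' @return A data.frame: `module`, `habitat`, `n_module`, `n_in_habitat`,
#'   `odds_ratio`, `p`.
#' @export
module_habitat_fisher <- function(partition, table, metadata) {
  stopifnot(inherits(partition, "module_partition"))
  hab <- site_habitats(table, metadata)
  otus <- names(partition$membership)
  missing_otus <- setdiff(otus, colnames(table))
  if (length(missing_otus))
    stop("partition OTUs missing from table: ",
         paste(missing_otus, collapse = ", "))
  m <- unclass(table)[, otus, drop = FALSE]
  res <- list()
  for (h in sort(unique(hab))) {
    detected <- colSums(m[hab == h, , drop = FALSE]) > 0
    if (!any(detected)) {
      warning("habitat with no detected OTUs skipped: ", h)
      next
    }
    for (mod in sort(unique(partition$membership))) {
      in_mod <- partition$membership == mod
      tab <- base::table(factor(in_mod, c(TRUE, FALSE)),
                         factor(detected, c(TRUE, FALSE)))
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      res[[length(res) + 1]] <- data.frame(
        module = mod, habitat = h, n_module = sum(in_mod),
        n_in_habitat = sum(in_mod & detected),
        odds_ratio = unname(ft$estimate), p = ft$p.value)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a network as edge-list TSV (and optional GraphML)
#'
#' @param net An [igraph::graph].
#' @param path Edge-list TSV output path.
#' @param graphml_path Optional GraphML output path.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  el <- igraph::as_edgelist(net)
  w <- if ("weight" %in% igraph::edge_attr_names(net))
    igraph::E(net)$weight else rep(NA_real_, nrow(el))
  utils::write.table(
    data.frame(from = el[, 1], to = el[, 2], weight = w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  invisible(path)
}
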