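#' Assemble a pipeline run configuration
#'
#' Collects input paths (or a synthetic-data spec), stage toggles, the
#' analysis thresholds, and the master seed.  Thresholds default to the
#' workflow's standard constants: OTU identity 0.97 for diversity and 0.90
#' for networks, Spearman rho > 0.6 with p < 0.01 and total count > 5 for
#' network edges, 1000 permutations for PERMANOVA, 999 for IndVal/PSV
#' randomizations, 1000 random subsamples for rarefied PD, alpha 0.05.
#'
#' @param otu_table_path,lineage_path,metadata_path,tree_path Input file
#'   paths; leave `NULL` and supply `synth` to run on generated data.
#' @param synth A [synth_spec] to generate inputs (ignored when paths are
#'   given).
#' @param stages Stages to run, a subset of
#'   `c("alpha", "psv", "beta", "indval", "mrt", "net")`.
#' @param identity_diversity,identity_network OTU identity thresholds
#'   (recorded in provenance; clustering itself runs only when sequences
#'   are supplied upstream).
#' @param rho_min,p_max,min_total Network thresholds.
#' @param n_perm,n_rand,n_subsamples,alpha Resampling settings.
#' @param seed Master seed; each stage derives a deterministic child seed.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(otu_table_path = NULL, lineage_path = NULL,
                       metadata_path = NULL, tree_path = NULL,
                       synth = NULL,
                       stages = c("alpha", "psv", "beta", "indval", "mrt",
                                  "net"),
                       identity_diversity = 0.97, identity_network = 0.90,
                       rho_min = 0.6, p_max = 0.01, min_total = 5L,
                       n_perm = 1000L, n_rand = 999L, n_subsamples = 1000L,
                       alpha = 0.05, seed = 1L, out_dir = "phylocomm_out") {
  stopifnot(rho_min >= 0, rho_min <= 1, p_max > 0, p_max <= 1,
            n_perm >= 1, n_rand >= 1, n_subsamples >= 1,
            alpha > 0, alpha < 1)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the community-phylogenetics pipeline end to end
#'
#' Loads (or generates) the OTU table, metadata and phylogeny, then runs
#' the requested stages in order: alpha diversity, PSV null models, beta
#' diversity (weighted UniFrac, PCoA, PERMANOVA for habitat and each
#' environmental covariate), indicator value analysis, the multivariate
#' regression tree, and the co-occurrence network.  Each stage writes its
#' results as TSV/JSON under `out_dir` and a machine-readable manifest
#' records package version, seed, thresholds and input provenance.  Output
#' files contain no timestamps, so two runs with the same config and seed
#' are byte-identical.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with every stage's in-memory results plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

  if (!is.null(config$otu_table_path)) {
    if (is.null(config$metadata_path) || !file.exists(config$metadata_path))
      stop("metadata_path missing or not found")
    metadata <- read_metadata(config$metadata_path)
    tab <- read_otu_table(config$otu_table_path, config$lineage_path,
                          metadata = metadata)
    tree <- read_newick(config$tree_path)
    input <- c(otu_table = config$otu_table_path,
               metadata = config$metadata_path, tree = config$tree_path)
  } else {
    spec <- config$synth
    if (is.null(spec)) spec <- synth_spec(seed = config$seed)
    log_msg("generating synthetic dataset (seed ", spec$seed, ")")
    dat <- generate_dataset(spec)
    metadata <- dat$metadata
    tab <- dat$table
    tree <- dat$tree
    write_otu_table(tab, file.path(config$out_dir, "otu_table.tsv"),
                    file.path(config$out_dir, "otu_lineage.tsv"))
    write_metadata(metadata, file.path(config$out_dir, "metadata.tsv"))
    write_newick(tree, file.path(config$out_dir, "tree.nwk"))
    input <- c(synthetic = sprintf("synth_spec(seed = %d)", spec$seed))
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  results <- list()

  if ("alpha" %in% config$stages) {
    log_msg("alpha diversity")
    results$alpha <- diversity_table(
      tab, tree, metadata, n_subsamples = config$n_subsamples,
      seed = child_seed(config$seed, "alpha"))
    tsv(results$alpha, "alpha_diversity.tsv")
    results$sad <- sad_regression(tab, metadata)
    tsv(data.frame(lineage = results$sad$lineage,
                   mean_relative_abundance =
                     results$sad$mean_relative_abundance,
                   occurrence = results$sad$occurrence),
        "sad_lineages.tsv")
    tsv(data.frame(slope = results$sad$slope,
                   r_squared = results$sad$r_squared, p = results$sad$p),
        "sad_regression.tsv")
  }
  if ("psv" %in% config$stages) {
    log_msg("PSV null models")
    for (mod in c("null1", "null2")) {
      res <- psv_null(tab, tree, metadata, model = mod,
                      n_rand = config$n_rand,
                      seed = child_seed(config$seed, paste0("psv_", mod)))
      results[[paste0("psv_", mod)]] <- res
      tsv(cbind(res, model = mod), paste0("psv_", mod, ".tsv"))
    }
  }
  if ("beta" %in% config$stages) {
    log_msg("beta diversity")
    uf <- weighted_unifrac(tab, tree, normalized = TRUE)
    results$unifrac <- uf
    tsv(data.frame(site_id = rownames(uf), uf, check.names = FALSE),
        "unifrac.tsv")
    ord <- pcoa(uf)
    results$pcoa <- ord
    tsv(data.frame(site_id = rownames(ord$coords), ord$coords,
                   check.names = FALSE), "pcoa_coords.tsv")
    tsv(data.frame(axis = seq_along(ord$axis_explained),
                   explained = ord$axis_explained), "pcoa_explained.tsv")
    hab <- site_habitats(tab, metadata)
    pm <- permanova(uf, hab, n_perm = config$n_perm,
                    seed = child_seed(config$seed, "permanova_habitat"))
    results$permanova_habitat <- pm
    rows <- list(cbind(pm, factor_tested = "habitat"))
    for (cv in intersect(c("pH", "salinity", "temperature", "TOC", "TN"),
                         names(metadata))) {
      v <- metadata[[cv]][match(rownames(tab), metadata$site_id)]
      if (anyNA(v)) next
      pmc <- permanova(uf, v, n_perm = config$n_perm,
                       seed = child_seed(config$seed,
                                         paste0("permanova_", cv)))
      pmc$term[1] <- cv
      results[[paste0("permanova_", cv)]] <- pmc
      rows[[length(rows) + 1]] <- cbind(pmc, factor_tested = cv)
    }
    tsv(do.call(rbind, rows), "permanova.tsv")
  }
  if ("indval" %in% config$stages) {
    log_msg("indicator value analysis")
    results$indval <- indval(tab, metadata, by = "lineage",
                             n_perm = config$n_rand, alpha = config$alpha,
                             seed = child_seed(config$seed, "indval"))
    tsv(results$indval, "indval.tsv")
  }
  if ("mrt" %in% config$stages) {
    log_msg("multivariate regression tree")
    y <- relative_abundance(tab, by = "lineage", group = "site")
    x <- metadata[match(rownames(y), metadata$site_id),
                  intersect(c("pH", "salinity", "temperature", "TOC", "TN"),
                            names(metadata)), drop = FALSE]
    results$mrt <- mrt_fit(y, x, seed = child_seed(config$seed, "mrt"))
    write_mrt_json(results$mrt, file.path(config$out_dir, "mrt_tree.json"))
    leaf <- mrt_leaf_summary(results$mrt, metadata)
    tsv(do.call(rbind, lapply(leaf, function(l)
      data.frame(node = l$node, n_sites = l$n_sites, ss = l$ss,
                 sites = paste(l$sites, collapse = ",")))),
      "mrt_leaves.tsv")
  }
  if ("net" %in% config$stages) {
    log_msg("co-occurrence network")
    corr <- spearman_matrix(tab, min_total = config$min_total)
    net <- build_network(corr, rho_min = config$rho_min,
                         p_max = config$p_max,
                         lineage = otu_lineage(tab))
    results$network <- net
    if (igraph::ecount(net) > 0) {
      results$topology <- topology(net)
      tsv(results$topology$nodes, "network_nodes.tsv")
      part <- louvain(net, seed = child_seed(config$seed, "louvain"))
      results$modules <- part
      tsv(data.frame(node = names(part$membership),
                     module = unname(part$membership)),
          "network_modules.tsv")
      results$module_fisher <- module_habitat_fisher(part, tab, metadata)
      tsv(results$module_fisher, "module_habitat_fisher.tsv")
      write_network(net, file.path(config$out_dir, "network_edges.tsv"),
                    file.path(config$out_dir, "network.graphml"))
    } else {
      log_msg("network has no edges at the configured thresholds")
    }
  }
  manifest <- list(
    package = "phylocomm",
    version = as.character(utils::packageVersion("phylocomm")),
    seed = config$seed,
    stages = config$stages,
    thresholds = config[c("identity_diversity", "identity_network",
                          "rho_min", "p_max", "min_total", "n_perm",
                          "n_rand", "n_subsamples", "alpha")],
    input = as.list(input),
    n_sites = nrow(tab), n_otus = ncol(tab))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  log_msg("done; outputs in ", config$out_dir)
  invisible(results)
}
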