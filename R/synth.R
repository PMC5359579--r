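#' Specification for a synthetic multi-habitat clone-library survey
#'
#' Bundles the generative parameters for the synthetic community module:
#' habitat layout, phylogeny size, abundance model (log-normal lineage
#' baselines, lineage-by-habitat effects, per-lineage responses to the
#' salinity/TOC/temperature gradients, log-normal overdispersion), planted
#' habitat-exclusive indicator lineages, planted positively co-occurring
#' OTU pairs, and the clone-library size distribution.
#'
#' Defaults emulate a six-habitat terrestrial survey of 28 clone libraries
#' (peat 4, soil 2, hot spring 2, lagoon 13, mangrove 4, estuary 3) over
#' 100 OTUs in 10 lineages, with one indicator lineage fully exclusive to
#' peat and three strongly co-occurring OTU pairs; library sizes are drawn
#' log-uniformly in \[50, 500\] clones.
#'
#' @param seed Master seed; stage generators derive child seeds from it.
#' @param sites_per_habitat Named integer vector of sites per habitat.
#' @param n_otus Number of OTU tips.
#' @param n_lineages Number of lineages (monophyletic clades of the tree).
#' @param baseline_sd SD of log-normal lineage baseline abundances.
#' @param otu_sd SD of within-lineage per-OTU log-abundance variation.
#' @param habitat_effect_sd SD of lineage-by-habitat log-effects.
#' @param gradient_sd SD of per-lineage gradient coefficients (applied to
#'   z-scaled salinity, TOC and temperature).
#' @param overdispersion SD of per-site-per-OTU log-normal noise.
#' @param planted_indicators List of `list(lineage=, habitat=,
#'   exclusivity=)` entries; with exclusivity 1 the lineage's expected
#'   abundance is zero outside its habitat.
#' @param planted_pairs List of `list(otu_i=, otu_j=, strength=)` entries;
#'   each pair shares a per-site latent factor scaled by `strength`
#'   (comonotone mixing), producing positive rank dependence.
#' @param planted_toc_split `list(threshold=, lineage=, shift=)` or `NULL`:
#'   adds `shift` to the log abundance of the lineage's OTUs at sites whose
#'   TOC exceeds `threshold` (% dry weight), planting a composition step a
#'   regression tree should find.
#' @param library_size_range Clone-library size range (log-uniform draw).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       sites_per_habitat = c(peat = 4L, soil = 2L,
                                             hot_spring = 2L, lagoon = 13L,
                                             mangrove = 4L, estuary = 3L),
                       n_otus = 100L, n_lineages = 10L,
                       baseline_sd = 1, otu_sd = 0.5,
                       habitat_effect_sd = 1.5, gradient_sd = 0.4,
                       overdispersion = 0.3,
                       planted_indicators = list(
                         list(lineage = "L01", habitat = "peat",
                              exclusivity = 1)),
                       planted_pairs = NULL,
                       planted_toc_split = list(threshold = 12,
                                                lineage = "L02", shift = 3),
                       library_size_range = c(50L, 500L)) {
  stopifnot(n_otus >= 2, n_lineages >= 1, n_lineages <= n_otus,
            all(sites_per_habitat >= 1), length(library_size_range) == 2)
  # planted_pairs = NULL means "auto": generate_counts picks three pairs
  # among tips outside the planted indicator lineages
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate the synthetic phylogeny
#'
#' A seeded pure-birth (Yule) tree over the spec's OTUs, rescaled to unit
#' root-to-tip depth (ultrametric).  The `n_lineages` clades obtained by
#' cutting the ultrametric tree are the lineages, labelled `L01`, `L02`,
#' ... in tip order; the map is attached as attribute `lineage`.
#'
#' @param spec A [synth_spec].
#' @return An ultrametric [ape::phylo] with tip labels `OTU_0001`, ... and
#'   attribute `lineage` (named by tip).
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_otus < 2) stop("n_otus must be >= 2")
  tree <- with_seed(child_seed(spec$seed, "tree"),
                    ape::rphylo(spec$n_otus, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("OTU_%04d", seq_len(spec$n_otus))
  cl <- stats::cutree(stats::as.hclust(ape::as.phylo(tree)),
                      k = spec$n_lineages)
  lineage <- sprintf("L%02d", match(cl, unique(cl)))
  names(lineage) <- tree$tip.label
  attr(tree, "lineage") <- lineage
  tree
}

#' Generate synthetic per-site metadata
#'
#' Habitat-specific covariate distributions chosen to mirror the habitats'
#' real contrasts: lagoons, estuaries and mangroves are saline; peat is
#' organic-rich (high TOC) and acidic; hot springs are hot.  Values are
#' normal draws truncated at zero where negative values are physically
#' meaningless.
#'
#' @param spec A [synth_spec].
#' @return A `sample_metadata` data.frame: `site_id`, `habitat`, `pH`,
#'   `salinity`, `temperature`, `TOC`, `TN`.
#' @export
generate_metadata <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  habs <- names(spec$sites_per_habitat)
  pars <- list( # mean, sd per habitat: pH, salinity (PSU), temp (C), TOC, TN (% dw)
    peat       = list(pH = c(4.5, 0.5), salinity = c(0.5, 0.3),
                      temperature = c(12, 4), TOC = c(25, 5), TN = c(1.5, 0.4)),
    soil       = list(pH = c(6.5, 0.8), salinity = c(0.5, 0.3),
                      temperature = c(18, 5), TOC = c(3, 1), TN = c(0.3, 0.1)),
    hot_spring = list(pH = c(7.5, 1.0), salinity = c(1, 0.5),
                      temperature = c(65, 10), TOC = c(0.5, 0.3), TN = c(0.1, 0.05)),
    lagoon     = list(pH = c(8.5, 0.5), salinity = c(25, 10),
                      temperature = c(18, 5), TOC = c(1.5, 0.8), TN = c(0.2, 0.1)),
    mangrove   = list(pH = c(7, 0.5), salinity = c(20, 5),
                      temperature = c(25, 3), TOC = c(8, 2), TN = c(0.5, 0.2)),
    estuary    = list(pH = c(7.5, 0.5), salinity = c(15, 5),
                      temperature = c(15, 4), TOC = c(2, 0.8), TN = c(0.25, 0.1)))
  md <- with_seed(child_seed(spec$seed, "metadata"), {
    rows <- lapply(habs, function(h) {
      n <- spec$sites_per_habitat[[h]]
      p <- pars[[h]]
      if (is.null(p)) p <- list(pH = c(7, 1), salinity = c(5, 3),
                                temperature = c(15, 5), TOC = c(2, 1),
                                TN = c(0.3, 0.1))
      data.frame(
        site_id = sprintf("%s_%02d", h, seq_len(n)), habitat = h,
        pH = pmax(stats::rnorm(n, p$pH[1], p$pH[2]), 1),
        salinity = pmax(stats::rnorm(n, p$salinity[1], p$salinity[2]), 0),
        temperature = pmax(stats::rnorm(n, p$temperature[1],
                                        p$temperature[2]), 0),
        TOC = pmax(stats::rnorm(n, p$TOC[1], p$TOC[2]), 0.05),
        TN = pmax(stats::rnorm(n, p$TN[1], p$TN[2]), 0.01))
    })
    do.call(rbind, rows)
  })
  rownames(md) <- NULL
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Generate synthetic OTU counts
#'
#' Per-site expected abundances follow
#' `exp(baseline + habitat effect + gradient terms + noise)` at lineage
#' resolution; planted co-occurring pairs additionally share a per-site
#' latent factor (comonotone mixing) and are freed of habitat structure so
#' their association is purely the shared factor; planted exclusive
#' indicator lineages have expected abundance forced to zero outside their
#' habitat (and boosted within it).  Counts are a multinomial draw per
#' site at its log-uniform library size.
#'
#' @param spec A [synth_spec].
#' @param tree Tree from [generate_tree] (same spec).
#' @param metadata Metadata from [generate_metadata] (same spec).
#' @return An [otu_table] with the tree's lineage labels.
#' @export
generate_counts <- function(spec, tree, metadata) {
  stopifnot(inherits(spec, "synth_spec"))
  lineage <- attr(tree, "lineage")
  if (is.null(lineage) || !setequal(names(lineage), tree$tip.label))
    stop("tree does not carry the spec's lineage map; use generate_tree")
  if (length(lineage) != spec$n_otus)
    stop("tree/spec mismatch: tree has ", length(lineage), " tips, spec ",
         spec$n_otus, " OTUs")
  habs <- names(spec$sites_per_habitat)
  if (!setequal(unique(metadata$habitat), habs))
    stop("metadata/spec habitat mismatch")
  otus <- tree$tip.label
  lins <- sort(unique(lineage))
  n_site <- nrow(metadata)
  with_seed(child_seed(spec$seed, "counts"), {
    base_lin <- stats::setNames(stats::rnorm(length(lins), 0,
                                             spec$baseline_sd), lins)
    base_otu <- stats::setNames(
      base_lin[lineage[otus]] + stats::rnorm(spec$n_otus, 0, spec$otu_sd),
      otus)
    hab_eff <- matrix(stats::rnorm(length(lins) * length(habs), 0,
                                   spec$habitat_effect_sd),
                      length(lins), length(habs),
                      dimnames = list(lins, habs))
    covars <- scale(as.matrix(metadata[, c("salinity", "TOC", "temperature")]))
    grad <- matrix(stats::rnorm(length(lins) * 3, 0, spec$gradient_sd),
                   length(lins), 3, dimnames = list(lins, colnames(covars)))
    # site x otu log expected abundance
    loglam <- matrix(rep(base_otu, each = n_site), n_site, spec$n_otus,
                     dimnames = list(metadata$site_id, otus))
    loglam <- loglam + t(hab_eff[lineage[otus], metadata$habitat])
    loglam <- loglam + covars %*% t(grad[lineage[otus], ])
    loglam <- loglam + matrix(stats::rnorm(n_site * spec$n_otus, 0,
                                           spec$overdispersion),
                              n_site, spec$n_otus)
    # planted TOC threshold: a composition step along the TOC gradient
    ts <- spec$planted_toc_split
    if (!is.null(ts)) {
      members <- otus[lineage[otus] == ts$lineage]
      high <- metadata$TOC > ts$threshold
      loglam[high, members] <- loglam[high, members] + ts$shift
    }
    # planted co-occurring pairs: habitat-neutral, shared latent factor;
    # "auto" default picks the last six tips outside indicator lineages
    pairs <- spec$planted_pairs
    if (is.null(pairs)) {
      excl_lin <- vapply(spec$planted_indicators, `[[`, character(1),
                         "lineage")
      elig <- otus[!(lineage[otus] %in% excl_lin)]
      pairs <- if (length(elig) >= 6) {
        last6 <- utils::tail(elig, 6)
        lapply(c(1, 3, 5), function(k)
          list(otu_i = last6[k], otu_j = last6[k + 1], strength = 2.5))
      } else list()
    }
    pair_otus <- unlist(lapply(pairs, function(p) c(p$otu_i, p$otu_j)))
    for (p in pairs) {
      z <- stats::rnorm(n_site)
      # fixed intercept (not the lineage baseline) keeps the pair's
      # expected share ~2%, so zero-count ties stay rare and the shared
      # factor is what drives the ranks
      for (o in c(p$otu_i, p$otu_j))
        loglam[, o] <- 1 + p$strength * z +
          stats::rnorm(n_site, 0, spec$overdispersion)
    }
    # planted indicators: exclusivity outside, boost inside (overrides any
    # pair effect so the exclusivity invariant is absolute)
    for (pi in spec$planted_indicators) {
      members <- otus[lineage[otus] == pi$lineage]
      if (any(members %in% pair_otus))
        warning("planted pair OTU inside indicator lineage ", pi$lineage,
                "; exclusivity takes precedence")
      inside <- metadata$habitat == pi$habitat
      loglam[inside, members] <- loglam[inside, members] + 2.5
      if (pi$exclusivity >= 1) {
        loglam[!inside, members] <- -Inf
      } else {
        loglam[!inside, members] <- loglam[!inside, members] +
          log(1 - pi$exclusivity)
      }
    }
    lam <- exp(loglam)
    sizes <- round(exp(stats::runif(n_site, log(spec$library_size_range[1]),
                                    log(spec$library_size_range[2]))))
    counts <- t(vapply(seq_len(n_site), function(s)
      as.vector(stats::rmultinom(1, sizes[s], prob = lam[s, ])),
      integer(spec$n_otus)))
    dimnames(counts) <- list(metadata$site_id, otus)
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    out <- otu_table(counts, lineage = lineage[colnames(counts)],
                     identity = NA_real_)
    attr(out, "planted_pairs") <- pairs
    out
  })
}

#' Generate a complete synthetic dataset
#'
#' @param spec A [synth_spec] (default spec when omitted).
#' @return A list of class `synth_data`: `spec`, `tree`, `metadata`,
#'   `table`, and `pairs` (the planted co-occurring OTU pairs actually
#'   used, after auto-resolution).
#' @export
generate_dataset <- function(spec = synth_spec()) {
  tree <- generate_tree(spec)
  metadata <- generate_metadata(spec)
  table <- generate_counts(spec, tree, metadata)
  structure(list(spec = spec, tree = tree, metadata = metadata,
                 table = table, pairs = attr(table, "planted_pairs")),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf(
    "synthetic clone-library survey: %d sites in %d habitats, %d OTUs, seed %d\n",
    nrow(x$metadata), length(unique(x$metadata$habitat)), ncol(x$table),
    x$spec$seed))
  invisible(x)
}
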