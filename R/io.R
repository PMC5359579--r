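#' Read an aligned FASTA file of 16S rRNA clones
#'
#' Reads a multiple alignment in FASTA format.  Sequence ids must be unique
#' and all records must have the same (aligned) length; the site each clone
#' came from is parsed out of the FASTA header as a delimited field.
#'
#' @param path Path to an aligned FASTA file.
#' @param site_sep Field separator in the FASTA id (fixed string, default
#'   `"|"`).
#' @param site_field Which delimited field of the id carries the site id
#'   (default 1).
#' @return An object of class `aln_set`: a list with character vectors `id`,
#'   `site_id` and `seq` (upper-case aligned residues, gaps as `-`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">siteA|c1", "ACGT", ">siteA|c2", "AC-T"), fa)
#' read_fasta_alignment(fa)
#' @export
read_fasta_alignment <- function(path, site_sep = "|", site_field = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    warning("empty FASTA: ", path)
    return(aln_set(character(), character(), character()))
  }
  bin <- ape::read.FASTA(path)
  ids <- names(bin)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(as.character(bin), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  len <- nchar(seqs)
  if (length(unique(len)) > 1) {
    bad <- ids[which(len != len[1])[1]]
    stop("ragged alignment: record '", bad, "' has length ",
         len[ids == bad][1], ", expected ", len[1])
  }
  site <- vapply(strsplit(ids, site_sep, fixed = TRUE), function(f) {
    if (length(f) >= site_field) f[site_field] else f[1]
  }, character(1))
  aln_set(ids, site, unname(seqs))
}

aln_set <- function(id, site_id, seq) {
  structure(list(id = id, site_id = site_id, seq = seq), class = "aln_set")
}

#' @export
print.aln_set <- function(x, ...) {
  cat(sprintf("aln_set: %d aligned sequences (%d columns), %d sites\n",
              length(x$id), if (length(x$seq)) nchar(x$seq[1]) else 0L,
              length(unique(x$site_id))))
  invisible(x)
}

#' @export
length.aln_set <- function(x) length(x$id)

#' Apply the clone-library sequence selection filter
#'
#' Retains sequences whose ungapped length is strictly greater than `min_len`
#' and whose residues contain no ambiguity codes (anything outside
#' A, C, G, T and the gap character).  Lowercase input is upper-cased on
#' read, so the check is case-insensitive.  Record order is preserved and
#' counts of removed records per reason are attached.
#'
#' @param seqs An `aln_set`.
#' @param min_len Minimum ungapped length, exclusive (default 700 bp).
#' @return The filtered `aln_set`, with attribute `removed`, a named integer
#'   vector with counts for `ambiguity` and `short`.
#' @export
filter_sequences <- function(seqs, min_len = 700L) {
  stopifnot(inherits(seqs, "aln_set"))
  ungapped <- nchar(gsub("-", "", seqs$seq, fixed = TRUE))
  ambig <- grepl("[^ACGT-]", seqs$seq)
  keep <- !ambig & ungapped > min_len
  out <- aln_set(seqs$id[keep], seqs$site_id[keep], seqs$seq[keep])
  attr(out, "removed") <- c(ambiguity = sum(ambig),
                            short = sum(!ambig & ungapped <= min_len))
  out
}

#' Read a rooted newick phylogeny
#'
#' @param path Path to a newick file.
#' @param missing_branch What to do when branch lengths are absent:
#'   `"error"` (default) or `"zero"` (assume 0 with a warning).
#' @return An [ape::phylo] tree, rooted, with finite non-negative branch
#'   lengths and unique tip labels.
#' @export
read_newick <- function(path, missing_branch = c("error", "zero")) {
  missing_branch <- match.arg(missing_branch)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (missing_branch == "error")
      stop("tree has missing branch lengths (set missing_branch = \"zero\" ",
           "to assume 0)")
    warning("missing branch lengths assumed 0")
    if (is.null(tree$edge.length))
      tree$edge.length <- numeric(nrow(tree$edge))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. with an outgroup, ape::root) first")
  tree
}

#' Write a phylogeny to newick
#'
#' Branch lengths are written with 10 significant digits so that a
#' read/write round trip preserves them.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read per-site metadata
#'
#' Reads a tab-delimited table with one row per site.  Requires `site_id`
#' and `habitat` columns; the environmental covariates used downstream
#' (pH, salinity, temperature, TOC, TN) are read as numeric when present,
#' any other columns are preserved untouched.  Empty cells become `NA` and
#' are never imputed here.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame of class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!all(c("site_id", "habitat") %in% names(md)))
    stop("metadata must have 'site_id' and 'habitat' columns")
  md$site_id <- as.character(md$site_id)
  md$habitat <- as.character(md$habitat)
  if (anyDuplicated(md$site_id)) stop("duplicate site_id in metadata")
  if (any(is.na(md$habitat) | md$habitat == ""))
    stop("habitat must be non-empty for every site")
  for (v in intersect(c("pH", "salinity", "temperature", "TOC", "TN"),
                      names(md)))
    md[[v]] <- as.numeric(md[[v]])
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Write per-site metadata
#' @param metadata A metadata data.frame.
#' @param path Output TSV path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an OTU count table
#'
#' Reads a TSV with sites as rows (first column `site_id`) and OTUs as
#' columns, plus an optional 2-column lineage sidecar (`otu_id`, `lineage`).
#'
#' @param path Path to the count TSV.
#' @param lineage_path Optional path to the lineage sidecar TSV.
#' @param metadata Optional metadata; when given, sites present in the
#'   table but absent from the metadata raise an error listing them.
#' @param identity Identity threshold to record on the table.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, lineage_path = NULL, metadata = NULL,
                           identity = NA_real_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "site_id") stop("first column must be 'site_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$site_id
  lineage <- NULL
  if (!is.null(lineage_path)) {
    ldf <- utils::read.delim(lineage_path, stringsAsFactors = FALSE)
    lineage <- stats::setNames(as.character(ldf[[2]]), ldf[[1]])
  }
  if (!is.null(metadata)) validate_sites(m, metadata)
  otu_table(m, lineage = lineage, identity = identity)
}

#' Write an OTU count table (and lineage sidecar)
#' @param x An [otu_table].
#' @param path Output TSV path for counts.
#' @param lineage_path Optional output path for the 2-column lineage map.
#' @export
write_otu_table <- function(x, path, lineage_path = NULL) {
  df <- data.frame(site_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lineage_path)) {
    lin <- attr(x, "lineage")
    utils::write.table(data.frame(otu_id = names(lin), lineage = unname(lin)),
                       lineage_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
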