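#' Construct a site-by-OTU count table
#'
#' The central abundance object of the pipeline: an integer matrix with sites
#' as rows and OTUs as columns, an OTU-to-lineage label map, and the identity
#' threshold the OTUs were clustered at.
#'
#' @param counts Numeric matrix of non-negative integer counts, sites as rows
#'   (rownames = site ids), OTUs as columns (colnames = OTU ids).
#' @param lineage Named character vector mapping OTU id to lineage label.
#'   OTUs missing from the map are labelled `"U"` (unclassified).
#' @param identity Identity threshold (fraction, e.g. 0.97) the OTUs were
#'   clustered at; `NA` when unknown.
#' @return An object of class `otu_table`: the count matrix with attributes
#'   `lineage` and `identity`.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_0001", "OTU_0002")))
#' otu_table(m, lineage = c(OTU_0001 = "MCG-6", OTU_0002 = "MCG-5b"))
#' @export
otu_table <- function(counts, lineage = NULL, identity = NA_real_) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have site rownames and OTU colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate site ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(colSums(counts) == 0))
    stop("every OTU must have at least one count; empty OTUs: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  storage.mode(counts) <- "integer"
  lin <- rep("U", ncol(counts))
  names(lin) <- colnames(counts)
  if (!is.null(lineage)) {
    known <- intersect(names(lineage), colnames(counts))
    lin[known] <- as.character(lineage[known])
  }
  structure(counts, lineage = lin, identity = identity, class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d sites x %d OTUs, %d clones", nrow(x), ncol(x),
              sum(x)))
  if (!is.na(attr(x, "identity")))
    cat(sprintf(", clustered at %.0f%% identity", 100 * attr(x, "identity")))
  cat(sprintf("\nlineages: %s\n",
              paste(utils::head(sort(unique(attr(x, "lineage"))), 8),
                    collapse = ", ")))
  invisible(x)
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  if (!is.matrix(out)) return(out)
  structure(out, lineage = attr(x, "lineage")[colnames(out)],
            identity = attr(x, "identity"), class = "otu_table")
}

#' Lineage labels of an OTU table
#' @param x An `otu_table`.
#' @return Named character vector, one lineage label per OTU.
#' @export
otu_lineage <- function(x) attr(x, "lineage")

#' Aggregate an OTU table to lineage level
#'
#' Sums counts of OTUs sharing a lineage label, yielding a site-by-lineage
#' count matrix.
#'
#' @param x An `otu_table`.
#' @return Integer matrix, sites as rows, lineages as columns.
#' @export
lineage_table <- function(x) {
  lin <- attr(x, "lineage")
  out <- t(rowsum(t(unclass(x)), group = lin[colnames(x)]))
  storage.mode(out) <- "integer"
  out
}

# shared validation: every OTU-table site must appear in the metadata
validate_sites <- function(counts, metadata) {
  orphans <- setdiff(rownames(counts), metadata$site_id)
  if (length(orphans))
    stop("sites in OTU table missing from metadata: ",
         paste(orphans, collapse = ", "))
  invisible(TRUE)
}

# habitat label per OTU-table row, in row order
site_habitats <- function(counts, metadata) {
  validate_sites(counts, metadata)
  metadata$habitat[match(rownames(counts), metadata$site_id)]
}
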