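# small programmatic fixtures shared across test files

# star phylogeny with k unit-length pendant branches
star_tree <- function(k, labels = paste0("t", seq_len(k))) {
  txt <- paste0("(", paste0(labels, ":1", collapse = ","), ");")
  ape::read.tree(text = txt)
}

# write an aligned FASTA and return its path
write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))
  writeLines(lines, path)
  path
}

# minimal metadata for a set of sites
make_metadata <- function(site_id, habitat, ...) {
  md <- data.frame(site_id = site_id, habitat = habitat, ...,
                   stringsAsFactors = FALSE)
  class(md) <- c("sample_metadata", "data.frame")
  md
}

# small otu_table from a named count matrix
make_table <- function(counts, lineage = NULL) {
  otu_table(counts, lineage = lineage)
}

# evaluate an expression under a fixed seed
with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# write a one-off text file and return its path
textConnection_file <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}

# random site x OTU count table (no structure)
random_table <- function(n_sites, n_otus, lambda = 5) {
  m <- matrix(rpois(n_sites * n_otus, lambda), n_sites, n_otus,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              sprintf("OTU_%04d", seq_len(n_otus))))
  m[, colSums(m) > 0, drop = FALSE]
}
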