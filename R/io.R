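# Readers/writers for the pipeline's flat interchange formats (TSV, FASTA,
# Newick). Every stage can be rerun from these files alone.

#' Write / read a presence matrix as TSV
#'
#' @param matrix clusters x genomes integer matrix.
#' @param path TSV path (first column `cluster_id`, then one column per
#'   genome).
#' @return `write_presence_matrix` returns the path invisibly;
#'   `read_presence_matrix` the integer matrix.
#' @export
write_presence_matrix <- function(matrix, path) {
  write_tsv(data.frame(cluster_id = rownames(matrix),
                       as.data.frame(matrix), check.names = FALSE), path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  tab <- read_tsv(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- tab$cluster_id
  m
}

#' Write / read an alignment as FASTA
#'
#' @param alignment an [msa()].
#' @param path FASTA path.
#' @return `write_msa_fasta` returns the path invisibly; `read_msa_fasta`
#'   an `MSA` (cluster id taken from the file name).
#' @export
write_msa_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "MSA"))
  writeLines(paste0(">", alignment$names, "\n", alignment$seqs), path)
  invisible(path)
}

#' @rdname write_msa_fasta
#' @export
read_msa_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  msa(names(x), as.character(x),
      cluster_id = sub("\\.(fa|fasta|fna)$", "", basename(path)))
}

#' Read a genome -> clade table
#'
#' @param path TSV with columns `genome`, `clade`.
#' @return Named character vector genome -> clade.
#' @export
read_clade_table <- function(path) {
  tab <- read_tsv(path)
  assert_that(all(c("genome", "clade") %in% names(tab)),
              "clade table needs columns genome, clade")
  stats::setNames(as.character(tab$clade), tab$genome)
}
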